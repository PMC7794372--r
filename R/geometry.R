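#' Derive the lower and left radii of an orb web
#'
#' Field protocols measure the upper vertical radius (`r_u`) and right
#' horizontal radius (`r_r`) from the hub centre to the outermost capture
#' spiral; the opposite radii follow by subtraction from the corresponding
#' capture-spiral diameters:
#' \deqn{r_l = d_v - r_u, \qquad r_{le} = d_h - r_r.}
#'
#' @param d_v Vertical capture-spiral diameter, mm.
#' @param r_u Upper vertical radius, mm.
#' @param d_h Horizontal capture-spiral diameter, mm.
#' @param r_r Right horizontal radius, mm.
#' @return A data frame with columns `r_l` (lower vertical radius, mm) and
#'   `r_le` (left horizontal radius, mm).
#' @examples
#' derive_radii(d_v = 20, r_u = 8, d_h = 16, r_r = 8)
#' @export
derive_radii <- function(d_v, r_u, d_h, r_r) {
  check_positive(d_v = d_v, r_u = r_u, d_h = d_h, r_r = r_r)
  if (any(r_u >= d_v)) {
    stop("invalid geometry: r_u >= d_v implies a non-positive lower radius",
         call. = FALSE)
  }
  if (any(r_r >= d_h)) {
    stop("invalid geometry: r_r >= d_h implies a non-positive left radius",
         call. = FALSE)
  }
  data.frame(r_l = d_v - r_u, r_le = d_h - r_r)
}

#' Capture area of an orb web (Ellipse-Hub estimator)
#'
#' Approximates the capture area as the ellipse spanned by the two
#' capture-spiral diameters minus the central disc occupied by the hub and
#' spiral-free zone:
#' \deqn{A = \frac{d_v}{2}\,\frac{d_h}{2}\,\pi - \left(\frac{H}{2}\right)^2 \pi.}
#'
#' `H` is the *diameter* of the hub + free zone, so the subtracted disc has
#' radius `H/2`.
#'
#' @param d_v,d_h Vertical and horizontal capture-spiral diameters, mm.
#' @param H Diameter of the central hub and free zone, mm.
#' @return Capture area in mm^2 (divide by 100 for cm^2).
#' @examples
#' ellipse_hub_area(20, 10, 2)  # 49 * pi
#' @export
ellipse_hub_area <- function(d_v, d_h, H) {
  check_positive(d_v = d_v, d_h = d_h)
  if (any(H < 0)) stop("H must be non-negative", call. = FALSE)
  if (any(H >= pmin(d_v, d_h))) {
    stop("invalid geometry: hub + free zone diameter H must be smaller than ",
         "both capture-spiral diameters", call. = FALSE)
  }
  (d_v / 2) * (d_h / 2) * pi - (H / 2)^2 * pi
}

#' Vertical asymmetry of an orb web
#'
#' \deqn{a = \frac{r_u - r_l}{r_u + r_l}}
#'
#' Bounded in \[-1, 1\]; 0 for a vertically symmetric web, negative when the
#' hub sits closer to the top of the web (the typical resting position of
#' many orb weavers).
#'
#' @param r_u Upper vertical radius, mm.
#' @param r_l Lower vertical radius, mm.
#' @return Dimensionless asymmetry index.
#' @examples
#' web_asymmetry(5, 5)   # 0: symmetric
#' web_asymmetry(1, 3)   # -0.5: hub above centre
#' @export
web_asymmetry <- function(r_u, r_l) {
  if (any(r_u < 0) || any(r_l < 0)) {
    stop("radii must be non-negative", call. = FALSE)
  }
  if (any(r_u + r_l <= 0)) {
    stop("asymmetry undefined when both radii are zero", call. = FALSE)
  }
  (r_u - r_l) / (r_u + r_l)
}

#' Shape of an orb web
#'
#' \deqn{s = \frac{d_h - d_v}{d_h + d_v}}
#'
#' Bounded in (-1, 1); 0 for a circular web, negative when the web is taller
#' than it is wide.
#'
#' @param d_h Horizontal capture-spiral diameter, mm.
#' @param d_v Vertical capture-spiral diameter, mm.
#' @return Dimensionless shape index.
#' @examples
#' web_shape(10, 10)  # 0: circular
#' web_shape(10, 30)  # -0.5: tall, narrow web
#' @export
web_shape <- function(d_h, d_v) {
  check_positive(d_h = d_h, d_v = d_v)
  (d_h - d_v) / (d_h + d_v)
}

#' Mean mesh height of the capture spiral
#'
#' Average spacing between adjacent capture-spiral loops, taken over all four
#' quadrants (an adaptation of the classical vertical-quadrant formula to
#' include the horizontal quadrants):
#' \deqn{\bar{m} = \frac{1}{4}\left[\frac{r_u - H/2}{s_{Q1} - 1}
#'   + \frac{r_l - H/2}{s_{Q3} - 1} + \frac{r_r - H/2}{s_{Q2} - 1}
#'   + \frac{r_{le} - H/2}{s_{Q4} - 1}\right]}
#'
#' Quadrants are paired with radii exactly as in the field protocol:
#' Q1 with the upper radius, Q3 with the lower, Q2 with the right and Q4 with
#' the left. Each quadrant contributes the width of its spiral annulus
#' (radius minus hub radius) divided by the number of inter-loop gaps
#' (`s_Q - 1`), so every `s_Q` must be at least 2 and every radius must
#' exceed the hub radius `H/2`.
#'
#' @param r_u,r_l,r_r,r_le Quadrant radii (upper, lower, right, left), mm.
#' @param H Diameter of the hub + free zone, mm.
#' @param s_q1,s_q2,s_q3,s_q4 Capture-spiral turn counts along the
#'   mid-radius of quadrants 1-4.
#' @return Mean mesh height in mm.
#' @examples
#' mean_mesh_height(10, 10, 10, 10, H = 2, s_q1 = 4, s_q2 = 4, s_q3 = 4, s_q4 = 4)
#' @export
mean_mesh_height <- function(r_u, r_l, r_r, r_le, H, s_q1, s_q2, s_q3, s_q4) {
  check_positive(r_u = r_u, r_l = r_l, r_r = r_r, r_le = r_le)
  if (any(H < 0)) stop("H must be non-negative", call. = FALSE)
  s <- cbind(s_q1, s_q2, s_q3, s_q4)
  if (any(s <= 1)) {
    stop("mesh height undefined: every quadrant needs at least 2 spiral ",
         "turns (s_Q >= 2)", call. = FALSE)
  }
  r <- cbind(r_u, r_r, r_l, r_le)  # column order matches s_q1, s_q2, s_q3, s_q4
  if (any(r <= H / 2)) {
    stop("mesh height undefined: every radius must exceed the hub radius H/2",
         call. = FALSE)
  }
  ((r_u - H / 2) / (s_q1 - 1) + (r_l - H / 2) / (s_q3 - 1) +
     (r_r - H / 2) / (s_q2 - 1) + (r_le - H / 2) / (s_q4 - 1)) / 4
}

#' Size-normalised (relative) metrics
#'
#' Divides a length-like metric by cephalothorax width and an area-like
#' metric by its square, removing spider-size scaling so species of
#' different sizes can be compared: relative web area = area / cw^2,
#' relative mesh height = mesh / cw, relative leg length = patella-tibia
#' length / cw.
#'
#' @param x Metric value(s): an area (mm^2) when `power = 2`, a length (mm)
#'   when `power = 1`.
#' @param ceph_width Cephalothorax width, mm; must be positive.
#' @param power Exponent applied to `ceph_width` (1 for lengths, 2 for areas).
#' @return Dimensionless relative metric.
#' @examples
#' relative_metric(100, 2, power = 2)  # relative area: 25
#' relative_metric(3, 2)               # relative mesh height: 1.5
#' @export
relative_metric <- function(x, ceph_width, power = 1) {
  if (any(ceph_width <= 0, na.rm = TRUE)) {
    stop("cephalothorax width must be positive", call. = FALSE)
  }
  x / ceph_width^power
}

#' Compute all derived web metrics for a measurement table
#'
#' Appends the derived geometric statistics to a web-measurement table (see
#' [read_measurements()] for the schema) and, when a paired morphology table
#' is supplied, the size-normalised metrics as well.
#'
#' Mesh height requires at least 2 spiral turns in every quadrant; webs
#' violating this are assigned `NA` mesh columns (flagged missing) rather
#' than dropped, and downstream models use available cases.
#'
#' Appended columns: `area_cm2` (Ellipse-Hub capture area, cm^2),
#' `asymmetry`, `shape`, `mesh_mm`, `spiral_turns` (mean of the four
#' quadrant counts), and with morphology `rel_area`, `rel_mesh`, `rel_leg1`,
#' `rel_leg3` (log-ready, dimensionless).
#'
#' @param webs Web-measurement data frame (measurement schema).
#' @param morphology Optional spider-morphology data frame (morphology
#'   schema) with a `web_id` column pairing each spider to its web.
#' @return The input table with metric columns appended (and morphology
#'   columns merged in, when supplied).
#' @seealso [ellipse_hub_area()], [web_asymmetry()], [web_shape()],
#'   [mean_mesh_height()], [relative_metric()]
#' @export
web_metrics <- function(webs, morphology = NULL) {
  rad <- derive_radii(webs$d_v_mm, webs$r_u_mm, webs$d_h_mm, webs$r_r_mm)
  out <- webs
  out$r_l_mm <- rad$r_l
  out$r_le_mm <- rad$r_le
  out$area_cm2 <- ellipse_hub_area(webs$d_v_mm, webs$d_h_mm, webs$H_mm) / 100
  out$asymmetry <- web_asymmetry(webs$r_u_mm, rad$r_l)
  out$shape <- web_shape(webs$d_h_mm, webs$d_v_mm)
  out$spiral_turns <- rowMeans(webs[, c("s_q1", "s_q2", "s_q3", "s_q4")])

  # mesh height only where defined (all s_Q >= 2, all radii beyond the hub)
  radii <- cbind(webs$r_u_mm, rad$r_l, webs$r_r_mm, rad$r_le)
  turns <- as.matrix(webs[, c("s_q1", "s_q2", "s_q3", "s_q4")])
  ok <- apply(turns >= 2, 1, all) & apply(radii > webs$H_mm / 2, 1, all)
  out$mesh_mm <- NA_real_
  if (any(ok)) {
    out$mesh_mm[ok] <- mean_mesh_height(
      webs$r_u_mm[ok], rad$r_l[ok], webs$r_r_mm[ok], rad$r_le[ok],
      webs$H_mm[ok],
      webs$s_q1[ok], webs$s_q2[ok], webs$s_q3[ok], webs$s_q4[ok]
    )
  }

  if (!is.null(morphology)) {
    morph <- morphology[, c("web_id", "ceph_width_mm", "total_length_mm",
                            "pt_leg1_mm", "pt_leg3_mm")]
    out <- merge(out, morph, by = "web_id", all.x = TRUE, sort = FALSE)
    out$rel_area <- relative_metric(out$area_cm2 * 100, out$ceph_width_mm,
                                    power = 2)
    out$rel_mesh <- relative_metric(out$mesh_mm, out$ceph_width_mm)
    out$rel_leg1 <- relative_metric(out$pt_leg1_mm, out$ceph_width_mm)
    out$rel_leg3 <- relative_metric(out$pt_leg3_mm, out$ceph_width_mm)
  }
  out
}

# shared argument check: every value strictly positive
check_positive <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    if (any(!is.finite(args[[nm]])) || any(args[[nm]] <= 0)) {
      stop(nm, " must be strictly positive and finite", call. = FALSE)
    }
  }
  invisible(TRUE)
}
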