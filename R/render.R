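#' Render a schematic SVG drawing of one web
#'
#' Produces a stylised orb-web schematic from a single measurement row:
#' the capture spiral as concentric ellipses between the hub and the outer
#' diameters, radii from the hub centre outwards, and — the structural
#' contrast between regimes — either an enclosing frame polygon to which the
#' radii attach (`n_frame > 0`) or, for frameless cave-style webs, a rough
#' substrate arc to which the radii anchor directly, acting as mooring
#' threads. The drawing is cosmetic (a visual check, not a measurement).
#'
#' @param web One row of a measurement table (data frame with the
#'   measurement schema columns).
#' @param path Output SVG file path.
#' @param size Canvas size in pixels.
#' @return `path`, invisibly.
#' @export
render_web_svg <- function(web, path, size = 400) {
  stopifnot(nrow(web) == 1)
  d_v <- web$d_v_mm; d_h <- web$d_h_mm; H <- web$H_mm
  r_u <- web$r_u_mm; r_l <- d_v - r_u
  n_radii <- max(3, round(web$n_radii))
  n_frame <- round(web$n_frame)
  turns <- max(2, round(mean(c(web$s_q1, web$s_q2, web$s_q3, web$s_q4))))

  sc <- (size * 0.36) / (max(d_v, d_h) / 2)  # mm -> px
  cx <- size / 2
  # place the ellipse centre so the hub sits at canvas centre
  cy <- size / 2 - (d_v / 2 - r_u) * sc
  hub_x <- size / 2
  hub_y <- size / 2

  el <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
    size, size, size, size),
    sprintf('<rect width="%d" height="%d" fill="white"/>', size, size))

  # capture spiral: interpolate from hub disc to the outer ellipse
  for (k in seq_len(turns)) {
    t <- k / turns
    ex <- hub_x + t * (cx - hub_x)
    ey <- hub_y + t * (cy - hub_y)
    rx <- (H / 2 + t * (d_h / 2 - H / 2)) * sc
    ry <- (H / 2 + t * (d_v / 2 - H / 2)) * sc
    el <- c(el, sprintf(
      '<ellipse cx="%.1f" cy="%.1f" rx="%.1f" ry="%.1f" fill="none" stroke="#777" stroke-width="0.8"/>',
      ex, ey, rx, ry))
  }

  # radii endpoints on (or beyond) the outer ellipse
  ang <- seq(0, 2 * pi, length.out = n_radii + 1)[-1]
  reach <- if (n_frame > 0) 1.0 else 1.22  # frameless radii run to substrate
  px <- cx + reach * (d_h / 2) * sc * cos(ang)
  py <- cy + reach * (d_v / 2) * sc * sin(ang)
  for (i in seq_len(n_radii)) {
    el <- c(el, sprintf(
      '<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#333" stroke-width="0.9"/>',
      hub_x, hub_y, px[i], py[i]))
  }

  if (n_frame > 0) {
    # enclosing frame: polygon slightly outside the capture spiral
    fang <- seq(0, 2 * pi, length.out = max(n_frame, 3) + 1)
    fx <- cx + 1.08 * (d_h / 2) * sc * cos(fang)
    fy <- cy + 1.08 * (d_v / 2) * sc * sin(fang)
    pts <- paste(sprintf("%.1f,%.1f", fx, fy), collapse = " ")
    el <- c(el, sprintf(
      '<polyline points="%s" fill="none" stroke="black" stroke-width="1.6"/>',
      pts))
  } else {
    # frameless: rough substrate arc the radii moor to directly
    aa <- seq(0, 2 * pi, length.out = 120)
    wob <- 1.24 + 0.02 * sin(7 * aa)
    sx <- cx + wob * (d_h / 2) * sc * cos(aa)
    sy <- cy + wob * (d_v / 2) * sc * sin(aa)
    pts <- paste(sprintf("%.1f,%.1f", sx, sy), collapse = " ")
    el <- c(el, sprintf(
      '<polyline points="%s" fill="none" stroke="#8a6d4f" stroke-width="3"/>',
      pts))
  }

  # hub + free zone
  el <- c(el, sprintf(
    '<ellipse cx="%.1f" cy="%.1f" rx="%.1f" ry="%.1f" fill="white" stroke="#333" stroke-width="1"/>',
    hub_x, hub_y, (H / 2) * sc, (H / 2) * sc),
    sprintf('<circle cx="%.1f" cy="%.1f" r="2.5" fill="#333"/>',
            hub_x, hub_y),
    sprintf('<text x="6" y="%d" font-size="11" fill="#333">%s (%s)</text>',
            size - 8, web$web_id, web$species),
    "</svg>")
  writeLines(el, path)
  invisible(path)
}
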