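#' @keywords internal
#' @noRd
# Run code with a temporary RNG state; the caller's .Random.seed is restored.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Truncated-normal draws by inverse-CDF, centred at `center` with fixed
# truncation window [lo, hi]. Errors out if the window has (numerically)
# zero mass under the centre's normal — an infeasible configuration.
rtnorm <- function(n, center, sd, lo, hi) {
  if (sd == 0) {
    x <- rep(pmin(pmax(center, lo), hi), length.out = n)
    return(x)
  }
  plo <- pnorm(lo, center, sd)
  phi <- pnorm(hi, center, sd)
  if (any(phi - plo < 1e-12)) {
    stop("truncation window [", signif(lo, 4), ", ", signif(hi, 4),
         "] is infeasible for the requested centre/sd", call. = FALSE)
  }
  qnorm(runif(n, plo, phi), center, sd)
}

# Symmetric truncation window about the target mean: mean +/- c with
# c = min(width * sd, distance to either physical bound). Symmetry keeps the
# draw unbiased for the target mean even after truncation.
trunc_window <- function(mean, sd, phys_lo, phys_hi, width = 3) {
  if (sd == 0) return(c(mean, mean))
  cc <- min(width * sd, mean - phys_lo, phys_hi - mean)
  if (cc <= 0) {
    stop("target mean ", signif(mean, 4), " lies outside its physical ",
         "bounds [", signif(phys_lo, 4), ", ", signif(phys_hi, 4), "]",
         call. = FALSE)
  }
  c(mean - cc, mean + cc)
}

# Unbiased stochastic rounding: E[round(x)] = x.
stochastic_round <- function(x) {
  fl <- floor(x)
  as.integer(fl + (runif(length(x)) < x - fl))
}

# physical bounds for each target metric (generator-wide)
.metric_bounds <- list(
  area_cm2     = c(1, Inf),
  asymmetry    = c(-0.85, 0.85),
  shape        = c(-0.6, 0.6),
  spiral_turns = c(2, Inf),
  ceph_width   = c(0.2, Inf),
  total_length = c(0.5, Inf),
  pt_leg1      = c(0.2, Inf),
  pt_leg3      = c(0.2, Inf)
)

# Deterministic round-robin assignment of n records to the archetype's
# locations; shared by sample_webs() and sample_morphology() so a web and
# its resident spider land in the same location.
location_labels <- function(config, n) {
  tag <- if (config$frame_regime == "eliminated") "cave" else "transect"
  idx <- rep_len(seq_len(config$n_locations), n)
  sprintf("%s_%s%02d", gsub("[^A-Za-z]+", "_", config$species), tag, idx)
}

# One draw of a target metric for n records: location offsets plus residual
# noise, truncated symmetrically about the configured mean. Decomposes the
# configured (total) SD into between-location and residual parts:
# sd_loc = f * sd_res, sd_loc^2 + sd_res^2 = sd_total^2. Offsets are centred
# to sum to zero within the species unless the archetype opts out.
draw_target <- function(config, metric, loc_idx, n) {
  tg <- config$targets[[metric]]
  b <- .metric_bounds[[metric]]
  win <- trunc_window(tg["mean"], tg["sd"], b[1], b[2])
  f <- config$location_sd
  sd_res <- tg["sd"] / sqrt(1 + f^2)
  sd_loc <- f * sd_res
  off <- rnorm(config$n_locations, 0, sd_loc)
  if (config$center_locations) {
    off <- if (config$n_locations > 1) off - mean(off) else 0 * off
  }
  rtnorm(n, center = tg["mean"] + off[loc_idx], sd = sd_res,
         lo = win[1], hi = win[2])
}

#' Simulate web measurements for one species archetype
#'
#' Samples webs in *metric* space and inverts the geometric formulas to emit
#' raw measurement variables, so the derived metrics of every generated web
#' reproduce its drawn targets exactly:
#'
#' 1. Draw target area \eqn{A} (cm^2), asymmetry \eqn{y}, shape \eqn{p} and
#'    per-quadrant spiral turns \eqn{s} from truncated normals around the
#'    archetype means, with a centred location-level offset shared by webs
#'    of the same location.
#' 2. Solve the shape identity and the Ellipse-Hub area for the diameters:
#'    \eqn{d_h = d_v (1+p)/(1-p)} and
#'    \eqn{d_v = \sqrt{4 \cdot 100A / (\pi [(1+p)/(1-p) - f^2])}} with hub
#'    diameter \eqn{H = f d_v} (`f = hub_fraction`).
#' 3. Set \eqn{r_u = d_v (1+y)/2} (so the recomputed asymmetry is exactly
#'    \eqn{y}); \eqn{r_r} is jittered around \eqn{d_h/2} (horizontal
#'    asymmetry is not a target).
#' 4. Allocate integer spiral counts per quadrant by unbiased stochastic
#'    rounding of \eqn{s} plus a small jitter, floored at 2.
#' 5. Draw the radius count from a Poisson around `radii_mean` (floor 3).
#' 6. Apply the structural regime: `eliminated` webs have 0-2 frame threads
#'    (heavily weighted to 0) and moor through their radii
#'    (`n_mooring = n_radii` + small jitter); `enclosed` webs carry a frame
#'    of about `n_radii` sections and only 3-7 mooring threads.
#'
#' @param config A [archetype_config()] object.
#' @param n Number of webs (defaults to the archetype's design size).
#' @param seed Integer seed; identical `(config, n, seed)` gives an
#'   identical table.
#' @return Data frame in the measurement schema (see [read_measurements()]).
#'   The drawn metric-space targets are attached as `attr(x, "targets")`;
#'   recomputing area, asymmetry and shape from the emitted measurements
#'   reproduces them to numerical precision (spiral counts are integers, so
#'   the per-web quadrant mean is the stochastically rounded target).
#' @export
sample_webs <- function(config, n = config$n_webs, seed = 1L) {
  stopifnot(inherits(config, "web_archetype"), n >= 1)
  with_seed(seed, {
    loc <- location_labels(config, n)
    loc_idx <- rep_len(seq_len(config$n_locations), n)

    A <- draw_target(config, "area_cm2", loc_idx, n)
    y <- draw_target(config, "asymmetry", loc_idx, n)
    p <- draw_target(config, "shape", loc_idx, n)
    s <- draw_target(config, "spiral_turns", loc_idx, n)

    f <- config$hub_fraction
    ratio <- (1 + p) / (1 - p)
    d_v <- sqrt(4 * (100 * A) / (pi * (ratio - f^2)))
    d_h <- d_v * ratio
    H <- f * d_v
    r_u <- d_v * (1 + y) / 2
    r_r <- d_h / 2 * (1 + runif(n, -0.08, 0.08))

    turns <- matrix(vapply(1:4, function(q) {
      stochastic_round(pmax(s + rnorm(n, 0, 0.5), 2))
    }, integer(n)), nrow = n)

    n_radii <- pmax(rpois(n, config$radii_mean), 3L)
    if (config$frame_regime == "eliminated") {
      n_frame <- sample(0:2, n, replace = TRUE, prob = c(0.92, 0.06, 0.02))
      n_mooring <- n_radii + sample(0:2, n, replace = TRUE,
                                    prob = c(0.6, 0.3, 0.1))
    } else {
      n_frame <- pmax(n_radii - rpois(n, 3), 1L)
      n_mooring <- sample(3:7, n, replace = TRUE)
    }

    webs <- data.frame(
      web_id = sprintf("%s_w%04d", gsub("[^A-Za-z]+", "_", config$species),
                       seq_len(n)),
      species = config$species, location = loc,
      d_v_mm = d_v, d_h_mm = d_h, r_u_mm = r_u, r_r_mm = r_r, H_mm = H,
      s_q1 = turns[, 1], s_q2 = turns[, 2], s_q3 = turns[, 3],
      s_q4 = turns[, 4],
      n_radii = n_radii, n_frame = as.integer(n_frame),
      n_mooring = as.integer(n_mooring),
      stringsAsFactors = FALSE
    )
    bad <- validate_measurements(webs)
    if (nrow(bad)) {
      stop("generator produced ", nrow(bad), " invalid web record(s); ",
           "the archetype configuration is infeasible", call. = FALSE)
    }
    # drawn metric-space targets, for round-trip verification
    attr(webs, "targets") <- data.frame(web_id = webs$web_id, area_cm2 = A,
                                        asymmetry = y, shape = p,
                                        spiral_turns = s)
    webs
  })
}

#' Simulate resident-spider morphology for one species archetype
#'
#' Truncated-normal draws of total length, cephalothorax width and the
#' patella-tibia lengths of legs I and III around the archetype means, with
#' the same centred location-offset construction as [sample_webs()].
#' Locations are assigned by the same deterministic round-robin, so record
#' `i` of the morphology table belongs to the resident spider of web `i`.
#'
#' @inheritParams sample_webs
#' @return Data frame in the morphology schema (see [read_morphology()]);
#'   `web_id` is filled in by [make_study()] when webs and spiders are
#'   paired.
#' @export
sample_morphology <- function(config, n = config$n_webs, seed = 1L) {
  stopifnot(inherits(config, "web_archetype"), n >= 1)
  with_seed(seed, {
    loc <- location_labels(config, n)
    loc_idx <- rep_len(seq_len(config$n_locations), n)
    tl <- draw_target(config, "total_length", loc_idx, n)
    cw <- draw_target(config, "ceph_width", loc_idx, n)
    l1 <- draw_target(config, "pt_leg1", loc_idx, n)
    l3 <- draw_target(config, "pt_leg3", loc_idx, n)
    spiders <- data.frame(
      spider_id = sprintf("%s_s%04d",
                          gsub("[^A-Za-z]+", "_", config$species),
                          seq_len(n)),
      web_id = NA_character_,
      species = config$species, location = loc,
      total_length_mm = tl, ceph_width_mm = cw,
      pt_leg1_mm = l1, pt_leg3_mm = l3,
      stringsAsFactors = FALSE
    )
    if (any(spiders$ceph_width_mm >= spiders$total_length_mm)) {
      stop("generator produced a spider with cephalothorax width >= total ",
           "length; the archetype configuration is infeasible",
           call. = FALSE)
    }
    spiders
  })
}

#' Simulate a full multi-species study
#'
#' Generates webs and their resident spiders for each archetype and joins
#' them into one study: one morphology record is paired to each web (field
#' protocols collect the resident spider of every measured web), and every
#' location label is nested within exactly one species.
#'
#' @param configs List of [archetype_config()] objects (one per species);
#'   defaults to [default_archetypes()].
#' @param seed Integer master seed; per-species sub-seeds are derived from
#'   it deterministically.
#' @return An object of class `orb_study`: a list with data frames `webs`
#'   and `morphology`, plus the `seed` used.
#' @examples
#' study <- make_study(seed = 1)
#' nrow(study$webs)  # 19 + 29 + 25 = 73
#' @export
make_study <- function(configs = default_archetypes(), seed = 1L) {
  if (length(configs) == 0) {
    return(structure(list(webs = empty_measurements(),
                          morphology = empty_morphology(), seed = seed),
                     class = "orb_study"))
  }
  sub <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                    2L * length(configs)))
  webs <- vector("list", length(configs))
  morph <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    w <- sample_webs(configs[[i]], seed = sub[2 * i - 1])
    m <- sample_morphology(configs[[i]], seed = sub[2 * i])
    m$web_id <- w$web_id
    webs[[i]] <- w
    morph[[i]] <- m
  }
  structure(list(webs = do.call(rbind, webs),
                 morphology = do.call(rbind, morph), seed = seed),
            class = "orb_study")
}

#' @export
print.orb_study <- function(x, ...) {
  cat("<orb_study> ", nrow(x$webs), " webs / ", nrow(x$morphology),
      " spiders (seed ", x$seed, ")\n", sep = "")
  tab <- table(x$webs$species)
  for (sp in names(tab)) {
    nl <- length(unique(x$webs$location[x$webs$species == sp]))
    cat("  ", sp, ": ", tab[[sp]], " webs across ", nl, " location(s)\n",
        sep = "")
  }
  invisible(x)
}
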