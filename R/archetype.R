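#' Generative archetype for one species
#'
#' An archetype bundles everything needed to simulate webs and resident
#' spiders of one species: target distributions for the derived web metrics
#' and morphology variables (each a mean plus a per-observation SD), the
#' structural regime of the web, and the sampling design (number of webs and
#' of sampling locations, with a between-location variance fraction).
#'
#' Target distributions are given on the *metric* scale (area in cm^2,
#' asymmetry/shape dimensionless, spiral turns per quadrant, morphology in
#' mm); the generator inverts the geometric formulas to produce raw
#' measurement variables whose recomputed metrics reproduce the drawn
#' targets exactly (see [sample_webs()]).
#'
#' @param species Species label.
#' @param n_webs Default number of webs (and resident spiders) to simulate.
#' @param n_locations Number of sampling locations (caves or transects);
#'   locations are nested within species.
#' @param targets Named list of `c(mean, sd)` pairs for `area_cm2`,
#'   `asymmetry`, `shape`, `spiral_turns`, `ceph_width`, `total_length`,
#'   `pt_leg1`, `pt_leg3`. SDs are per-observation (total) SDs.
#' @param frame_regime `"eliminated"` (cave webs: no enclosing frame, radii
#'   attach directly to the substrate and so act as mooring threads) or
#'   `"enclosed"` (conventional orb: frame present, few mooring threads).
#' @param hub_fraction Hub + free-zone diameter `H` as a fraction of the
#'   vertical diameter `d_v`.
#' @param radii_mean Mean radius count (Poisson).
#' @param location_sd Between-location SD as a fraction of the residual SD.
#' @param center_locations If `TRUE` (default), the drawn location offsets
#'   are centred to sum to zero within the species, so the generated sample
#'   mean recovers the configured target mean exactly in expectation even
#'   with very few locations — the right choice for calibration round
#'   trips. Set `FALSE` to leave the offsets as exchangeable iid draws,
#'   the right choice when simulating data to probe mixed-model inference
#'   (sum-to-zero offsets are negatively dependent and make species-level
#'   F tests conservative).
#' @return An object of class `web_archetype`.
#' @seealso [default_archetypes()] for the three calibrated species
#'   archetypes.
#' @export
archetype_config <- function(species, n_webs, n_locations, targets,
                             frame_regime = c("enclosed", "eliminated"),
                             hub_fraction = 0.1, radii_mean = 18,
                             location_sd = 0.3, center_locations = TRUE) {
  frame_regime <- match.arg(frame_regime)
  required <- c("area_cm2", "asymmetry", "shape", "spiral_turns",
                "ceph_width", "total_length", "pt_leg1", "pt_leg3")
  missing <- setdiff(required, names(targets))
  if (length(missing)) {
    stop("targets missing: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  for (nm in required) {
    t <- targets[[nm]]
    if (length(t) != 2 || !all(is.finite(t)) || t[2] < 0) {
      stop("target '", nm, "' must be c(mean, sd) with sd >= 0",
           call. = FALSE)
    }
  }
  stopifnot(n_webs >= 1, n_locations >= 1,
            hub_fraction > 0, hub_fraction < 1,
            radii_mean >= 3, location_sd >= 0)
  structure(
    list(species = species, n_webs = as.integer(n_webs),
         n_locations = as.integer(n_locations),
         targets = lapply(targets[required], function(t) {
           setNames(as.numeric(t), c("mean", "sd"))
         }),
         frame_regime = frame_regime, hub_fraction = hub_fraction,
         radii_mean = radii_mean, location_sd = location_sd,
         center_locations = isTRUE(center_locations)),
    class = "web_archetype"
  )
}

#' @export
print.web_archetype <- function(x, ...) {
  cat("<web_archetype> ", x$species, "\n", sep = "")
  cat("  design: ", x$n_webs, " webs across ", x$n_locations,
      " location(s); frame regime: ", x$frame_regime, "\n", sep = "")
  tg <- do.call(rbind, x$targets)
  cat("  targets (mean, sd):\n")
  print(round(tg, 3))
  invisible(x)
}

#' Convert a standard error of the mean to a per-observation SD
#'
#' Published group summaries are typically mean +/- SEM; the generator needs
#' the per-observation SD, recovered as `SEM * sqrt(n)` for the printed
#' group size.
#'
#' @param sem Standard error of the mean.
#' @param n Group sample size the SEM was computed from.
#' @return Per-observation standard deviation.
#' @examples
#' sem_to_sd(11, 19)  # ~47.96
#' @export
sem_to_sd <- function(sem, n) {
  stopifnot(sem >= 0, n >= 1)
  sem * sqrt(n)
}

#' Default archetypes: one cave and two surface tetragnathids
#'
#' Returns the three calibrated species archetypes used throughout the
#' package, emulating a field study of the European cave orb spider
#' *Meta menardi* (19 webs from 3 caves) and two surface-dwelling relatives,
#' *Metellina mengei* (29 webs from 10 woodland transects) and *Tetragnatha
#' montana* (25 webs from 5 riverside transects).
#'
#' Web-metric and body-size means and SEMs are the published group summaries
#' for these species (absolute web area 108/132/251 cm^2; asymmetry
#' -0.02/-0.16/-0.17; shape 0.05/-0.05/-0.06; spiral turns 6.0/15.0/14.4;
#' cephalothorax width 2.57/1.56/1.72 mm; total length 8.28/4.47/8.81 mm),
#' with SEMs converted to per-observation SDs via [sem_to_sd()] at the
#' printed group sizes. Patella-tibia leg lengths are calibration choices
#' (no published means exist) set so that relative leg I is longest in
#' *T. montana* and relative leg III shortest in *M. mengei*, matching the
#' published ordination. The cave archetype uses the `eliminated` frame
#' regime; the radius-count mean (18) and hub fraction (0.1) are free
#' parameters shared by all three archetypes.
#'
#' @return Named list of three [archetype_config()] objects
#'   (`"Meta menardi"`, `"Metellina mengei"`, `"Tetragnatha montana"`).
#' @export
default_archetypes <- function() {
  cave <- archetype_config(
    species = "Meta menardi", n_webs = 19, n_locations = 3,
    frame_regime = "eliminated",
    targets = list(
      area_cm2     = c(108,  sem_to_sd(11,   19)),
      asymmetry    = c(-0.02, sem_to_sd(0.04, 19)),
      shape        = c(0.05, sem_to_sd(0.03, 19)),
      spiral_turns = c(6.0,  sem_to_sd(0.4,  19)),
      ceph_width   = c(2.57, sem_to_sd(0.10, 19)),
      total_length = c(8.28, sem_to_sd(0.32, 19)),
      pt_leg1      = c(9.0,  0.9),   # calibration: rel leg I ~ 3.5
      pt_leg3      = c(5.1,  0.5)    # calibration: rel leg III ~ 2.0
    )
  )
  wood <- archetype_config(
    species = "Metellina mengei", n_webs = 29, n_locations = 10,
    frame_regime = "enclosed",
    targets = list(
      area_cm2     = c(132,  sem_to_sd(11,   29)),
      asymmetry    = c(-0.16, sem_to_sd(0.02, 29)),
      shape        = c(-0.05, sem_to_sd(0.02, 29)),
      spiral_turns = c(15.0, sem_to_sd(0.7,  29)),
      ceph_width   = c(1.56, sem_to_sd(0.03, 29)),
      total_length = c(4.47, sem_to_sd(0.10, 29)),
      pt_leg1      = c(4.4,  0.4),   # calibration: rel leg I ~ 2.8
      pt_leg3      = c(2.3,  0.2)    # calibration: rel leg III ~ 1.5
    )
  )
  river <- archetype_config(
    species = "Tetragnatha montana", n_webs = 25, n_locations = 5,
    frame_regime = "enclosed",
    targets = list(
      area_cm2     = c(251,  sem_to_sd(25,   25)),
      asymmetry    = c(-0.17, sem_to_sd(0.03, 25)),
      shape        = c(-0.06, sem_to_sd(0.03, 25)),
      spiral_turns = c(14.4, sem_to_sd(0.6,  25)),
      ceph_width   = c(1.72, sem_to_sd(0.04, 25)),
      total_length = c(8.81, sem_to_sd(0.16, 25)),
      pt_leg1      = c(10.3, 1.0),   # calibration: rel leg I ~ 6.0
      pt_leg3      = c(3.4,  0.35)   # calibration: rel leg III ~ 2.0
    )
  )
  list("Meta menardi" = cave, "Metellina mengei" = wood,
       "Tetragnatha montana" = river)
}
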