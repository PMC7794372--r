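# Independent oracles and small fixture builders shared across tests.

# Monte-Carlo rejection-sampling estimate of the area of the ellipse with
# axes d_h x d_v minus the central disc of diameter H. Independent of the
# closed-form estimator under test.
mc_ellipse_hub_area <- function(d_v, d_h, H, n = 1e6) {
  x <- runif(n, -d_h / 2, d_h / 2)
  y <- runif(n, -d_v / 2, d_v / 2)
  inside <- (x / (d_h / 2))^2 + (y / (d_v / 2))^2 <= 1 &
    x^2 + y^2 >= (H / 2)^2
  mean(inside) * d_h * d_v
}

# Closed-form one-way fixed-effects ANOVA F for the group factor.
oneway_anova_F <- function(y, group) {
  g <- split(y, group)
  k <- length(g)
  N <- length(y)
  gm <- mean(y)
  ssb <- sum(vapply(g, function(x) length(x) * (mean(x) - gm)^2, 0))
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), 0))
  (ssb / (k - 1)) / (ssw / (N - k))
}

# One valid measurement row with overridable fields.
measurement_row <- function(web_id = "w1", species = "sp", location = "loc1",
                            d_v_mm = 100, d_h_mm = 110, r_u_mm = 48,
                            r_r_mm = 56, H_mm = 10,
                            s_q1 = 6, s_q2 = 6, s_q3 = 6, s_q4 = 6,
                            n_radii = 18, n_frame = 15, n_mooring = 5) {
  data.frame(web_id = web_id, species = species, location = location,
             d_v_mm = d_v_mm, d_h_mm = d_h_mm, r_u_mm = r_u_mm,
             r_r_mm = r_r_mm, H_mm = H_mm, s_q1 = s_q1, s_q2 = s_q2,
             s_q3 = s_q3, s_q4 = s_q4, n_radii = n_radii,
             n_frame = n_frame, n_mooring = n_mooring,
             stringsAsFactors = FALSE)
}

morphology_row <- function(spider_id = "s1", web_id = "w1", species = "sp",
                           location = "loc1", total_length_mm = 8,
                           ceph_width_mm = 2, pt_leg1_mm = 7,
                           pt_leg3_mm = 4) {
  data.frame(spider_id = spider_id, web_id = web_id, species = species,
             location = location, total_length_mm = total_length_mm,
             ceph_width_mm = ceph_width_mm, pt_leg1_mm = pt_leg1_mm,
             pt_leg3_mm = pt_leg3_mm, stringsAsFactors = FALSE)
}

# Balanced 3-species dataset whose location variance is exactly zero
# (each species block duplicated across its two locations), for the
# ANOVA-limit equivalence check.
zero_location_variance_data <- function(seed = 7, per_species = 6,
                                        means = c(0, 1, 2)) {
  withr::with_seed(seed, {
    base <- data.frame(
      species = rep(c("A", "B", "C"), each = per_species),
      y = rnorm(3 * per_species, rep(means, each = per_species))
    )
    rbind(transform(base, location = paste0(species, "1")),
          transform(base, location = paste0(species, "2")))
  })
}

# Archetype with all target SDs forced to a constant (default 0) --
# degenerate noiseless generator for exactness checks.
flat_archetype <- function(sd = 0, asymmetry_mean = 0) {
  archetype_config(
    species = "flat", n_webs = 10, n_locations = 2,
    frame_regime = "enclosed",
    targets = list(area_cm2 = c(100, sd), asymmetry = c(asymmetry_mean, sd),
                   shape = c(0, sd), spiral_turns = c(8, sd),
                   ceph_width = c(2, sd), total_length = c(8, sd),
                   pt_leg1 = c(7, sd), pt_leg3 = c(4, sd)),
    location_sd = if (sd == 0) 0 else 0.3
  )
}

quiet_fit <- function(...) {
  suppressMessages(suppressWarnings(fit_lmm(...)))
}
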