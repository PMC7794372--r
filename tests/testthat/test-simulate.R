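test_that("generation is deterministic in the seed and leaves the RNG alone", {
  cave <- default_archetypes()[["Meta menardi"]]
  a <- sample_webs(cave, seed = 5)
  b <- sample_webs(cave, seed = 5)
  c <- sample_webs(cave, seed = 6)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$d_v_mm, c$d_v_mm)))

  set.seed(123); before <- runif(3)
  set.seed(123); invisible(sample_webs(cave, seed = 1)); after <- runif(3)
  expect_identical(before, after)  # caller's RNG stream untouched

  s1 <- sample_morphology(cave, seed = 5)
  s2 <- sample_morphology(cave, seed = 5)
  expect_identical(s1, s2)
})

test_that("recomputed metrics reproduce each web's drawn targets (round trip)", {
  for (cfg in default_archetypes()) {
    webs <- sample_webs(cfg, n = 200, seed = 11)
    tg <- attr(webs, "targets")
    m <- web_metrics(webs)
    expect_equal(m$area_cm2, tg$area_cm2, tolerance = 1e-6)
    expect_equal(m$asymmetry, tg$asymmetry, tolerance = 1e-6)
    expect_equal(m$shape, tg$shape, tolerance = 1e-6)
    # spiral counts are integers: per-web quadrant means sit within the
    # rounding jitter of the drawn target, unbiased across webs
    expect_lt(max(abs(m$spiral_turns - tg$spiral_turns)), 2)
    expect_lt(abs(mean(m$spiral_turns - tg$spiral_turns)), 0.15)
  }
})

test_that("noiseless archetype collapses to exact configured values", {
  flat <- flat_archetype(sd = 0, asymmetry_mean = 0)
  webs <- sample_webs(flat, seed = 2)
  rad <- derive_radii(webs$d_v_mm, webs$r_u_mm, webs$d_h_mm, webs$r_r_mm)
  expect_equal(webs$r_u_mm, rad$r_l)  # asymmetry 0 => r_u = r_l exactly
  m <- web_metrics(webs)
  expect_equal(m$area_cm2, rep(100, nrow(webs)))
  expect_equal(m$shape, rep(0, nrow(webs)))

  sp <- sample_morphology(flat, seed = 2)
  expect_equal(unique(sp$ceph_width_mm), 2)
  expect_equal(unique(sp$total_length_mm), 8)
  expect_equal(unique(sp$pt_leg1_mm), 7)
})

test_that("every generated record satisfies the physical invariants", {
  for (seed in c(1, 202, 4040)) {
    for (cfg in default_archetypes()) {
      webs <- sample_webs(cfg, n = 400, seed = seed)
      expect_equal(nrow(validate_measurements(webs)), 0)
      expect_true(all(webs$s_q1 >= 2 & webs$s_q2 >= 2 &
                        webs$s_q3 >= 2 & webs$s_q4 >= 2))
      sp <- sample_morphology(cfg, n = 400, seed = seed + 1)
      expect_equal(nrow(validate_morphology(sp)), 0)
    }
  }
})

test_that("generated means recover the configured targets", {
  # 3-SEM bound: at a fixed seed, a 2-SEM band would falsely trip on ~1 of
  # every 20 metrics checked; 3 SEM keeps the per-metric false-alarm rate
  # below 0.3% while still catching any real calibration bias
  cfg <- default_archetypes()[["Metellina mengei"]]
  n <- 1000
  m <- web_metrics(sample_webs(cfg, n = n, seed = 8))
  for (metric in c("area_cm2", "asymmetry", "shape", "spiral_turns")) {
    tgt <- cfg$targets[[metric]][["mean"]]
    sem <- sd(m[[metric]]) / sqrt(n)
    expect_lt(abs(mean(m[[metric]]) - tgt), 3 * sem,
              label = paste("mean deviation for", metric))
  }
  sp <- sample_morphology(cfg, n = n, seed = 9)
  for (v in c("total_length_mm", "ceph_width_mm", "pt_leg1_mm",
              "pt_leg3_mm")) {
    tgt <- cfg$targets[[sub("_mm$", "", v)]][["mean"]]
    sem <- sd(sp[[v]]) / sqrt(n)
    expect_lt(abs(mean(sp[[v]]) - tgt), 3 * sem,
              label = paste("mean deviation for", v))
  }
})

test_that("structural regimes produce the cave-vs-surface signature", {
  cave <- default_archetypes()[["Meta menardi"]]
  webs <- sample_webs(cave, n = 500, seed = 13)
  expect_gte(mean(webs$n_frame == 0), 0.9)
  expect_gt(cor(webs$n_radii, webs$n_mooring), 0.9)
  expect_true(all(webs$n_mooring >= webs$n_radii))

  surf <- sample_webs(default_archetypes()[["Tetragnatha montana"]],
                      n = 500, seed = 13)
  expect_true(all(surf$n_mooring >= 3 & surf$n_mooring <= 7))
  expect_true(all(surf$n_frame >= 1))
  expect_lt(cor(surf$n_radii, surf$n_mooring), 0.3)
})

test_that("make_study joins species with nested locations and paired spiders", {
  study <- make_study(seed = 1)
  expect_s3_class(study, "orb_study")
  expect_equal(nrow(study$webs), 19 + 29 + 25)
  expect_equal(nrow(study$morphology), 73)
  # one resident spider per web
  expect_setequal(study$morphology$web_id, study$webs$web_id)
  # every location belongs to exactly one species
  nest <- unique(study$webs[, c("species", "location")])
  expect_equal(anyDuplicated(nest$location), 0)
  # paired spider shares the web's location
  j <- merge(study$webs[, c("web_id", "location")],
             study$morphology[, c("web_id", "location")], by = "web_id")
  expect_equal(j$location.x, j$location.y)
  expect_output(print(study), "73 webs")

  empty <- make_study(configs = list(), seed = 1)
  expect_equal(nrow(empty$webs), 0)
  expect_equal(nrow(empty$morphology), 0)
})

test_that("infeasible configurations fail loudly", {
  tg <- flat_archetype(sd = 1)$targets
  tg$asymmetry <- c(0.95, 0.1)  # mean outside physical bounds
  cfg <- archetype_config("bad", 10, 2, targets = tg)
  expect_error(sample_webs(cfg, seed = 1), "outside its physical bounds")
})
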