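test_that("derived radii follow by subtraction and reject impossible geometry", {
  r <- derive_radii(d_v = 20, r_u = 8, d_h = 16, r_r = 8)
  expect_equal(r$r_l, 12)
  expect_equal(r$r_le, 8)

  sym <- derive_radii(d_v = 20, r_u = 10, d_h = 20, r_r = 10)
  expect_equal(sym$r_l, 10)   # symmetric web: radius = half diameter
  expect_equal(sym$r_le, 10)

  expect_error(derive_radii(d_v = 10, r_u = 12, d_h = 10, r_r = 5),
               "r_u >= d_v")
  expect_error(derive_radii(d_v = 10, r_u = 5, d_h = 10, r_r = 11),
               "r_r >= d_h")
})

test_that("Ellipse-Hub area matches hand-evaluated cases and rejects oversized hubs", {
  expect_equal(ellipse_hub_area(2, 2, 0), pi)          # unit circle, no hub
  expect_equal(ellipse_hub_area(20, 10, 2), 49 * pi)   # 10*5*pi - 1*pi
  expect_error(ellipse_hub_area(20, 10, 10), "H must be smaller")
  expect_error(ellipse_hub_area(-5, 10, 1), "strictly positive")
})

test_that("Ellipse-Hub area agrees with the Monte-Carlo oracle on a spot case", {
  withr::with_seed(11, {
    mc <- mc_ellipse_hub_area(20, 10, 2, n = 1e6)
  })
  expect_equal(ellipse_hub_area(20, 10, 2), mc, tolerance = 1e-2)
})

test_that("asymmetry index: sign, bounds and degenerate input", {
  expect_identical(web_asymmetry(5, 5), 0)   # vertically symmetric web
  expect_equal(web_asymmetry(1, 3), -0.5)    # hub above centre -> negative
  expect_equal(web_asymmetry(5, 0), 1)       # upper bound
  expect_error(web_asymmetry(0, 0), "both radii are zero")
  expect_error(web_asymmetry(-1, 2), "non-negative")
})

test_that("shape index: sign, antisymmetry and validation", {
  expect_identical(web_shape(10, 10), 0)     # circular web
  expect_equal(web_shape(10, 30), -0.5)      # taller than wide -> negative
  expect_error(web_shape(0, 10), "strictly positive")
  withr::with_seed(3, {
    a <- runif(200, 1, 500)
    b <- runif(200, 1, 500)
  })
  expect_equal(web_shape(a, b), -web_shape(b, a))
  expect_true(all(abs(web_shape(a, b)) < 1))
  expect_true(all(abs(web_asymmetry(a, b)) <= 1))
})

test_that("mean mesh height: regular-web closed form, quadrant pairing, errors", {
  expect_equal(mean_mesh_height(10, 10, 10, 10, H = 2,
                                s_q1 = 4, s_q2 = 4, s_q3 = 4, s_q4 = 4), 3)
  # a single inter-loop gap spans the whole quadrant annulus
  expect_equal(mean_mesh_height(10, 10, 10, 10, H = 2,
                                s_q1 = 2, s_q2 = 2, s_q3 = 2, s_q4 = 2), 9)
  # regular web equals (r - H/2) / (s - 1) for random r, H, s
  withr::with_seed(5, {
    for (i in 1:25) {
      r <- runif(1, 5, 80)
      H <- runif(1, 0.5, r)  # H/2 < r
      s <- sample(2:20, 1)
      expect_equal(mean_mesh_height(r, r, r, r, H, s, s, s, s),
                   (r - H / 2) / (s - 1))
    }
  })
  # quadrant-to-radius pairing: Q1<->r_u, Q3<->r_l, Q2<->r_r, Q4<->r_le
  got <- mean_mesh_height(r_u = 9, r_l = 5, r_r = 7, r_le = 3, H = 2,
                          s_q1 = 5, s_q2 = 3, s_q3 = 2, s_q4 = 4)
  expect_equal(got, ((9 - 1) / 4 + (5 - 1) / 1 + (7 - 1) / 2 + (3 - 1) / 3) / 4)

  expect_error(mean_mesh_height(10, 10, 10, 10, 2, 1, 4, 4, 4),
               "at least 2 spiral")
  expect_error(mean_mesh_height(1, 10, 10, 10, 4, 4, 4, 4, 4),
               "exceed the hub radius")
})

test_that("metrics are scale-covariant in the web dimensions", {
  withr::with_seed(9, {
    for (i in 1:20) {
      d_v <- runif(1, 40, 200)
      d_h <- runif(1, 40, 200)
      H <- runif(1, 1, 0.4 * min(d_v, d_h))
      r_u <- runif(1, 0.3, 0.7) * d_v
      r_r <- runif(1, 0.3, 0.7) * d_h
      cw <- runif(1, 1, 3)
      k <- runif(1, 0.5, 4)
      s <- sample(3:12, 4, replace = TRUE)
      rl <- derive_radii(d_v, r_u, d_h, r_r)

      expect_equal(ellipse_hub_area(k * d_v, k * d_h, k * H),
                   k^2 * ellipse_hub_area(d_v, d_h, H))
      expect_equal(web_asymmetry(k * r_u, k * rl$r_l),
                   web_asymmetry(r_u, rl$r_l))
      expect_equal(web_shape(k * d_h, k * d_v), web_shape(d_h, d_v))
      expect_equal(
        mean_mesh_height(k * r_u, k * rl$r_l, k * r_r, k * rl$r_le, k * H,
                         s[1], s[2], s[3], s[4]),
        k * mean_mesh_height(r_u, rl$r_l, r_r, rl$r_le, H,
                             s[1], s[2], s[3], s[4]))
      # relative metrics invariant when cw scales with the web
      a <- ellipse_hub_area(d_v, d_h, H)
      expect_equal(relative_metric(k^2 * a, k * cw, power = 2),
                   relative_metric(a, cw, power = 2))
    }
  })
})

test_that("relative metrics divide by cephalothorax width at the right power", {
  expect_equal(relative_metric(100, 1, power = 2), 100)
  expect_equal(relative_metric(100, 2, power = 2), 25)
  expect_equal(relative_metric(3, 2), 1.5)
  expect_error(relative_metric(3, 0), "must be positive")
})

test_that("web_metrics appends documented columns and flags undefined mesh", {
  webs <- rbind(measurement_row("w1"),
                measurement_row("w2", s_q1 = 1),   # mesh undefined
                measurement_row("w3", s_q3 = 0))   # mesh undefined
  m <- web_metrics(webs)
  expect_true(all(c("area_cm2", "asymmetry", "shape", "mesh_mm",
                    "spiral_turns") %in% names(m)))
  expect_false(is.na(m$mesh_mm[1]))
  expect_true(all(is.na(m$mesh_mm[2:3])))      # flagged missing, not dropped
  expect_equal(nrow(m), 3)
  expect_equal(m$area_cm2[1], ellipse_hub_area(100, 110, 10) / 100)

  morph <- morphology_row(web_id = "w1")
  mm <- web_metrics(webs[1, ], morph)
  expect_equal(mm$rel_area, ellipse_hub_area(100, 110, 10) / 2^2)
  expect_equal(mm$rel_leg1, 7 / 2)
  expect_equal(mm$rel_mesh, mm$mesh_mm / 2)
})
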