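test_that("saturation vapor pressure matches hand-evaluated values and is increasing", {
  expect_equal(svp(0), 6.11)
  # 6.11 * exp(17.27 * 25 / 298.3) and 6.11 * exp(17.27 * -10 / 263.3)
  expect_equal(svp(25), 25.97917, tolerance = 1e-6)
  expect_equal(svp(-10), 3.170917, tolerance = 1e-6)
  ta <- seq(-40, 45, by = 0.5)
  expect_true(all(diff(svp(ta)) > 0))
  expect_error(svp(NA_real_), "finite")
})

test_that("the two VPD formulations agree and behave at the boundaries", {
  expect_equal(vpd_from_rh(13.7, 100), 0)
  expect_equal(vpd_from_rh(0, 50), 3.055)
  ta <- rep(seq(-20, 30, length.out = 100), each = 100)
  rh <- rep(seq(0, 100, length.out = 100), times = 100)
  expect_equal(vpd_from_rh(ta, rh),
               as.numeric(vpd_from_avp(ta, svp(ta) * rh / 100)),
               tolerance = 1e-12)
  # decreasing in rh at fixed ta
  expect_true(all(diff(vpd_from_rh(rep(10, 50), seq(0, 100, length.out = 50))) < 0))
  expect_error(vpd_from_rh(10, 101), "\\[0, 100\\]")
  expect_error(vpd_from_rh(10, -1), "\\[0, 100\\]")
})

test_that("VPD from actual vapor pressure flags but keeps supersaturation", {
  expect_equal(as.numeric(vpd_from_avp(25, svp(25))), 0)
  expect_equal(as.numeric(vpd_from_avp(25, 10)), svp(25) - 10)
  expect_equal(as.numeric(vpd_from_avp(12, 0)), svp(12))
  over <- vpd_from_avp(10, svp(10) + 1)
  expect_lt(as.numeric(over), 0)
  expect_equal(attr(over, "n_negative"), 1L)
  clipped <- vpd_from_avp(10, svp(10) + 1, clip_negative = TRUE)
  expect_equal(as.numeric(clipped), 0)
  expect_error(vpd_from_avp(10, -0.1), "non-negative")
})

test_that("aerodynamic resistance matches hand evaluation and its scaling law", {
  # ws*k^2 / ln(exp(4) - 0.7)^2 = 0.48 / 15.8957...
  expect_equal(aerodynamic_resistance(3, 0.3),
               3 * 0.16 / log(exp(4) - 0.7)^2, tolerance = 1e-12)
  expect_equal(aerodynamic_resistance(3, 0.3), 0.0302, tolerance = 1e-3)
  # scaling ws and u_star together multiplies the numerator only
  expect_equal(aerodynamic_resistance(12, 1.2),
               4 * aerodynamic_resistance(3, 0.3), tolerance = 1e-12)
  # exp(k*ws/u_star) near 1.7 puts the log through zero
  expect_error(aerodynamic_resistance(0.5, 0.4), "degenerate")
})

test_that("Penman-Monteith inversion recovers the forward conductance", {
  d <- random_pm_draw(1000, seed = 101)
  pm <- penman_monteith_le(d$gc, d$a_energy, d$vpd, d$ws, d$u_star, d$ta)
  gc_hat <- canopy_conductance(pm$le, pm$h, d$vpd, d$ws, d$u_star, d$ta)
  expect_true(all(is.finite(gc_hat)))
  expect_lt(max(abs(gc_hat - d$gc) / d$gc), 1e-10)
  expect_equal(attr(gc_hat, "n_rejected"), 0L)
})

test_that("conductance inversion algebra: vanishing first bracket and VPD monotonicity", {
  cs <- phys_constants(15)
  le <- 120; vpd <- 8; ws <- 3; u_star <- 0.3
  h <- le * cs$gamma / cs$delta  # makes Delta/gamma * H/LE = 1
  gc <- canopy_conductance(le, h, vpd, ws, u_star, 15)
  expect_equal(as.numeric(gc),
               1000 * cs$gamma * le / (cs$rho * cs$cp * vpd * 100),
               tolerance = 1e-12)
  gc2 <- canopy_conductance(le, h, 2 * vpd, ws, u_star, 15)
  expect_lt(as.numeric(gc2), as.numeric(gc))
})

test_that("non-physical inverted conductances are masked and counted, not clipped", {
  # strongly negative H with small VPD term drives the bracket negative
  gc <- canopy_conductance(le = c(50, 120), h = c(-4000, 60), vpd = c(0.05, 8),
                           ws = 3, u_star = 0.3, ta = 15)
  expect_true(is.na(gc[1]))
  expect_false(is.na(gc[2]))
  expect_equal(attr(gc, "n_rejected"), 1L)
})

test_that("latent heat to water flux conversion is linear with the MJ default", {
  expect_equal(et_from_le(0), 0)
  expect_equal(et_from_le(244), 1e-4)
  le <- c(10, 100, 250)
  expect_equal(et_from_le(3 * le), 3 * et_from_le(le))
  expect_equal(et_from_le(244, coeff_scale = "J"), 100)
})

test_that("underlying water-use efficiency: worked values, scale property, unit guard", {
  expect_equal(uwue(2, 1, 1), 2)
  expect_equal(uwue(3, 0.25, 1.5), 1.0)
  expect_equal(uwue(5, 0, 2), 0)
  expect_true(is.na(uwue(5, 1, 0)))
  # uwue(a*gpp, vpd, a*et) == uwue(gpp, vpd, et)
  expect_equal(uwue(7 * 2.3, 0.8, 7 * 1.1), uwue(2.3, 0.8, 1.1))
  expect_error(uwue(2, 10, 1, vpd_unit = "hPa"), "kPa")
})

test_that("growing-season mask uses a strict zero threshold and a climatology mode", {
  expect_equal(growing_season_mask(c(-5, 0, 1)), c(FALSE, FALSE, TRUE))
  expect_true(all(growing_season_mask(runif(12, 1, 20))))
  # climatology: per calendar month multi-year means, vs per-month brute force
  set.seed(11)
  ta <- as.vector(vapply(1:5, function(y) {
    -8 + 16 * sin(2 * pi * (1:12 - 4) / 12) + rnorm(12, 0, 2)
  }, numeric(12)))
  mask <- growing_season_mask(ta, climatology = TRUE)
  brute <- sapply(1:12, function(m) mean(ta[seq(m, 60, by = 12)]) > 0)
  expect_equal(mask, rep(brute, 5))
  expect_error(growing_season_mask(ta[1:13], climatology = TRUE), "whole years")
})
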