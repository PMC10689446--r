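test_that("paired warming test handles identical, shifted and noisy treatments", {
  x <- c(10.2, 11.5, 9.8, 12.1, 10.9)
  same <- paired_warming_test(x, x)
  expect_true(same$degenerate)
  expect_equal(same$mean_diff, 0)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # constant shift with zero noise: infinite t, flagged not computed
  shift <- paired_warming_test(x, x + 2)
  expect_true(shift$degenerate)
  expect_equal(shift$mean_diff, 2)
  expect_true(is.na(shift$t))
  # simulated warming: t equals the textbook closed form
  set.seed(21)
  ctl <- rnorm(30, 10, 2)
  wrm <- ctl + rnorm(30, 3.8, 1.0)
  res <- paired_warming_test(ctl, wrm)
  expect_equal(res$t, paired_t_closed_form(ctl, wrm), tolerance = 1e-12)
  expect_equal(res$df, 29)
  expect_lt(res$p, 1e-10)
  expect_gt(res$shapiro_p, 0.05)
  expect_true(is.na(res$wilcoxon_p))
  expect_error(paired_warming_test(1:2, 3:4), ">= 3")
})

test_that("non-normal differences trigger the signed-rank fallback", {
  set.seed(22)
  ctl <- rnorm(40, 10, 1)
  wrm <- ctl + rexp(40, rate = 0.5)^2   # strongly skewed differences
  res <- paired_warming_test(ctl, wrm)
  expect_lte(res$shapiro_p, 0.05)
  expect_false(is.na(res$wilcoxon_p))
  expect_equal(res$wilcoxon_p,
               suppressWarnings(wilcox.test(wrm, ctl, paired = TRUE))$p.value)
})

test_that("exponential temperature-VPD fit recovers noiseless and noisy laws", {
  ta <- seq(-5, 25, length.out = 60)
  fit <- fit_ta_vpd_exponential(ta, 2 * exp(0.06 * ta))
  expect_equal(fit$a, 2, tolerance = 1e-10)
  expect_equal(fit$b, 0.06, tolerance = 1e-10)
  expect_equal(fit$r, 1, tolerance = 1e-10)
  # lognormal noise: recovery within 2 standard errors of the log-linear fit
  set.seed(23)
  ta2 <- runif(200, -5, 25)
  vpd2 <- 6 * exp(0.07 * ta2) * exp(rnorm(200, 0, 0.1))
  fit2 <- fit_ta_vpd_exponential(ta2, vpd2)
  se_b <- summary(lm(log(vpd2) ~ ta2))$coefficients[2, 2]
  expect_lt(abs(fit2$b - 0.07), 2 * se_b)
  expect_gt(fit2$r, 0.9)
  # OLS sign property and non-positive-VPD filtering
  expect_gt(fit_ta_vpd_exponential(ta2, vpd2)$b, 0)
  fit3 <- fit_ta_vpd_exponential(c(ta2, 0), c(vpd2, -1))
  expect_equal(fit3$n_dropped, 1L)
})

test_that("simulated VPD contrasts follow the fitted exponential law", {
  fit <- list(a = 2, b = 0.06)
  expect_equal(simulate_vpd_delta(fit, 12, 12), 0)
  expect_equal(simulate_vpd_delta(fit, 10, 13), 2 * (exp(0.78) - exp(0.6)),
               tolerance = 1e-12)
  expect_equal(simulate_vpd_delta(fit, 10, 13), 0.71871, tolerance = 1e-4)
  d <- simulate_vpd_delta(fit, 10, c(11, 12, 13, 14))
  expect_true(all(diff(d) > 0))
  # composed with a noiseless fit, the generator's contrast is reproduced
  ta <- seq(0, 20, length.out = 30)
  f <- fit_ta_vpd_exponential(ta, 3 * exp(0.05 * ta))
  expect_equal(simulate_vpd_delta(f, 8, 11), 3 * (exp(0.55) - exp(0.4)),
               tolerance = 1e-8)
})

test_that("growth-response regression: exact slopes, nulls and the OLS oracle", {
  dvpd <- seq(0.2, 3, length.out = 20)
  exact <- suppressWarnings(vpd_effect_regression(-0.5 * dvpd, dvpd))
  expect_equal(exact$slope, -0.5, tolerance = 1e-12)
  expect_lt(exact$p, 1e-12)
  set.seed(24)
  resp <- rnorm(500); dv <- rnorm(500, 1, 0.3)
  null <- vpd_effect_regression(resp, dv)
  expect_lt(abs(null$slope), 2 * null$se)
  ne <- ols_normal_equations(resp, dv)
  expect_equal(null$slope, unname(ne["beta1"]), tolerance = 1e-12)
  expect_true(null$ci_lower < null$slope && null$slope < null$ci_upper)
  expect_error(vpd_effect_regression(resp, rep(1, 500)), "singular")
})

test_that("growth response modes and RH/VPD conventions in the synthesis table", {
  expect_equal(growth_response(100, 150), log(1.5))
  expect_equal(growth_response(100, 150, mode = "ratio"), 1.5)
  expect_equal(growth_response(100, 150, mode = "difference"), 50)
  expect_error(growth_response(-1, 2), "positive")
  # VPD-reporting sites pass through; RH-reporting sites go through the
  # deficit formula; bare-Ta sites need the fitted law
  sites <- data.frame(
    ta_c = c(10, 10, 10), ta_w = c(13, 13, 13),
    vpd_c = c(4, NA, NA), vpd_w = c(5.5, NA, NA),
    rh_c = c(NA, 70, NA), rh_w = c(NA, 68, NA)
  )
  fit <- list(a = 2, b = 0.06)
  d <- synthesis_vpd_delta(sites, fit = fit)
  expect_equal(d[1], 1.5)
  expect_equal(d[2], vpd_from_rh(13, 68) - vpd_from_rh(10, 70))
  expect_equal(d[3], simulate_vpd_delta(fit, 10, 13))
  expect_error(synthesis_vpd_delta(sites[3, ]), "law")
})

test_that("the warming-site generator plants a recoverable effect slope", {
  g <- gen_warming_sites(seed = 31)
  g2 <- gen_warming_sites(seed = 31)
  expect_identical(g$sites, g2$sites)   # fixed-seed determinism
  # planted negative slope recovered within 2 se at low noise
  gp <- gen_warming_sites(effect_slope = -0.5, noise_sd = 0.1, seed = 32)
  reg <- vpd_effect_regression(
    growth_response(gp$sites$growth_c, gp$sites$growth_w),
    synthesis_vpd_delta(gp$sites))
  expect_lt(abs(reg$slope - (-0.5)), 2 * reg$se)
  # generated humidities are physical
  expect_true(all(gp$sites$rh_c > 0 & gp$sites$rh_c <= 100))
})
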