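test_that("OLS trend matches exact lines and the normal-equation oracle", {
  t <- 1982:2018
  tr <- ols_trend(2 * t + 5, t)
  expect_equal(tr$beta1, 2, tolerance = 1e-12)
  expect_equal(tr$beta0, 5, tolerance = 1e-9)
  expect_equal(tr$adj_r2, 1, tolerance = 1e-12)
  flat <- ols_trend(rep(3.2, 10))
  expect_equal(flat$beta1, 0, tolerance = 1e-12)
  expect_lte(flat$adj_r2, 0)
  set.seed(3)
  y <- rnorm(37)
  ne <- ols_normal_equations(y, t)
  tr2 <- ols_trend(y, t)
  expect_equal(tr2$beta1, unname(ne["beta1"]), tolerance = 1e-12)
  expect_equal(tr2$beta0, unname(ne["beta0"]), tolerance = 1e-12)
  expect_error(ols_trend(y, rep(2000, 37)), "singular")
})

test_that("detrending zeroes lines, centers residuals, and is idempotent", {
  t <- 1:30
  expect_equal(max(abs(detrend_series(3 * t + 1, t))), 0, tolerance = 1e-10)
  set.seed(4)
  y <- cumsum(rnorm(30))
  d <- detrend_series(y, t)
  expect_equal(mean(d), 0, tolerance = 1e-12)
  expect_equal(unname(detrend_series(d, t)), unname(d), tolerance = 1e-10)
  # independent implementation: pracma's linear detrend
  expect_equal(unname(d), as.numeric(pracma::detrend(y, tt = "linear")),
               tolerance = 1e-8)
})

test_that("partial correlation equals the two-stage residual-regression oracle", {
  set.seed(5)
  for (k in 1:25) {
    n <- sample(10:50, 1)
    g <- sample(0:4, 1)
    if (n - 2 - g < 2) g <- 0
    y <- rnorm(n); x <- rnorm(n)
    z <- replicate(g, rnorm(n), simplify = FALSE)
    pc <- partial_correlation(y, x, z)
    expect_equal(pc$r, pcor_residual_oracle(y, x, z), tolerance = 1e-12)
    expect_equal(pc$df, n - 2 - g)
    # p from the two-sided t transform of r
    tt <- pc$r * sqrt(pc$df / (1 - pc$r^2))
    expect_equal(pc$p_value, 2 * pt(abs(tt), pc$df, lower.tail = FALSE))
  }
})

test_that("partial correlation washes out a shared covariate signal", {
  set.seed(6)
  n <- 1e4
  z <- rnorm(n)
  y <- z + rnorm(n)
  x <- z + rnorm(n)
  expect_gt(cor(y, x), 0.4)                    # raw correlation is strong
  pc <- partial_correlation(y, x, list(z))
  expect_lt(abs(pc$r), 0.1)                    # conditional correlation ~ 0
  expect_error(partial_correlation(rnorm(20), rnorm(20),
                                   list(z = 1:20, z2 = 2 * (1:20))),
               "rank|collinear")
})

test_that("a single-pixel map reduces to partial_correlation, with detrending", {
  set.seed(7)
  n <- 37
  t <- 1982:2018
  mk <- function(v) grid_cube(array(v, c(n, 1, 1)), t, 60, 100)
  y <- 0.5 * t + rnorm(n); x <- -0.2 * t + rnorm(n)
  z1 <- rnorm(n); z2 <- rnorm(n)
  m <- pcor_map(mk(y), mk(x), list(mk(z1), mk(z2)))
  ref <- partial_correlation(detrend_series(y, t), detrend_series(x, t),
                             list(detrend_series(z1, t), detrend_series(z2, t)))
  expect_equal(m$r[1, 1], ref$r, tolerance = 1e-12)
  expect_equal(m$p_value[1, 1], ref$p_value, tolerance = 1e-12)
  # misaligned grids are rejected
  bad <- grid_cube(array(x, c(n, 1, 1)), t, 61, 100)
  expect_error(pcor_map(mk(y), bad, list()), "aligned")
})

test_that("skipping detrending on co-trending series inflates the correlation", {
  set.seed(8)
  t <- 1982:2018
  n <- length(t)
  infl <- detr <- numeric(40)
  for (k in 1:40) {
    y <- 0.8 * t + rnorm(n, 0, 3)   # strong shared trend, independent noise
    x <- 0.8 * t + rnorm(n, 0, 3)
    detr[k] <- partial_correlation(detrend_series(y, t), detrend_series(x, t))$r
    infl[k] <- partial_correlation(y, x)$r
  }
  expect_gt(mean(infl), 0.7)
  expect_lt(abs(mean(detr)), 0.15)
})

test_that("region summary partitions pixels by sign and significance", {
  mk_map <- function(r, p) {
    structure(list(r = r, p_value = p, lat = seq_len(nrow(r)),
                   lon = seq_len(ncol(r)), g = 4), class = "pcor_map")
  }
  all_pos <- mk_map(matrix(0.5, 2, 2), matrix(0.01, 2, 2))
  s <- region_summary(all_pos)
  expect_equal(s$pct_sig_pos, 100)
  expect_equal(s$pct_sig_neg + s$pct_neg + s$pct_pos, 0)
  # hand-built 4-pixel enumeration: sig-neg, neg, pos, sig-pos
  m <- mk_map(matrix(c(-0.6, -0.1, 0.1, 0.6), 2, 2),
              matrix(c(0.01, 0.5, 0.5, 0.01), 2, 2))
  s2 <- region_summary(m)
  expect_equal(c(s2$pct_sig_neg, s2$pct_neg, s2$pct_pos, s2$pct_sig_pos),
               c(25, 25, 25, 25))
  expect_equal(s2$mean_r, 0)
  expect_equal(s2$pct_sig_neg + s2$pct_neg + s2$pct_sig_pos + s2$pct_pos, 100,
               tolerance = 1e-9)
  # r exactly 0 counts as positive
  s3 <- region_summary(mk_map(matrix(0, 1, 1), matrix(1, 1, 1)))
  expect_equal(s3$pct_pos, 100)
  expect_error(region_summary(m, mask = matrix(FALSE, 2, 2)), "empty region")
})

test_that("extent gradient bins pixels left-closed with a terminal closed bin", {
  r <- matrix(c(-0.5, -0.2, 0.1, 0.3, 0.6, 0.9), 2, 3)
  p <- matrix(c(0.01, 0.5, 0.5, 0.01, 0.01, 0.01), 2, 3)
  rmap <- structure(list(r = r, p_value = p, lat = 1:2, lon = 1:3, g = 4),
                    class = "pcor_map")
  extent <- matrix(c(5, 10, 20, 35, 70, 100), 2, 3)
  g <- extent_gradient(rmap, extent)
  # enumeration: 5 -> excluded; 10 -> [10,20); 20 -> [20,30); 35 -> [30,40);
  # 70 and 100 -> [70,100]; union >=10 has 5 pixels
  expect_equal(g$label, c("[10,20)", "[20,30)", "[30,40)", "[70,100]", ">=10"))
  expect_equal(g$n_pixels, c(1, 1, 1, 2, 5))
  expect_equal(g$mean_r[1], -0.2)
  expect_equal(g$mean_r[4], mean(c(0.6, 0.9)))
  expect_equal(g$mean_r[5], mean(c(-0.2, 0.1, 0.3, 0.6, 0.9)))
  uni <- extent_gradient(rmap, matrix(50, 2, 3))
  expect_equal(uni$label, c("[50,60)", ">=10"))
  expect_error(extent_gradient(rmap, matrix(120, 2, 3)), "percentage")
})

test_that("aridity split: 0.65 is humid, the masks partition valid pixels", {
  ai <- matrix(c(0.64999, 0.65, 0.1, 2, NA, 0.7), 2, 3)
  s <- aridity_split(ai)
  expect_false(s$humid_mask[1, 1])
  expect_true(s$nonhumid_mask[1, 1])
  expect_true(s$humid_mask[2, 1])
  expect_false(any(s$humid_mask & s$nonhumid_mask))
  expect_equal(s$humid_mask | s$nonhumid_mask, !is.na(ai))
  expect_error(aridity_split(matrix(-0.2, 1, 1)), ">= 0")
})

test_that("tower/grid agreement counts matched signs and correlates coefficients", {
  r <- c(-0.4, 0.2, 0.5, -0.1)
  same <- tower_grid_agreement(r, r)
  expect_equal(same$sign_agreement_pct, 100)
  expect_equal(same$r, 1)
  expect_equal(tower_grid_agreement(r, -r)$sign_agreement_pct, 0)
  set.seed(9)
  a <- rnorm(50, 0, 0.3); b <- a + rnorm(50, 0, 0.2)
  ag <- tower_grid_agreement(a, b)
  expect_equal(ag$sign_agreement_pct, 100 * mean(sign(a) == sign(b)))
  expect_equal(ag$r, cor(a, b))
  expect_error(tower_grid_agreement(a, b[-1]), "length")
})

test_that("grid cubes round-trip through the CSV writer and normalize latitude", {
  set.seed(10)
  vals <- array(rnorm(5 * 3 * 4), c(5, 3, 4))
  vm <- matrix(c(TRUE, FALSE), 3, 4)
  cube <- grid_cube(vals, 2001:2005, c(50, 55, 60), c(10, 20, 30, 40),
                    units = "hPa", valid_mask = vm)
  path <- tempfile(fileext = ".csv")
  write_grid_cube(cube, path)
  back <- read_grid_cube(path)
  expect_identical(back$valid_mask, cube$valid_mask)
  expect_equal(back$values, cube$values, tolerance = 1e-12)
  expect_equal(back$units, "hPa")
  # descending latitude is flipped to ascending with data reordered
  desc <- grid_cube(vals, 2001:2005, c(60, 55, 50), c(10, 20, 30, 40))
  expect_equal(desc$lat, c(50, 55, 60))
  expect_equal(desc$values[, 1, ], vals[, 3, ])
})
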