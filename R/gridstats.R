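#' Ordinary least-squares trend of a series over time
#'
#' Fits `y = beta0 + beta1 * t + e` by OLS and reports the slope (the linear
#' trend per unit of `t`, typically per year) with its standard error,
#' two-sided t-test p-value and adjusted R-squared.
#'
#' @param y Numeric response series (no missing values after masking).
#' @param t Time coordinate, same length; defaults to `seq_along(y)`.
#' @return List of class `trend_result`: `beta0`, `beta1`, `se_beta1`,
#'   `p_value`, `adj_r2`, `n`.
#' @export
ols_trend <- function(y, t = seq_along(y)) {
  if (length(y) != length(t)) stop("`y` and `t` lengths differ", call. = FALSE)
  if (length(y) < 3) stop("need n >= 3", call. = FALSE)
  if (anyNA(y) || anyNA(t)) stop("missing values; mask before fitting", call. = FALSE)
  if (stats::var(t) == 0) stop("singular design: constant `t`", call. = FALSE)
  n <- length(y)
  fit <- stats::lm.fit(cbind(1, t), y)
  b <- fit$coefficients
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  sxx <- sum((t - mean(t))^2)
  se1 <- sqrt(rss / (n - 2) / sxx)
  # degenerate exact fits: p collapses to 0 (true slope) or 1 (flat line)
  p <- if (se1 == 0) as.numeric(b[2] == 0)
       else 2 * stats::pt(abs(b[2] / se1), n - 2, lower.tail = FALSE)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  structure(
    list(beta0 = unname(b[1]), beta1 = unname(b[2]),
         se_beta1 = se1, p_value = p,
         adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2), n = n),
    class = "trend_result"
  )
}

#' Remove a linear time trend from a series
#'
#' Residuals of the OLS regression of `y` on `t`. The result has mean zero
#' (to machine precision) and is idempotent: detrending an already detrended
#' series returns it unchanged.
#'
#' @inheritParams ols_trend
#' @return Detrended series, same length as `y`.
#' @export
detrend_series <- function(y, t = seq_along(y)) {
  if (length(y) < 3) stop("need n >= 3", call. = FALSE)
  stats::residuals(stats::lm(y ~ t))
}

#' Partial correlation of two series given covariates
#'
#' The first-order machinery of the whole analysis: the Pearson correlation
#' between `y` and `x` after the linear effect of the covariates `z` (with
#' intercept) has been removed from both. Computed via the precision matrix
#' of `(y, x, z)`; algebraically identical to correlating the residuals of
#' the two regressions on `z`, which the test-suite checks against an
#' independent two-stage `lm()` oracle. Significance is a two-sided t-test
#' with `df = n - 2 - g` where `g` is the number of covariates.
#'
#' @param y,x Numeric series of equal length `n`.
#' @param z List of covariate series (possibly empty), or a numeric matrix
#'   with `n` rows. With no covariates the plain Pearson correlation is
#'   returned.
#' @return List of class `pcor_result`: `r`, `p_value`, `n`, `g`, `df`.
#' @export
partial_correlation <- function(y, x, z = list()) {
  if (is.matrix(z)) z <- lapply(seq_len(ncol(z)), function(j) z[, j])
  n <- length(y)
  if (length(x) != n || any(vapply(z, length, 1L) != n)) {
    stop("all series must share length", call. = FALSE)
  }
  g <- length(z)
  df <- n - 2 - g
  if (df < 1) stop("n - 2 - g must be >= 1", call. = FALSE)
  m <- cbind(y = y, x = x, do.call(cbind, z))
  cv <- stats::cov(m)
  # zero-variance y or x residuals make the partial correlation undefined
  pr <- tryCatch(solve(cv), error = function(e) {
    stop("rank-deficient covariance: collinear covariates", call. = FALSE)
  })
  denom <- pr[1, 1] * pr[2, 2]
  if (!is.finite(denom) || denom <= 0) {
    return(structure(list(r = NA_real_, p_value = NA_real_, n = n, g = g, df = df),
                     class = "pcor_result"))
  }
  r <- -pr[1, 2] / sqrt(denom)
  r <- max(-1, min(1, r))
  tt <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  structure(list(r = r, p_value = p, n = n, g = g, df = df),
            class = "pcor_result")
}

#' @export
print.pcor_result <- function(x, ...) {
  cat(sprintf("partial correlation r = %.4f (n = %d, g = %d covariates, df = %d, p = %.3g)\n",
              x$r, x$n, x$g, x$df, x$p_value))
  invisible(x)
}

#' Pixel-wise detrended partial correlation map
#'
#' For every valid pixel, detrends the response, the driver and each covariate
#' series, then computes the partial correlation of the detrended response and
#' driver conditional on the detrended covariates. This is the workhorse
#' behind maps of the VPD effect on GPP: `pcor_map(gpp, vpd, list(ta, rad,
#' ws, pr))` with annual growing-season aggregates gives one coefficient and
#' p-value per pixel. Pixels with fewer than `min_valid_frac` of time steps
#' present (or failing the shared validity masks) are returned as `NA`.
#' No multiple-testing correction is applied across pixels; maps report raw
#' p-values.
#'
#' @param response,driver `grid_cube`s on a shared grid (e.g. GPP and VPD).
#' @param covariates List of covariate `grid_cube`s (air temperature,
#'   radiation, wind speed, precipitation in the reference analysis).
#' @param min_valid_frac Minimum fraction of non-missing time steps a pixel
#'   needs (default 0.8).
#' @param detrend Detrend every series before correlating (default `TRUE`).
#' @return List of class `pcor_map` with matrices `r`, `p_value` (lat x lon),
#'   integer matrix `n_used`, and the grid coordinates.
#' @export
pcor_map <- function(response, driver, covariates, min_valid_frac = 0.8,
                     detrend = TRUE) {
  do.call(check_aligned, c(list(response, driver), covariates))
  d <- dim(response$values)
  nlat <- d[2]; nlon <- d[3]
  rmat <- matrix(NA_real_, nlat, nlon)
  pmat <- matrix(NA_real_, nlat, nlon)
  nmat <- matrix(0L, nlat, nlon)
  valid <- response$valid_mask & driver$valid_mask
  for (cb in covariates) valid <- valid & cb$valid_mask
  t_axis <- response$time_axis
  for (i in seq_len(nlat)) {
    for (j in seq_len(nlon)) {
      if (!valid[i, j]) next
      series <- cbind(response$values[, i, j], driver$values[, i, j],
                      vapply(covariates, function(cb) cb$values[, i, j],
                             numeric(d[1])))
      ok <- stats::complete.cases(series)
      if (sum(ok) < ceiling(min_valid_frac * d[1]) ||
          sum(ok) - 2 - length(covariates) < 1) next
      s <- series[ok, , drop = FALSE]
      tt <- t_axis[ok]
      if (detrend) s <- apply(s, 2, detrend_series, t = tt)
      pc <- partial_correlation(s[, 1], s[, 2],
                                lapply(seq_len(ncol(s) - 2) + 2,
                                       function(kk) s[, kk]))
      rmat[i, j] <- pc$r
      pmat[i, j] <- pc$p_value
      nmat[i, j] <- pc$n
    }
  }
  structure(list(r = rmat, p_value = pmat, n_used = nmat,
                 lat = response$lat, lon = response$lon,
                 g = length(covariates)),
            class = "pcor_map")
}

#' Regional summary of a partial-correlation map
#'
#' Mean coefficient over the masked valid pixels and the four-way percentage
#' partition of pixels by sign and significance: significantly negative,
#' insignificantly negative, significantly positive, insignificantly positive
#' (as in map insets reporting Neg*, Neg, Pos*, Pos). Percentages always sum
#' to 100 over valid pixels; the measure-zero tie `r == 0` counts as
#' positive. Regional means are unweighted by default; `cos_lat_weight`
#' applies cos-latitude area weights to the mean coefficient.
#'
#' @param rmap A `pcor_map`.
#' @param mask Logical lat x lon matrix selecting the region (default: all).
#' @param alpha Significance level (default 0.05).
#' @param cos_lat_weight Weight the mean by cos(latitude).
#' @param label Optional stratum label.
#' @return List of class `region_summary`: `mean_r`, `pct_sig_neg`,
#'   `pct_neg`, `pct_sig_pos`, `pct_pos`, `n_pixels`, `label`.
#' @export
region_summary <- function(rmap, mask = NULL, alpha = 0.05,
                           cos_lat_weight = FALSE, label = NA_character_) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(rmap$r), ncol(rmap$r))
  if (!all(dim(mask) == dim(rmap$r))) stop("mask does not match grid", call. = FALSE)
  sel <- mask & !is.na(rmap$r)
  n <- sum(sel)
  if (n == 0) stop("empty region: no valid pixels under mask", call. = FALSE)
  r <- rmap$r[sel]
  p <- rmap$p_value[sel]
  w <- if (cos_lat_weight) {
    matrix(cos(rmap$lat * pi / 180), nrow(rmap$r), ncol(rmap$r))[sel]
  } else rep(1, n)
  neg <- r < 0
  sig <- p < alpha
  structure(
    list(mean_r = sum(w * r) / sum(w),
         pct_sig_neg = 100 * sum(neg & sig) / n,
         pct_neg = 100 * sum(neg & !sig) / n,
         pct_sig_pos = 100 * sum(!neg & sig) / n,
         pct_pos = 100 * sum(!neg & !sig) / n,
         n_pixels = n, alpha = alpha, label = label),
    class = "region_summary"
  )
}

#' @export
print.region_summary <- function(x, ...) {
  cat(sprintf(
    "region%s: mean r = %.3f over %d px | Neg* %.1f%% Neg %.1f%% Pos %.1f%% Pos* %.1f%%\n",
    if (is.na(x$label)) "" else paste0(" [", x$label, "]"),
    x$mean_r, x$n_pixels, x$pct_sig_neg, x$pct_neg, x$pct_pos, x$pct_sig_pos))
  invisible(x)
}

#' @export
as.data.frame.region_summary <- function(x, ...) {
  data.frame(label = x$label, mean_r = x$mean_r, pct_sig_neg = x$pct_sig_neg,
             pct_neg = x$pct_neg, pct_sig_pos = x$pct_sig_pos,
             pct_pos = x$pct_pos, n_pixels = x$n_pixels)
}

#' Regional summaries along a peatland-extent gradient
#'
#' Bins pixels by peatland extent fraction (percent) into
#' `[10,20), [20,30), ..., [70,100]` plus the `>=10%` union, and summarises
#' the correlation map within each bin. Bin edges are left-closed,
#' right-open, except the last bin which is closed; a declining suppression
#' gradient shows up as bin-mean r increasing with extent.
#'
#' @param rmap A `pcor_map`.
#' @param extent Numeric lat x lon matrix of peatland extent in percent
#'   (0-100).
#' @param alpha Significance level passed through.
#' @return `data.frame` with one row per populated bin (empty bins dropped)
#'   and the union row labelled `">=10"`.
#' @export
extent_gradient <- function(rmap, extent, alpha = 0.05) {
  if (!all(dim(extent) == dim(rmap$r))) stop("extent grid mismatch", call. = FALSE)
  if (any(extent < 0 | extent > 100, na.rm = TRUE)) {
    stop("extent must be a percentage in [0, 100]", call. = FALSE)
  }
  lower <- seq(10, 70, by = 10)
  upper <- c(seq(20, 70, by = 10), 100)
  labels <- c(sprintf("[%d,%d)", lower[-7], upper[-7]), "[70,100]")
  rows <- list()
  for (b in seq_along(lower)) {
    m <- if (b < 7) extent >= lower[b] & extent < upper[b]
         else extent >= lower[b] & extent <= upper[b]
    m[is.na(m)] <- FALSE
    if (!any(m & !is.na(rmap$r))) next
    rows[[length(rows) + 1]] <-
      as.data.frame(region_summary(rmap, m, alpha, label = labels[b]))
  }
  m <- extent >= 10
  m[is.na(m)] <- FALSE
  if (any(m & !is.na(rmap$r))) {
    rows[[length(rows) + 1]] <-
      as.data.frame(region_summary(rmap, m, alpha, label = ">=10"))
  }
  do.call(rbind, rows)
}

#' Humid / nonhumid stratification by aridity index
#'
#' Splits a grid on the aridity index (precipitation over potential
#' evapotranspiration): nonhumid where `ai < 0.65` strictly, humid where
#' `ai >= 0.65`. The two masks partition the valid (non-missing) pixels.
#'
#' @param ai Numeric matrix of aridity index values (>= 0).
#' @return List with logical matrices `nonhumid_mask` and `humid_mask`.
#' @export
aridity_split <- function(ai) {
  if (any(ai < 0, na.rm = TRUE)) stop("`ai` must be >= 0", call. = FALSE)
  nonhumid <- !is.na(ai) & ai < 0.65
  humid <- !is.na(ai) & ai >= 0.65
  list(nonhumid_mask = nonhumid, humid_mask = humid)
}

#' Agreement between tower-based and grid-based partial correlations
#'
#' Compares paired partial-correlation results from flux towers and from the
#' satellite grid pixels matched to them (by site and time span): percentage
#' of pairs whose coefficients share a sign, and the Pearson correlation of
#' the two coefficient vectors.
#'
#' @param tower_pcors,grid_pcors Lists of `pcor_result` (or numeric vectors
#'   of coefficients), paired by position.
#' @return List with `sign_agreement_pct`, `r`, `n`.
#' @export
tower_grid_agreement <- function(tower_pcors, grid_pcors) {
  rt <- if (is.numeric(tower_pcors)) tower_pcors
        else vapply(tower_pcors, `[[`, numeric(1), "r")
  rg <- if (is.numeric(grid_pcors)) grid_pcors
        else vapply(grid_pcors, `[[`, numeric(1), "r")
  if (length(rt) != length(rg)) stop("paired lists differ in length", call. = FALSE)
  ok <- !is.na(rt) & !is.na(rg)
  rt <- rt[ok]; rg <- rg[ok]
  list(sign_agreement_pct = 100 * mean(sign(rt) == sign(rg)),
       r = if (length(rt) > 2) stats::cor(rt, rg) else NA_real_,
       n = length(rt))
}
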