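#' Paired test of a warming treatment effect
#'
#' Paired t-test of warming minus control for one variable (air temperature,
#' relative humidity or VPD), with a Shapiro-Wilk normality screen on the
#' paired differences. When the differences fail the screen
#' (`shapiro_p <= shapiro_alpha`) a Wilcoxon signed-rank test is attached as
#' the nonparametric fallback. Identical treatments (all differences zero)
#' and zero-variance differences are degenerate for the t statistic and are
#' reported as such rather than erroring.
#'
#' @param control,warming Paired numeric series (same length, >= 3).
#' @param shapiro_alpha Normality-screen level for triggering the fallback
#'   (default 0.05).
#' @return List of class `warming_test`: `mean_diff`, `se_diff`, `t`, `df`,
#'   `p`, `shapiro_p`, `degenerate`, and `wilcoxon_p` (`NA` unless the
#'   fallback triggered).
#' @export
paired_warming_test <- function(control, warming, shapiro_alpha = 0.05) {
  if (length(control) != length(warming)) stop("series not paired", call. = FALSE)
  n <- length(control)
  if (n < 3) stop("need >= 3 paired observations", call. = FALSE)
  d <- warming - control
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    # constant shift (or identical treatments): t is 0/0 or infinite
    return(structure(
      list(mean_diff = md, se_diff = 0,
           t = if (md == 0) 0 else NA_real_, df = n - 1,
           p = if (md == 0) 1 else NA_real_,
           shapiro_p = NA_real_, wilcoxon_p = NA_real_,
           degenerate = TRUE, n = n),
      class = "warming_test"
    ))
  }
  tt <- stats::t.test(warming, control, paired = TRUE)
  sw <- stats::shapiro.test(d)
  wp <- NA_real_
  if (sw$p.value <= shapiro_alpha) {
    wp <- suppressWarnings(stats::wilcox.test(warming, control,
                                              paired = TRUE))$p.value
  }
  structure(
    list(mean_diff = md, se_diff = sdd / sqrt(n),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, shapiro_p = sw$p.value, wilcoxon_p = wp,
         degenerate = FALSE, n = n),
    class = "warming_test"
  )
}

#' @export
print.warming_test <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("paired test: degenerate (zero-variance differences), mean diff = %.3g\n",
                x$mean_diff))
  } else {
    cat(sprintf("paired t: mean diff = %.3g +/- %.3g, t = %.3f (df = %d), p = %.3g; Shapiro-Wilk p = %.3g%s\n",
                x$mean_diff, x$se_diff, x$t, x$df, x$p, x$shapiro_p,
                if (!is.na(x$wilcoxon_p))
                  sprintf("; Wilcoxon fallback p = %.3g", x$wilcoxon_p) else ""))
  }
  invisible(x)
}

#' Exponential temperature-VPD relationship
#'
#' Fits `VPD = a * exp(b * Ta)` by OLS on `ln(VPD)` (log-linear fit:
#' deterministic and closed-form; a nonlinear least-squares refinement is
#' available via `refine = TRUE`). The goodness-of-fit `r` reported is the
#' Pearson correlation between fitted and observed VPD on the original
#' scale. Non-positive VPD values cannot enter the log fit and are dropped
#' with their count recorded.
#'
#' @param ta Air temperature series, deg C.
#' @param vpd VPD series, hPa (> 0 where used).
#' @param refine Refine the log-linear estimates by nonlinear least squares
#'   on the original scale (default `FALSE`).
#' @return List of class `exp_fit`: `a` (hPa), `b` (per deg C), `r`, `n`,
#'   `n_dropped`.
#' @export
fit_ta_vpd_exponential <- function(ta, vpd, refine = FALSE) {
  if (length(ta) != length(vpd)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(ta) & is.finite(vpd) & vpd > 0
  n_dropped <- sum(!ok)
  ta_f <- ta[ok]; vpd_f <- vpd[ok]
  if (length(ta_f) < 5) stop("need >= 5 positive-VPD observations", call. = FALSE)
  fit <- stats::lm(log(vpd_f) ~ ta_f)
  a <- exp(unname(stats::coef(fit)[1]))
  b <- unname(stats::coef(fit)[2])
  if (refine) {
    nls_fit <- try(stats::nls(vpd_f ~ a * exp(b * ta_f),
                              start = list(a = a, b = b)), silent = TRUE)
    if (!inherits(nls_fit, "try-error")) {
      a <- unname(stats::coef(nls_fit)["a"])
      b <- unname(stats::coef(nls_fit)["b"])
    }
  }
  fitted_vpd <- a * exp(b * ta_f)
  r <- if (stats::sd(fitted_vpd) > 0 && stats::sd(vpd_f) > 0) {
    stats::cor(fitted_vpd, vpd_f)
  } else NA_real_
  structure(list(a = a, b = b, r = r, n = length(ta_f), n_dropped = n_dropped),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("VPD = %.4g * exp(%.4g * Ta) hPa  (r = %.3f, n = %d)\n",
              x$a, x$b, x$r, x$n))
  invisible(x)
}

#' VPD contrast implied by a temperature contrast
#'
#' Given a fitted exponential temperature-VPD law, the VPD difference between
#' a warming and a control temperature:
#' `a * exp(b * ta_warm) - a * exp(b * ta_control)`. Used to reconstruct the
#' VPD increase at warming-experiment sites where VPD itself was not
#' measured; positive whenever `b > 0` and `ta_warm > ta_control`.
#'
#' @param fit An `exp_fit` (or list with `a`, `b`).
#' @param ta_control,ta_warm Control and warming temperatures, deg C
#'   (vectorized).
#' @return Simulated VPD difference, hPa.
#' @export
simulate_vpd_delta <- function(fit, ta_control, ta_warm) {
  fit$a * exp(fit$b * ta_warm) - fit$a * exp(fit$b * ta_control)
}

#' Regression of growth response on the VPD contrast across sites
#'
#' OLS of the per-site growth response (by default the log response ratio
#' `ln(growth_warming / growth_control)`) on the per-site VPD increase. A
#' neutral VPD effect corresponds to a slope confidence interval covering
#' zero.
#'
#' @param response Per-site growth response (e.g. log response ratio).
#' @param dvpd Per-site VPD difference, hPa.
#' @return List of class `effect_regression`: `slope`, `se`, `p`,
#'   `intercept`, `n`, plus the 95% CI bounds `ci_lower`, `ci_upper`.
#' @export
vpd_effect_regression <- function(response, dvpd) {
  if (length(response) != length(dvpd)) stop("length mismatch", call. = FALSE)
  ok <- is.finite(response) & is.finite(dvpd)
  response <- response[ok]; dvpd <- dvpd[ok]
  if (length(response) < 3) stop("need n >= 3", call. = FALSE)
  if (stats::var(dvpd) == 0) stop("singular design: zero-variance VPD contrast", call. = FALSE)
  fit <- stats::lm(response ~ dvpd)
  co <- suppressWarnings(summary(fit))$coefficients
  slope <- unname(co[2, 1]); se <- unname(co[2, 2])
  tcrit <- stats::qt(0.975, df = length(response) - 2)
  structure(
    list(slope = slope, se = se, p = unname(co[2, 4]),
         intercept = unname(co[1, 1]), n = length(response),
         ci_lower = slope - tcrit * se, ci_upper = slope + tcrit * se),
    class = "effect_regression"
  )
}

#' @export
print.effect_regression <- function(x, ...) {
  cat(sprintf("growth response ~ dVPD: slope = %.3f +/- %.3f (p = %.3g, n = %d, 95%% CI [%.3f, %.3f])\n",
              x$slope, x$se, x$p, x$n, x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Growth response metric for warming/control pairs
#'
#' Encodes the per-site vegetation growth response. Default is the log
#' response ratio `ln(warming/control)`; `"ratio"` and `"difference"` modes
#' are provided for syntheses that report raw ratios or absolute changes.
#'
#' @param growth_control,growth_warming Positive growth metrics (NPP,
#'   biomass, canopy conductance) for ratio-based modes.
#' @param mode One of `"log_ratio"` (default), `"ratio"`, `"difference"`.
#' @return Numeric response vector.
#' @export
growth_response <- function(growth_control, growth_warming,
                            mode = c("log_ratio", "ratio", "difference")) {
  mode <- match.arg(mode)
  if (mode != "difference" && any(growth_control <= 0 | growth_warming <= 0)) {
    stop("ratio modes require positive growth values", call. = FALSE)
  }
  switch(mode,
         log_ratio = log(growth_warming / growth_control),
         ratio = growth_warming / growth_control,
         difference = growth_warming - growth_control)
}

#' Per-site VPD contrasts for a warming synthesis table
#'
#' Takes a synthesis table of warming experiments and returns the per-site
#' VPD difference. Sites reporting RH get VPD via the temperature/relative
#' humidity formula; sites reporting VPD pass through. When VPD must be
#' simulated from temperature alone, a fitted exponential law is applied
#' per site (`fit` may be a single pooled `exp_fit` or a list of per-site
#' fits).
#'
#' @param sites `data.frame` with columns `ta_c`, `ta_w` and either
#'   `vpd_c`/`vpd_w` or `rh_c`/`rh_w` (or neither, requiring `fit`).
#' @param fit Optional `exp_fit` (pooled) or list of per-site fits, used for
#'   sites with neither RH nor VPD observed.
#' @return Numeric vector of per-site VPD differences (warming - control), hPa.
#' @export
synthesis_vpd_delta <- function(sites, fit = NULL) {
  n <- nrow(sites)
  dvpd <- rep(NA_real_, n)
  has <- function(col) {
    if (!col %in% names(sites)) return(rep(FALSE, n))
    !is.na(sites[[col]])
  }
  use_vpd <- has("vpd_c") & has("vpd_w")
  use_rh <- !use_vpd & has("rh_c") & has("rh_w")
  dvpd[use_vpd] <- sites$vpd_w[use_vpd] - sites$vpd_c[use_vpd]
  if (any(use_rh)) {
    dvpd[use_rh] <- vpd_from_rh(sites$ta_w[use_rh], sites$rh_w[use_rh]) -
      vpd_from_rh(sites$ta_c[use_rh], sites$rh_c[use_rh])
  }
  rest <- !use_vpd & !use_rh
  if (any(rest)) {
    if (is.null(fit)) stop("sites without RH/VPD need a fitted Ta-VPD law", call. = FALSE)
    single <- inherits(fit, "exp_fit") ||
      (is.list(fit) && all(c("a", "b") %in% names(fit)))
    if (single) fit <- rep(list(fit), n)
    dvpd[rest] <- vapply(which(rest), function(i) {
      simulate_vpd_delta(fit[[i]], sites$ta_c[i], sites$ta_w[i])
    }, numeric(1))
  }
  dvpd
}
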