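# Independent oracles used across test files. These deliberately take the
# long way around (explicit residual regressions, closed-form normal
# equations) so they share no code path with the implementations they check.

# Partial correlation as the correlation of residuals from two explicit
# lm() fits on the covariates (with intercept).
pcor_residual_oracle <- function(y, x, z) {
  if (length(z) == 0) return(stats::cor(y, x))
  zm <- do.call(cbind, z)
  ry <- stats::residuals(stats::lm(y ~ zm))
  rx <- stats::residuals(stats::lm(x ~ zm))
  stats::cor(ry, rx)
}

# OLS slope/intercept from the closed-form normal equations.
ols_normal_equations <- function(y, t) {
  xb <- mean(t); yb <- mean(y)
  b1 <- sum((t - xb) * (y - yb)) / sum((t - xb)^2)
  c(beta0 = yb - b1 * xb, beta1 = b1)
}

# Paired t statistic from the textbook closed form.
paired_t_closed_form <- function(control, warming) {
  d <- warming - control
  mean(d) / (stats::sd(d) / sqrt(length(d)))
}

# Random met/flux draws for Penman-Monteith round trips.
random_pm_draw <- function(n, seed) {
  set.seed(seed)
  ws <- stats::runif(n, 0.5, 8)
  data.frame(
    gc = stats::runif(n, 1, 20),             # mm s^-1
    a_energy = stats::runif(n, 40, 250),     # W m^-2
    vpd = stats::runif(n, 1, 25),            # hPa
    ws = ws,
    u_star = ws * stats::runif(n, 0.05, 0.25),  # keeps k*ws/u* > ln(1.7)
    ta = stats::runif(n, -5, 30)
  )
}
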