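#' Serial two-mediator mediation model
#'
#' Quantifies how an exposure `x` (e.g. water availability or a soil
#' hydraulic property) acts on an outcome `y` (the GPP-VPD partial
#' correlation) directly and through two ordered mediators `m1` (underlying
#' water-use efficiency) and `m2` (the transpiration-VPD coupling). Three
#' OLS regressions are fitted on z-standardized variables:
#' \itemize{
#'   \item `m1 ~ x` (path `a1`)
#'   \item `m2 ~ x + m1` (paths `a2`, `d21`)
#'   \item `y ~ x + m1 + m2` (paths `c_prime`, `b1`, `b2`)
#' }
#' Indirect effects are path products: `ind_m1 = a1*b1`, `ind_m2 = a2*b2`,
#' `ind_serial = a1*d21*b2`; the total effect decomposes exactly as
#' `c = c_prime + ind_m1 + ind_m2 + ind_serial` (an OLS identity on any
#' sample). Percentile bootstrap confidence intervals are attached to every
#' effect; an effect is flagged significant when its interval excludes zero.
#'
#' @param x,m1,m2,y Numeric series of equal length (n >= 10); standardized
#'   internally so all paths are standardized effects.
#' @param n_boot Bootstrap resamples (default 5000; a warning below 200).
#' @param seed Integer seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return List of class `mediation_result` with elements `paths` (a1, a2,
#'   d21, b1, b2, c_prime), `effects` (named vector: c_prime, ind_m1,
#'   ind_m2, ind_serial, total), `ci` (matrix with lower/upper rows),
#'   `se` (bootstrap standard errors), `significant` (logical), `n`,
#'   `n_boot`.
#' @export
serial_mediation <- function(x, m1, m2, y, n_boot = 5000, seed = 1L,
                             conf = 0.95) {
  n <- length(x)
  if (length(m1) != n || length(m2) != n || length(y) != n) {
    stop("series lengths differ", call. = FALSE)
  }
  if (n < 10) stop("need n >= 10", call. = FALSE)
  if (n_boot < 200) warning("n_boot < 200 gives unstable percentile intervals")
  zs <- function(v) {
    s <- stats::sd(v)
    if (s == 0) stop("zero-variance variable", call. = FALSE)
    (v - mean(v)) / s
  }
  dat <- data.frame(x = zs(x), m1 = zs(m1), m2 = zs(m2), y = zs(y))

  fit_paths <- function(d) {
    f1 <- stats::lm.fit(cbind(1, d$x), d$m1)
    f2 <- stats::lm.fit(cbind(1, d$x, d$m1), d$m2)
    f3 <- stats::lm.fit(cbind(1, d$x, d$m1, d$m2), d$y)
    if (any(is.na(f2$coefficients)) || any(is.na(f3$coefficients))) {
      stop("rank-deficient mediation design (collinear variables)", call. = FALSE)
    }
    a1 <- f1$coefficients[2]
    a2 <- f2$coefficients[2]; d21 <- f2$coefficients[3]
    c_prime <- f3$coefficients[2]; b1 <- f3$coefficients[3]; b2 <- f3$coefficients[4]
    c(a1 = unname(a1), a2 = unname(a2), d21 = unname(d21),
      b1 = unname(b1), b2 = unname(b2), c_prime = unname(c_prime),
      ind_m1 = unname(a1 * b1), ind_m2 = unname(a2 * b2),
      ind_serial = unname(a1 * d21 * b2),
      total = unname(c_prime + a1 * b1 + a2 * b2 + a1 * d21 * b2))
  }

  est <- fit_paths(dat)
  set.seed(seed)
  boot <- matrix(NA_real_, n_boot, length(est),
                 dimnames = list(NULL, names(est)))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    boot[b, ] <- tryCatch(fit_paths(dat[idx, ]), error = function(e) rep(NA_real_, length(est)))
  }
  alpha <- (1 - conf) / 2
  ci <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  se <- apply(boot, 2, stats::sd, na.rm = TRUE)
  eff_names <- c("c_prime", "ind_m1", "ind_m2", "ind_serial", "total")
  structure(
    list(paths = est[c("a1", "a2", "d21", "b1", "b2", "c_prime")],
         effects = est[eff_names],
         ci = ci, se = se,
         significant = ci[1, eff_names] > 0 | ci[2, eff_names] < 0,
         n = n, n_boot = n_boot, conf = conf, seed = seed),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("serial mediation (n = %d, %d bootstrap resamples):\n", x$n, x$n_boot))
  for (nm in names(x$effects)) {
    cat(sprintf("  %-10s %+ .4f  [%+.4f, %+.4f]%s\n", nm, x$effects[nm],
                x$ci[1, nm], x$ci[2, nm],
                if (nm != "total" && isTRUE(x$significant[nm])) " *" else ""))
  }
  invisible(x)
}

#' Mediation battery over the four soil/water exposures
#'
#' Runs the serial two-mediator model once per exposure in
#' `c("vwc", "cwd", "soc", "bd")` with the shared mediator pair
#' (`m1 = uwue`, `m2 = pcor_et_vpd`, order configurable) and the outcome
#' `pcor_gpp_vpd`, all on the same complete-case sample.
#'
#' @param table A `predictor_table` (or plain `data.frame` with the needed
#'   columns).
#' @param x_vars Exposure column names.
#' @param m1,m2 Mediator column names (order matters for the serial path).
#' @param y Outcome column name.
#' @param n_boot,seed,conf Passed to [serial_mediation()].
#' @return Named list of `mediation_result`, one per exposure.
#' @export
mediation_battery <- function(table, x_vars = c("vwc", "cwd", "soc", "bd"),
                              m1 = "uwue", m2 = "pcor_et_vpd",
                              y = "pcor_gpp_vpd",
                              n_boot = 5000, seed = 1L, conf = 0.95) {
  df <- if (inherits(table, "predictor_table")) table$raw else table
  missing_cols <- setdiff(c(x_vars, m1, m2, y), names(df))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[stats::complete.cases(df[, c(x_vars, m1, m2, y)]), ]
  out <- lapply(seq_along(x_vars), function(i) {
    serial_mediation(df[[x_vars[i]]], df[[m1]], df[[m2]], df[[y]],
                     n_boot = n_boot, seed = seed + i - 1L, conf = conf)
  })
  names(out) <- x_vars
  out
}
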