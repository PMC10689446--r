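#' Assemble the predictor table for the sensitivity analysis
#'
#' Keeps the six predictors of the VPD-effect model (available volumetric
#' water content `vwc`, climate water deficit `cwd`, soil organic carbon
#' `soc`, bulk density `bd`, underlying water-use efficiency `uwue`, and the
#' transpiration-VPD partial correlation `pcor_et_vpd`) plus the response
#' `pcor_gpp_vpd`; drops rows with any missing value (listwise, counted),
#' and attaches a z-score-normalized copy of the predictors alongside the
#' raw columns.
#'
#' @param df `data.frame` containing the predictor and response columns.
#' @param predictors Character vector of predictor column names.
#' @param response Response column name.
#' @return List of class `predictor_table`: `raw` (complete-case
#'   data.frame), `normalized` (predictors z-scored), `predictors`,
#'   `response`, `n_dropped`, and `scale` (per-predictor sd used).
#' @export
predictor_table <- function(df,
                            predictors = c("vwc", "cwd", "soc", "bd",
                                           "uwue", "pcor_et_vpd"),
                            response = "pcor_gpp_vpd") {
  missing_cols <- setdiff(c(predictors, response), names(df))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sub <- df[, c(predictors, response)]
  cc <- stats::complete.cases(sub)
  raw <- sub[cc, , drop = FALSE]
  ctr <- vapply(raw[predictors], mean, numeric(1))
  scl <- vapply(raw[predictors], stats::sd, numeric(1))
  if (any(scl == 0)) stop("constant predictor column", call. = FALSE)
  normalized <- raw
  normalized[predictors] <- scale(raw[predictors], center = ctr, scale = scl)
  structure(list(raw = raw, normalized = normalized,
                 predictors = predictors, response = response,
                 center = ctr, scale = scl, n_dropped = sum(!cc)),
            class = "predictor_table")
}

#' Fit the random-forest model of the VPD effect
#'
#' Random-forest regression of the response (the GPP-VPD partial
#' correlation) on the normalized predictors, trained on a random 60% of
#' rows; skill is the Pearson correlation `model_r` between predictions and
#' observations on the held-out 40%. Sensitivities should only be
#' interpreted when `model_r > 0.8` (the `gate_passed` flag).
#'
#' @param table A `predictor_table`.
#' @param seed Integer seed controlling the split and the forest.
#' @param ntree Number of trees (default 500).
#' @param train_frac Training fraction (default 0.6).
#' @return List of class `rf_fit`: `model`, `model_r`, `gate_passed`,
#'   `train_idx`, `table`, `seed`.
#' @export
fit_rf <- function(table, seed = 1L, ntree = 500, train_frac = 0.6) {
  stopifnot(inherits(table, "predictor_table"))
  dat <- table$normalized
  n <- nrow(dat)
  if (n < 100) stop("need >= 100 rows for a meaningful split", call. = FALSE)
  if (stats::sd(dat[[table$response]]) == 0) {
    stop("degenerate fit: constant response", call. = FALSE)
  }
  set.seed(seed)
  train_idx <- sample.int(n, size = floor(train_frac * n))
  fm <- stats::as.formula(paste(table$response, "~",
                                paste(table$predictors, collapse = " + ")))
  model <- randomForest::randomForest(fm, data = dat[train_idx, ], ntree = ntree)
  test <- dat[-train_idx, ]
  pred <- stats::predict(model, newdata = test)
  model_r <- stats::cor(pred, test[[table$response]])
  structure(list(model = model, model_r = model_r,
                 gate_passed = model_r > 0.8,
                 train_idx = train_idx, table = table, seed = seed),
            class = "rf_fit")
}

#' @export
print.rf_fit <- function(x, ...) {
  cat(sprintf("random forest VPD-effect model: held-out r = %.3f (%s)\n",
              x$model_r,
              if (x$gate_passed) "passes r > 0.8 gate" else "below r > 0.8 gate"))
  invisible(x)
}

#' Perturbation sensitivity of the VPD effect to one predictor
#'
#' Perturbs the named (normalized) predictor by one standard deviation
#' (+1 on the normalized scale), re-predicts with the fitted forest, and
#' takes the mean prediction difference divided by the standard deviation of
#' the raw (non-normalized) response. The procedure is repeated
#' `n_repeats` times (default 15) on bootstrap resamples of the prediction
#' rows with the model held fixed (`repeat_mode = "bootstrap"`; a
#' refit-per-repeat variant is available), and the median over repeats is
#' reported. The raw-scale denominator makes the sensitivity scale-free in
#' the response.
#'
#' @param fit An `rf_fit`.
#' @param predictor Predictor name to perturb.
#' @param seed Integer seed for the repeat resampling (and refits).
#' @param n_repeats Number of repeats (default 15).
#' @param direction `"+1"` (default) perturbs by +1 SD; `"sym"` averages the
#'   +1 and -1 SD responses (sign-preserving: the -1 difference is negated).
#' @param repeat_mode `"bootstrap"` (default) or `"refit"`.
#' @return Scalar median sensitivity with attribute `repeats` (the 15
#'   per-repeat values).
#' @export
rf_sensitivity <- function(fit, predictor, seed = 1L, n_repeats = 15,
                           direction = c("+1", "sym"),
                           repeat_mode = c("bootstrap", "refit")) {
  direction <- match.arg(direction)
  repeat_mode <- match.arg(repeat_mode)
  tab <- fit$table
  if (!predictor %in% tab$predictors) {
    stop("unknown predictor: ", predictor, call. = FALSE)
  }
  dat <- tab$normalized
  sd_raw <- stats::sd(tab$raw[[tab$response]])
  one <- function(model, rows) {
    base <- stats::predict(model, newdata = rows)
    up <- rows
    up[[predictor]] <- up[[predictor]] + 1
    d <- stats::predict(model, newdata = up) - base
    if (direction == "sym") {
      dn <- rows
      dn[[predictor]] <- dn[[predictor]] - 1
      d <- (d + (base - stats::predict(model, newdata = dn))) / 2
    }
    mean(d) / sd_raw
  }
  set.seed(seed)
  reps <- vapply(seq_len(n_repeats), function(k) {
    rows <- dat[sample.int(nrow(dat), replace = TRUE), , drop = FALSE]
    model <- if (repeat_mode == "refit") {
      fm <- stats::as.formula(paste(tab$response, "~",
                                    paste(tab$predictors, collapse = " + ")))
      randomForest::randomForest(fm, data = rows,
                                 ntree = fit$model$ntree)
    } else fit$model
    one(model, rows)
  }, numeric(1))
  structure(stats::median(reps), repeats = reps)
}

#' Sensitivities for every predictor
#'
#' @param fit An `rf_fit`.
#' @param seed,n_repeats,direction,repeat_mode Passed to [rf_sensitivity()].
#' @return Named numeric vector of median sensitivities, one per predictor.
#' @export
rf_sensitivity_all <- function(fit, seed = 1L, n_repeats = 15,
                               direction = "+1", repeat_mode = "bootstrap") {
  out <- vapply(fit$table$predictors, function(p) {
    as.numeric(rf_sensitivity(fit, p, seed = seed, n_repeats = n_repeats,
                              direction = direction, repeat_mode = repeat_mode))
  }, numeric(1))
  names(out) <- fit$table$predictors
  out
}

#' Partial-dependence-style response curve for one predictor
#'
#' Mean forest prediction as the named normalized predictor is set to each
#' grid value, all other predictors held at their observed values. Used to
#' inspect the qualitative monotonicities (e.g. the VPD effect decreasing
#' with uWUE and increasing with the transpiration-VPD coupling).
#'
#' @param fit An `rf_fit`.
#' @param predictor Predictor name.
#' @param grid Numeric grid of (normalized) predictor values; default 25
#'   points over the observed range. Values outside the observed range
#'   trigger an extrapolation warning.
#' @return `data.frame` with columns `value` and `prediction`.
#' @export
sensitivity_profile <- function(fit, predictor, grid = NULL) {
  tab <- fit$table
  if (!predictor %in% tab$predictors) {
    stop("unknown predictor: ", predictor, call. = FALSE)
  }
  obs <- tab$normalized[[predictor]]
  if (is.null(grid)) grid <- seq(min(obs), max(obs), length.out = 25)
  if (any(grid < min(obs) | grid > max(obs))) {
    warning("grid extends beyond the observed predictor range (extrapolation)")
  }
  preds <- vapply(grid, function(v) {
    rows <- tab$normalized
    rows[[predictor]] <- v
    mean(stats::predict(fit$model, newdata = rows))
  }, numeric(1))
  data.frame(value = grid, prediction = preds)
}
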