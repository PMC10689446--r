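#' Configuration for the gridded synthetic-data generator
#'
#' Defaults encode the conditions of the reference analysis: annual
#' growing-season aggregates for 1982-2018 (37 years), a warming trend of
#' 0.028 deg C per year with essentially flat relative humidity (so VPD rises
#' through temperature alone, the northern-peatland regime), an exponential
#' temperature-VPD law `VPD = 2 exp(0.07 Ta)` hPa (sized so the implied
#' relative humidity sits near 65-75%), a planted conditional
#' correlation of 0.07 between detrended GPP and detrended VPD given the four
#' climatic covariates (the scale of reported regional means), and mild 0.3
#' cross-correlation among covariate anomalies so the partial correlation is
#' exercised nontrivially.
#'
#' @param n_lat,n_lon Grid size (pixels).
#' @param years Calendar years of the annual time axis.
#' @param ta_base Mean growing-season temperature at the first year, deg C.
#' @param ta_trend Temperature trend, deg C per year.
#' @param rh_trend Relative-humidity trend, percentage points per year;
#'   applied as the first-order VPD adjustment `-svp(ta) * rh_trend * t / 100`.
#' @param ta_vpd_a,ta_vpd_b Exponential law parameters (hPa; per deg C).
#' @param target_pcor Planted partial correlation: a scalar in (-1, 1) or a
#'   function of peatland extent percent returning one.
#' @param ta_noise_sd,vpd_lognoise_sd,gpp_noise_sd Noise scales.
#' @param covar_beta Loadings of the GPP anomaly on the standardized
#'   covariate anomalies (recycled to 4).
#' @param covar_cross_cor Common correlation among the four covariate
#'   anomalies (temperature, radiation, wind, precipitation).
#' @param gpp_base,gpp_trend GPP level (g C m^-2) and trend.
#' @param extent_range Range of the uniform peatland-extent field, percent.
#' @param ai_range Range of the uniform aridity-index field.
#' @param seed Integer seed (mandatory; no global RNG state is relied on).
#' @return List of class `grid_gen_config`.
#' @export
grid_gen_config <- function(n_lat = 20, n_lon = 20, years = 1982:2018,
                            ta_base = 10, ta_trend = 0.028, rh_trend = 0,
                            ta_vpd_a = 2, ta_vpd_b = 0.07,
                            target_pcor = 0.07,
                            ta_noise_sd = 0.6, vpd_lognoise_sd = 0.08,
                            gpp_noise_sd = 60,
                            covar_beta = 0.3, covar_cross_cor = 0.3,
                            gpp_base = 600, gpp_trend = 2,
                            extent_range = c(0, 100), ai_range = c(0.2, 1.6),
                            seed = 1L) {
  stopifnot(length(years) >= 5, ta_noise_sd > 0, vpd_lognoise_sd > 0,
            gpp_noise_sd > 0)
  if (is.numeric(target_pcor) && any(abs(target_pcor) >= 1)) {
    stop("|target_pcor| must be < 1", call. = FALSE)
  }
  structure(as.list(environment()), class = "grid_gen_config")
}

# Correlated standard-normal anomaly draws: k series of length n with common
# pairwise correlation rho, first column pinned to `first` if given.
correlated_anomalies <- function(n, k, rho, first = NULL) {
  sigma <- matrix(rho, k, k); diag(sigma) <- 1
  l <- chol(sigma)
  z <- matrix(stats::rnorm(n * k), n, k)
  if (!is.null(first)) z[, 1] <- first
  z %*% l
}

#' Generate a gridded synthetic dataset with known ground truth
#'
#' Produces annual growing-season cubes of GPP, VPD, Ta, RH, radiation, wind
#' speed and precipitation on a lat/lon grid, plus static peatland-extent and
#' aridity-index fields and a per-pixel truth table. Per pixel:
#' temperature is `baseline + trend * t + noise`; VPD follows the exponential
#' law with lognormal noise (and the configured RH-trend adjustment); RH is
#' recovered by exact inversion of the deficit formula, resampling the rare
#' draws that would imply supersaturation; the GPP anomaly is built from the
#' detrended, covariate-residualized, standardized VPD anomaly `u` as
#' `rho * u + sqrt(1 - rho^2) * e + sum(beta_j * z_j)`, so the planted
#' conditional correlation `rho` is exactly the population partial
#' correlation that [pcor_map()] estimates.
#'
#' @param cfg A [grid_gen_config()].
#' @return List: `cubes` (named list of `grid_cube`: gpp, vpd, ta, rh,
#'   radiation, wind, precip), `extent` and `ai` (static matrices), `truth`
#'   (`data.frame` of per-pixel planted rho and extent), `n_rh_resampled`,
#'   and the `cfg` used.
#' @export
gen_gridded <- function(cfg = grid_gen_config()) {
  stopifnot(inherits(cfg, "grid_gen_config"))
  set.seed(cfg$seed)
  nt <- length(cfg$years)
  nlat <- cfg$n_lat; nlon <- cfg$n_lon
  t_c <- cfg$years - cfg$years[1]
  lat <- seq(45, 70, length.out = nlat)
  lon <- seq(-180, 180, length.out = nlon + 1)[-1]

  extent <- matrix(stats::runif(nlat * nlon, cfg$extent_range[1],
                                cfg$extent_range[2]), nlat, nlon)
  ai <- matrix(stats::runif(nlat * nlon, cfg$ai_range[1], cfg$ai_range[2]),
               nlat, nlon)
  rho_px <- if (is.function(cfg$target_pcor)) cfg$target_pcor(extent)
            else matrix(cfg$target_pcor, nlat, nlon)
  if (any(abs(rho_px) >= 1)) stop("target_pcor function produced |rho| >= 1", call. = FALSE)

  arr <- function() array(NA_real_, c(nt, nlat, nlon))
  cubes <- list(gpp = arr(), vpd = arr(), ta = arr(), rh = arr(),
                radiation = arr(), wind = arr(), precip = arr())
  beta <- rep_len(cfg$covar_beta, 4)
  n_resampled <- 0L

  for (i in seq_len(nlat)) {
    for (j in seq_len(nlon)) {
      ta_noise <- stats::rnorm(nt, 0, cfg$ta_noise_sd)
      ta <- cfg$ta_base + cfg$ta_trend * t_c + ta_noise
      # lognormal multiplicative noise on the exponential law, then the
      # first-order RH-trend adjustment dVPD = -SVP * dRH / 100
      vpd <- cfg$ta_vpd_a * exp(cfg$ta_vpd_b * ta) *
        exp(stats::rnorm(nt, 0, cfg$vpd_lognoise_sd)) -
        svp(ta) * cfg$rh_trend * t_c / 100
      bad <- which(vpd <= 0 | vpd >= svp(ta))
      while (length(bad)) {
        n_resampled <- n_resampled + length(bad)
        vpd[bad] <- cfg$ta_vpd_a * exp(cfg$ta_vpd_b * ta[bad]) *
          exp(stats::rnorm(length(bad), 0, cfg$vpd_lognoise_sd)) -
          svp(ta[bad]) * cfg$rh_trend * t_c[bad] / 100
        bad <- which(vpd <= 0 | vpd >= svp(ta))
      }
      rh <- 100 * (1 - vpd / svp(ta))

      z <- correlated_anomalies(nt, 4, cfg$covar_cross_cor,
                                first = scale(ta_noise)[, 1])
      radiation <- 160 + 15 * z[, 2]
      wind <- 3 + 0.5 * z[, 3]
      precip <- 450 + 80 * z[, 4]

      # plant the conditional correlation on the residualized VPD anomaly
      v_d <- detrend_series(vpd, t_c)
      z_d <- apply(cbind(ta, radiation, wind, precip), 2, detrend_series, t = t_c)
      u <- stats::residuals(stats::lm.fit(cbind(1, z_d), v_d))
      u <- u / stats::sd(u)
      # the independent part must live in the same residual space as u, or
      # the realized conditional correlation exceeds rho by a 1/n factor
      e <- stats::rnorm(nt)
      e <- stats::residuals(stats::lm.fit(cbind(1, t_c, z_d), e))
      e <- e / stats::sd(e)
      z_std <- scale(z_d)
      rho <- rho_px[i, j]
      g_anom <- rho * u + sqrt(1 - rho^2) * e + as.vector(z_std %*% beta)
      gpp <- cfg$gpp_base + cfg$gpp_trend * t_c + cfg$gpp_noise_sd * g_anom

      cubes$gpp[, i, j] <- gpp
      cubes$vpd[, i, j] <- vpd
      cubes$ta[, i, j] <- ta
      cubes$rh[, i, j] <- rh
      cubes$radiation[, i, j] <- radiation
      cubes$wind[, i, j] <- wind
      cubes$precip[, i, j] <- precip
    }
  }
  stopifnot(all(cubes$rh > 0 & cubes$rh <= 100), all(cubes$vpd >= 0))

  units <- c(gpp = "gC m-2", vpd = "hPa", ta = "degC", rh = "%",
             radiation = "W m-2", wind = "m s-1", precip = "mm")
  cubes <- lapply(stats::setNames(names(cubes), names(cubes)), function(nm) {
    grid_cube(cubes[[nm]], cfg$years, lat, lon, units = units[[nm]])
  })
  truth <- data.frame(
    lat_idx = rep(seq_len(nlat), times = nlon),
    lon_idx = rep(seq_len(nlon), each = nlat),
    rho = as.vector(rho_px),
    extent = as.vector(extent),
    ai = as.vector(ai)
  )
  list(cubes = cubes, extent = extent, ai = ai, truth = truth,
       n_rh_resampled = n_resampled, cfg = cfg)
}

#' Configuration for the synthetic flux-tower generator
#'
#' @param n_months Number of monthly records (default 120).
#' @param true_gc True canopy conductance, mm s^-1: a scalar or a length-12
#'   seasonal cycle (recycled).
#' @param uwue_true Underlying water-use efficiency used by the GPP law,
#'   g C kPa^0.5 kg^-1 H2O (default 1.23, the wet-peatland scale).
#' @param ta_mean,ta_amp Mean and seasonal amplitude of temperature, deg C.
#' @param flux_noise_sd Multiplicative lognormal noise sd applied to LE and
#'   H (default 0.05; set 0 for exact round trips).
#' @param seed Integer seed.
#' @return List of class `flux_gen_config`.
#' @export
flux_gen_config <- function(n_months = 120, true_gc = 6, uwue_true = 1.23,
                            ta_mean = 8, ta_amp = 14,
                            flux_noise_sd = 0.05, seed = 1L) {
  stopifnot(all(true_gc > 0), n_months >= 12, flux_noise_sd >= 0)
  structure(as.list(environment()), class = "flux_gen_config")
}

#' Generate a synthetic monthly flux-tower series
#'
#' Meteorology (seasonal temperature, exponential-law VPD, wind, friction
#' velocity, available energy) drives the standard forward Penman-Monteith
#' equation at a known canopy conductance; sensible heat is the energy
#' residual, and GPP follows the configured water-use-efficiency law
#' `GPP = uwue_true * ET / sqrt(VPD_kPa)`. Inverting the generated fluxes
#' with [canopy_conductance()] recovers the true conductance (exactly at
#' zero noise), and [uwue()] on the generated series returns `uwue_true`
#' by construction.
#'
#' @param cfg A [flux_gen_config()].
#' @return List: `data` (monthly `data.frame`: year, month, ta, vpd, rh, ws,
#'   ustar, le, h, gpp, et, pa, qc), `truth` (list with `gc`, `uwue`), `cfg`.
#' @export
gen_flux_tower <- function(cfg = flux_gen_config()) {
  stopifnot(inherits(cfg, "flux_gen_config"))
  set.seed(cfg$seed)
  n <- cfg$n_months
  month <- ((seq_len(n) - 1) %% 12) + 1
  year <- 2001 + (seq_len(n) - 1) %/% 12
  ta <- cfg$ta_mean + cfg$ta_amp * sin(2 * pi * (month - 4) / 12) +
    stats::rnorm(n, 0, 0.8)
  vpd <- pmin(6 * exp(0.05 * ta) * exp(stats::rnorm(n, 0, 0.1)),
              0.95 * svp(ta))
  rh <- 100 * (1 - vpd / svp(ta))
  ws <- exp(stats::rnorm(n, log(3), 0.2))
  ustar <- 0.08 + 0.07 * ws
  a_energy <- 80 + 70 * sin(2 * pi * (month - 4) / 12) + stats::rnorm(n, 0, 5)
  a_energy <- pmax(a_energy, 20)
  gc_true <- rep_len(cfg$true_gc, 12)[month]
  pm <- penman_monteith_le(gc_true, a_energy, vpd, ws, ustar, ta)
  le <- pm$le * exp(stats::rnorm(n, 0, cfg$flux_noise_sd))
  h <- pm$h * exp(stats::rnorm(n, 0, cfg$flux_noise_sd))
  secs <- 30.4 * 86400  # mean month
  et <- et_from_le(le) * secs
  gpp <- cfg$uwue_true * et / sqrt(vpd / 10)
  data <- data.frame(year = year, month = month, ta = ta, vpd = vpd, rh = rh,
                     ws = ws, ustar = ustar, le = le, h = h, gpp = gpp,
                     et = et, pa = 101.325, qc = 1)
  list(data = data,
       truth = list(gc = gc_true, uwue = cfg$uwue_true,
                    le_clean = pm$le, h_clean = pm$h),
       cfg = cfg)
}

#' Generate a synthetic warming-experiment synthesis table
#'
#' Emulates a multi-site warming synthesis: per site a control temperature,
#' a warming offset, VPD in both treatments from an exponential
#' temperature-VPD law, RH back-computed from the deficit, and a growth
#' response (log response ratio) of `effect_slope * dVPD + noise`. The
#' defaults match the reference synthesis conditions: 67 sites, a mean
#' warming of 2.7 deg C, and a neutral planted effect (`effect_slope = 0`);
#' `noise_sd = 0.8` sizes the regression slope standard error near 0.27 at
#' those defaults.
#'
#' @param n_sites Number of sites (default 67).
#' @param dta_mean,dta_sd Mean and site-to-site sd of the warming offset,
#'   deg C.
#' @param vpd_law List with `a` (hPa) and `b` (per deg C).
#' @param effect_slope Planted slope of the log response ratio on dVPD
#'   (per hPa); 0 is the neutral scenario.
#' @param noise_sd Sd of the response noise.
#' @param ta_c_mean,ta_c_sd Distribution of control-site temperatures, deg C.
#' @param growth_base Baseline control growth metric (e.g. NPP g C m^-2).
#' @param seed Integer seed.
#' @return List: `sites` (`data.frame` with site_id, ta_c, ta_w, vpd_c,
#'   vpd_w, rh_c, rh_w, growth_c, growth_w, metric), `truth` (list with
#'   `effect_slope`, `vpd_law`, `dvpd`), `cfg` echo of the arguments.
#' @export
gen_warming_sites <- function(n_sites = 67, dta_mean = 2.7, dta_sd = 1.0,
                              vpd_law = list(a = 2, b = 0.07),
                              effect_slope = 0, noise_sd = 0.8,
                              ta_c_mean = 8, ta_c_sd = 3,
                              growth_base = 400, seed = 1L) {
  stopifnot(n_sites >= 3, dta_sd > 0, noise_sd >= 0)
  set.seed(seed)
  ta_c <- stats::rnorm(n_sites, ta_c_mean, ta_c_sd)
  ta_w <- ta_c + stats::rnorm(n_sites, dta_mean, dta_sd)
  vpd_c <- vpd_law$a * exp(vpd_law$b * ta_c)
  vpd_w <- vpd_law$a * exp(vpd_law$b * ta_w)
  rh_c <- 100 * (1 - vpd_c / svp(ta_c))
  rh_w <- 100 * (1 - vpd_w / svp(ta_w))
  stopifnot(all(rh_c > 0 & rh_c <= 100), all(rh_w > 0 & rh_w <= 100))
  dvpd <- vpd_w - vpd_c
  response <- effect_slope * dvpd + stats::rnorm(n_sites, 0, noise_sd)
  growth_c <- growth_base * exp(stats::rnorm(n_sites, 0, 0.2))
  growth_w <- growth_c * exp(response)
  sites <- data.frame(site_id = sprintf("S%03d", seq_len(n_sites)),
                      ta_c = ta_c, ta_w = ta_w, vpd_c = vpd_c, vpd_w = vpd_w,
                      rh_c = rh_c, rh_w = rh_w,
                      growth_c = growth_c, growth_w = growth_w,
                      metric = "NPP")
  list(sites = sites,
       truth = list(effect_slope = effect_slope, vpd_law = vpd_law,
                    dvpd = dvpd),
       cfg = list(n_sites = n_sites, dta_mean = dta_mean, dta_sd = dta_sd,
                  vpd_law = vpd_law, effect_slope = effect_slope,
                  noise_sd = noise_sd, seed = seed))
}

#' Generate a pixel table with a planted additive law
#'
#' Synthetic predictor table for the sensitivity and mediation analyses: six
#' predictors drawn standard normal (optionally correlated), response
#' `y = sum(coef_j * x_j) + noise`. The planted coefficients are the ground
#' truth the perturbation sensitivity must recover in sign (and, scaled by
#' `sd(x_j)/sd(y)`, in magnitude).
#'
#' @param n Rows (pixels).
#' @param coefs Named numeric vector of planted coefficients over the six
#'   predictor columns (`vwc`, `cwd`, `soc`, `bd`, `uwue`, `pcor_et_vpd`);
#'   missing names get 0.
#' @param noise_sd Response noise sd (default 0.3).
#' @param cross_cor Common predictor correlation (default 0).
#' @param seed Integer seed.
#' @return List: `table` (a [predictor_table()]), `truth` (list with
#'   `coefs`, `noise_sd`, `sd_y`).
#' @export
gen_predictor_table <- function(n = 2000,
                                coefs = c(vwc = 0.3, cwd = -0.4, soc = 0.3,
                                          bd = -0.3, uwue = -0.5,
                                          pcor_et_vpd = 0.5),
                                noise_sd = 0.3, cross_cor = 0, seed = 1L) {
  preds <- c("vwc", "cwd", "soc", "bd", "uwue", "pcor_et_vpd")
  full <- stats::setNames(rep(0, length(preds)), preds)
  full[names(coefs)] <- coefs
  set.seed(seed)
  x <- correlated_anomalies(n, length(preds), cross_cor)
  colnames(x) <- preds
  y <- as.vector(x %*% full) + stats::rnorm(n, 0, noise_sd)
  df <- as.data.frame(x)
  df$pcor_gpp_vpd <- y
  list(table = predictor_table(df),
       truth = list(coefs = full, noise_sd = noise_sd, sd_y = stats::sd(y)))
}

#' Generate serial-mediation data with planted standardized paths
#'
#' Draws `x ~ N(0,1)`, `m1 = a1*x + e1`, `m2 = a2*x + d21*m1 + e2`,
#' `y = c_prime*x + b1*m1 + b2*m2 + e3`, with each structural noise variance
#' solved so that every variable has unit population variance. The planted
#' coefficients are then directly the population *standardized* paths, and
#' the planted serial indirect effect is exactly `a1 * d21 * b2` on the
#' scale [serial_mediation()] estimates. The path set must be feasible: the
#' implied systematic variance of each equation has to stay below 1.
#'
#' @param n Sample size.
#' @param a1,a2,d21,b1,b2,c_prime Planted standardized path coefficients.
#' @param seed Integer seed.
#' @return List: `data` (`data.frame` x, m1, m2, y), `truth` (planted paths,
#'   `ind_m1`, `ind_m2`, `ind_serial`, `total`).
#' @export
gen_mediation_data <- function(n = 2000, a1 = 0.5, a2 = 0, d21 = 0.4,
                               b1 = 0, b2 = 0.6, c_prime = 0, seed = 1L) {
  # population covariances under unit variances
  c_xm1 <- a1
  v_m2_sys <- a2^2 + d21^2 + 2 * a2 * d21 * c_xm1
  c_xm2 <- a2 + d21 * c_xm1
  c_m1m2 <- a2 * c_xm1 + d21
  sig3 <- matrix(c(1, c_xm1, c_xm2,
                   c_xm1, 1, c_m1m2,
                   c_xm2, c_m1m2, 1), 3, 3)
  w <- c(c_prime, b1, b2)
  v_y_sys <- as.numeric(t(w) %*% sig3 %*% w)
  if (a1^2 >= 1 || v_m2_sys >= 1 || v_y_sys >= 1) {
    stop("infeasible standardized paths (systematic variance >= 1)", call. = FALSE)
  }
  set.seed(seed)
  x <- stats::rnorm(n)
  m1 <- a1 * x + stats::rnorm(n, 0, sqrt(1 - a1^2))
  m2 <- a2 * x + d21 * m1 + stats::rnorm(n, 0, sqrt(1 - v_m2_sys))
  y <- c_prime * x + b1 * m1 + b2 * m2 + stats::rnorm(n, 0, sqrt(1 - v_y_sys))
  list(data = data.frame(x = x, m1 = m1, m2 = m2, y = y),
       truth = list(a1 = a1, a2 = a2, d21 = d21, b1 = b1, b2 = b2,
                    c_prime = c_prime,
                    ind_m1 = a1 * b1, ind_m2 = a2 * b2,
                    ind_serial = a1 * d21 * b2,
                    total = c_prime + a1 * b1 + a2 * b2 + a1 * d21 * b2))
}

#' Write a generator's truth sidecar
#'
#' Every generator returns a `truth` element; this writes it as JSON next to
#' the generated data so recovery tests and pipeline audits read planted
#' values only from the sidecar, never from the generating code.
#'
#' @param truth The `truth` element of a generator result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_sidecar <- function(truth, path) {
  if (is.function(truth$rho)) truth$rho <- "function"
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
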