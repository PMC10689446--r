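#' Saturation vapor pressure of air
#'
#' Magnus-type saturation vapor pressure (SVP) over water,
#' \deqn{SVP(hPa) = 6.11 \exp\left(\frac{17.27\,Ta}{Ta + 273.3}\right),}
#' with air temperature `ta` in degrees Celsius. Strictly increasing in `ta`.
#'
#' @param ta Air temperature, deg C. Numeric vector; must be finite.
#' @return SVP in hPa, same length as `ta`.
#' @examples
#' svp(0)    # 6.11 hPa at freezing
#' svp(25)   # ~25.98 hPa
#' @export
svp <- function(ta) {
  if (!is.numeric(ta) || any(!is.finite(ta))) {
    stop("`ta` must be finite numeric (deg C)", call. = FALSE)
  }
  6.11 * exp(17.27 * ta / (ta + 273.3))
}

#' Vapor pressure deficit from temperature and relative humidity
#'
#' \deqn{VPD = SVP(Ta) \times (1 - RH/100)} in hPa. At saturation
#' (`rh = 100`) the deficit is zero.
#'
#' @param ta Air temperature, deg C.
#' @param rh Relative humidity, percent in \[0, 100\].
#' @return VPD in hPa (non-negative).
#' @seealso [vpd_from_avp()] for the actual-vapor-pressure form; the two agree
#'   through the identity `vpd_from_rh(ta, rh) == vpd_from_avp(ta, svp(ta) * rh / 100)`.
#' @examples
#' vpd_from_rh(0, 50)   # 3.055 hPa
#' @export
vpd_from_rh <- function(ta, rh) {
  if (!is.numeric(rh) || any(!is.finite(rh)) || any(rh < 0 | rh > 100)) {
    stop("`rh` must lie in [0, 100] percent", call. = FALSE)
  }
  svp(ta) * (1 - rh / 100)
}

#' Vapor pressure deficit from temperature and actual vapor pressure
#'
#' \deqn{VPD = SVP(Ta) - AVP} in hPa. Gridded humidity products occasionally
#' report `avp > svp(ta)` (apparent supersaturation); by default the negative
#' deficit is retained and flagged via an attribute rather than zeroed, so
#' that downstream means are not silently biased.
#'
#' @param ta Air temperature, deg C.
#' @param avp Actual vapor pressure, hPa (non-negative).
#' @param clip_negative If `TRUE`, negative deficits are clipped to 0.
#'   Default `FALSE`: negatives kept, their count attached as
#'   `attr(, "n_negative")`.
#' @return VPD in hPa with attribute `n_negative`.
#' @export
vpd_from_avp <- function(ta, avp, clip_negative = FALSE) {
  if (!is.numeric(avp) || any(!is.finite(avp)) || any(avp < 0)) {
    stop("`avp` must be non-negative finite numeric (hPa)", call. = FALSE)
  }
  out <- svp(ta) - avp
  n_neg <- sum(out < 0)
  if (clip_negative) out <- pmax(out, 0)
  attr(out, "n_negative") <- n_neg
  out
}

#' Aerodynamic resistance from wind speed and friction velocity
#'
#' Empirical aerodynamic resistance
#' \deqn{\gamma_a = \frac{ws \, k^2}{\left[\ln\left(e^{k\,ws/u_*} - 0.7\right)\right]^2}}
#' with the von Karman constant fixed at k = 0.4 and the natural logarithm
#' (standard in Monin-Obukhov-derived resistances). Note this form yields
#' values well below textbook canopy aerodynamic resistances for typical
#' inputs; it is applied verbatim because the inverted conductance it feeds
#' is used comparatively, not as an absolute resistance estimate.
#'
#' @param ws Wind speed, m s^-1 (> 0).
#' @param u_star Friction velocity, m s^-1 (> 0).
#' @return Aerodynamic resistance in s m^-1.
#' @examples
#' aerodynamic_resistance(3, 0.3)  # ~0.0302 s m^-1
#' @export
aerodynamic_resistance <- function(ws, u_star) {
  if (any(!is.finite(ws)) || any(ws <= 0)) stop("`ws` must be > 0", call. = FALSE)
  if (any(!is.finite(u_star)) || any(u_star <= 0)) stop("`u_star` must be > 0", call. = FALSE)
  k <- 0.4
  ex <- exp(k * ws / u_star)
  # at exp(k*ws/u_star) = 1.7 the squared log vanishes; at or below it the
  # formula degenerates
  if (any(ex <= 1.7) || any(abs(log(ex - 0.7)) < 1e-8)) {
    stop("degenerate input: exp(k*ws/u_star) must exceed 1.7", call. = FALSE)
  }
  arg <- ex - 0.7
  (ws * k^2) / log(arg)^2
}

#' Physical constants for the Penman-Monteith inversion
#'
#' The inversion needs the SVP slope, psychrometric constant and air density,
#' which are computed from air temperature and pressure rather than tabulated:
#' * `delta` — analytic derivative of the Magnus SVP curve, Pa K^-1;
#' * `gamma` — `cp * p / (0.622 * lambda_v)`, Pa K^-1;
#' * `rho` — dry-air ideal gas law at (Ta, p), kg m^-3.
#'
#' `lambda_v` defaults to 2.44e6 J kg^-1 for internal consistency with
#' [et_from_le()].
#'
#' @param ta Air temperature, deg C.
#' @param pressure Atmospheric pressure, kPa. Default 101.325 (sea level).
#' @param cp Specific heat of air at constant pressure, J kg^-1 K^-1.
#' @param lambda_v Latent heat of vaporization, J kg^-1.
#' @return List with elements `delta`, `gamma`, `rho`, `cp`, `k`,
#'   `lambda_v` (k is the von Karman constant, always 0.4).
#' @export
phys_constants <- function(ta, pressure = 101.325, cp = 1013,
                           lambda_v = 2.44e6) {
  p_pa <- pressure * 1000
  svp_pa <- 100 * svp(ta)
  delta <- svp_pa * 17.27 * 273.3 / (ta + 273.3)^2
  gamma <- cp * p_pa / (0.622 * lambda_v)
  rho <- p_pa / (287.05 * (ta + 273.15))
  list(delta = delta, gamma = gamma, rho = rho, cp = cp, k = 0.4,
       lambda_v = lambda_v)
}

#' Canopy conductance by Penman-Monteith inversion
#'
#' Bulk canopy (surface) conductance obtained by rearranging the
#' Penman-Monteith equation around eddy-covariance fluxes:
#' \deqn{G_c = \left[\left(\frac{\Delta}{\gamma}\frac{H}{LE} - 1\right)\gamma_a
#'   + \frac{\rho C_p}{\gamma}\frac{VPD}{LE}\right]^{-1}.}
#' Inversion of noisy fluxes routinely produces non-physical (non-positive)
#' bracket values; those are returned as `NA` and counted in the
#' `n_rejected` attribute — never clipped, since clipping biases means.
#'
#' @param le Latent heat flux, W m^-2 (non-zero).
#' @param h Sensible heat flux, W m^-2.
#' @param vpd Vapor pressure deficit, hPa (> 0).
#' @param ws Wind speed, m s^-1.
#' @param u_star Friction velocity, m s^-1.
#' @param ta Air temperature, deg C (for `Delta`, `rho`).
#' @param pressure Atmospheric pressure, kPa.
#' @param constants Optional list as returned by [phys_constants()]; computed
#'   from `ta` and `pressure` when `NULL`.
#' @return Canopy conductance in mm s^-1, `NA` where non-physical, with
#'   attribute `n_rejected`.
#' @export
canopy_conductance <- function(le, h, vpd, ws, u_star, ta,
                               pressure = 101.325, constants = NULL) {
  if (any(le == 0, na.rm = TRUE)) stop("`le` must be non-zero", call. = FALSE)
  if (any(vpd <= 0, na.rm = TRUE)) stop("`vpd` must be > 0 (hPa)", call. = FALSE)
  cs <- if (is.null(constants)) phys_constants(ta, pressure) else constants
  ra <- aerodynamic_resistance(ws, u_star)
  vpd_pa <- 100 * vpd
  bracket <- (cs$delta / cs$gamma * h / le - 1) * ra +
    (cs$rho * cs$cp / cs$gamma) * vpd_pa / le
  bad <- !is.finite(bracket) | bracket <= 0
  gc_ms <- ifelse(bad, NA_real_, 1 / bracket)
  out <- gc_ms * 1000  # m s^-1 -> mm s^-1
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Forward Penman-Monteith latent heat flux
#'
#' Standard big-leaf Penman-Monteith evaporation at known surface conductance:
#' \deqn{LE = \frac{\Delta A + \rho C_p VPD / \gamma_a}
#'   {\Delta + \gamma (1 + r_c/\gamma_a)}}
#' with `r_c = 1/G_c`. This is the generative counterpart of
#' [canopy_conductance()]: inverting fluxes produced here recovers the
#' conductance used to produce them, which anchors the round-trip tests.
#'
#' @param gc Canopy conductance, mm s^-1 (> 0).
#' @param available_energy Available energy `A = H + LE`, W m^-2.
#' @param vpd Vapor pressure deficit, hPa.
#' @param ws,u_star Wind speed and friction velocity, m s^-1.
#' @param ta Air temperature, deg C.
#' @param pressure Atmospheric pressure, kPa.
#' @return List with `le` and `h` (W m^-2).
#' @export
penman_monteith_le <- function(gc, available_energy, vpd, ws, u_star, ta,
                               pressure = 101.325) {
  if (any(gc <= 0)) stop("`gc` must be > 0 (mm s^-1)", call. = FALSE)
  cs <- phys_constants(ta, pressure)
  ra <- aerodynamic_resistance(ws, u_star)
  rc <- 1 / (gc / 1000)  # mm s^-1 -> m s^-1 -> s m^-1
  vpd_pa <- 100 * vpd
  le <- (cs$delta * available_energy + cs$rho * cs$cp * vpd_pa / ra) /
    (cs$delta + cs$gamma * (1 + rc / ra))
  list(le = le, h = available_energy - le)
}

#' Evapotranspiration mass flux from latent heat flux
#'
#' Converts latent heat flux (W m^-2) to a water mass flux (kg H2O m^-2 s^-1)
#' by dividing by the latent heat of vaporization. The conversion coefficient
#' is 2.44; its physical unit is MJ kg^-1, so the default divides by 2.44e6.
#' A literal mode (`coeff_scale = "J"`, dividing by 2.44) is provided for
#' compatibility with analyses that applied the coefficient on the printed
#' scale; the choice rescales ET (and hence uWUE) by a constant and does not
#' affect correlation-based results.
#'
#' @param le Latent heat flux, W m^-2.
#' @param coeff Latent heat coefficient, default 2.44.
#' @param coeff_scale `"MJ"` (default, divide by `coeff * 1e6`) or `"J"`
#'   (divide by `coeff`).
#' @return ET in kg H2O m^-2 s^-1.
#' @export
et_from_le <- function(le, coeff = 2.44, coeff_scale = c("MJ", "J")) {
  coeff_scale <- match.arg(coeff_scale)
  if (any(!is.finite(le))) stop("`le` must be finite", call. = FALSE)
  le / (coeff * switch(coeff_scale, MJ = 1e6, J = 1))
}

#' Underlying water-use efficiency
#'
#' \deqn{uWUE = \frac{GPP \sqrt{VPD}}{ET}} in g C kPa^0.5 kg^-1 H2O.
#' A high uWUE marks a conservative "reduce expenditure" water-use strategy
#' (stomata close early under drying air); a low uWUE marks an "open"
#' strategy. **VPD must be supplied in kPa** — most of this package works in
#' hPa, so divide by 10 at this call; the unit is asserted via the
#' `vpd_unit` tag to make accidental hPa input a hard error.
#'
#' @param gpp Gross primary productivity, g C m^-2 per period.
#' @param vpd Vapor pressure deficit in kPa.
#' @param et Evapotranspiration, kg H2O m^-2 per period (> 0).
#' @param vpd_unit Must be `"kPa"`; a guard against the hPa/kPa mix-up.
#' @return uWUE; `NA` where `et <= 0`.
#' @examples
#' uwue(3, 0.25, 1.5)  # 1.0
#' @export
uwue <- function(gpp, vpd, et, vpd_unit = "kPa") {
  if (!identical(vpd_unit, "kPa")) {
    stop("`uwue()` takes VPD in kPa; convert hPa with vpd/10", call. = FALSE)
  }
  if (any(vpd < 0, na.rm = TRUE)) stop("`vpd` must be >= 0", call. = FALSE)
  ifelse(et > 0, gpp * sqrt(vpd) / et, NA_real_)
}

#' Growing-season mask from monthly air temperature
#'
#' A month belongs to the growing season when its mean air temperature is
#' strictly above 0 deg C. With `climatology = TRUE` the mask is computed per
#' calendar month from the multi-year mean temperature and recycled across
#' years, so every year shares one season definition.
#'
#' @param monthly_ta Numeric vector of monthly mean temperatures, deg C. Its
#'   length must be a multiple of 12 when `climatology = TRUE`.
#' @param climatology Use multi-year per-calendar-month means (default
#'   `FALSE`: each month judged on its own value).
#' @return Logical vector, `TRUE` in growing-season months.
#' @examples
#' growing_season_mask(c(-5, 0, 1))  # FALSE FALSE TRUE
#' @export
growing_season_mask <- function(monthly_ta, climatology = FALSE) {
  if (!is.numeric(monthly_ta)) stop("monthly series required", call. = FALSE)
  if (!climatology) return(monthly_ta > 0)
  if (length(monthly_ta) %% 12 != 0) {
    stop("climatology mode needs whole years of monthly data", call. = FALSE)
  }
  m <- matrix(monthly_ta, nrow = 12)
  clim <- rowMeans(m, na.rm = TRUE)
  rep(clim > 0, length.out = length(monthly_ta))
}
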