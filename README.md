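# peatvpd

Does rising atmospheric dryness suppress plant growth when the air dries
because of warming alone? In most of the world, vapor pressure deficit (VPD)
increases through the combination of warming and falling relative humidity,
and vegetation indices respond negatively. Northern peatlands are different:
their wet, moss-dominated surfaces keep relative humidity roughly constant, so
VPD rises through temperature alone — and the vegetation response there is a
live scientific question. `peatvpd` implements the full analysis chain used to
ask that question, from raw meteorology to attribution modelling, together
with synthetic-data generators with known ground truth so every stage can be
validated without multi-gigabyte climate archives.

The package is aimed at ecosystem ecologists and eco-climate analysts working
with gridded climate/productivity products, eddy-covariance towers, or
warming-experiment syntheses.

## What it computes

**Ecophysiological primitives.** Saturation vapor pressure
`SVP = 6.11·exp(17.27·Ta/(Ta+273.3))` hPa and VPD from either relative
humidity (`SVP·(1−RH/100)`) or actual vapor pressure (`SVP−AVP`);
growing-season masks (months with mean Ta > 0 °C); underlying water-use
efficiency `uWUE = GPP·√VPD/ET` (g C kPa^0.5 kg⁻¹ H₂O), a proxy for plant
water-use strategy; and bulk canopy conductance by inverting the
Penman–Monteith equation around measured fluxes:

```
Gc = [ (Δ/γ · H/LE − 1)·γa + (ρ·Cp/γ)·VPD/LE ]⁻¹
```

with the matching forward model so inversion can be verified by round trip.

**Detrended partial-correlation mapping.** Per-pixel linear trends
(`y = β0 + β1·t`), detrending, and the partial correlation of GPP with VPD
conditional on temperature, radiation, wind speed and precipitation
(two-sided t-test, df = n − 2 − g). Maps are summarised as regional mean
coefficients and four-way sign × significance percentages, stratified along
peatland-extent bins (10–20 % … >70 %) and by aridity class (nonhumid
AI < 0.65, humid AI ≥ 0.65).

**Warming-experiment analysis.** Paired t-tests with Shapiro–Wilk normality
screening (Wilcoxon signed-rank fallback), exponential temperature–VPD fits
`VPD = a·exp(b·Ta)`, simulated VPD contrasts between control and warming
treatments, and the regression of growth responses (log response ratios) on
the per-site VPD increase — the "neutral effect" question is whether that
slope's CI covers zero.

**Attribution.** A random-forest model of the pixel-level GPP–VPD partial
correlation as a function of six predictors (VWC, CWD, SOC, BD, uWUE, and
the Et–VPD partial correlation), with a one-standard-deviation perturbation
sensitivity (15 repeats, median, response-sd normalised); and serial
two-mediator mediation models (X → uWUE → Et–VPD coupling → VPD effect) with
percentile-bootstrap intervals.

**Synthetic data.** Seeded generators for gridded cubes with a planted
conditional correlation (optionally a function of peatland extent), forward
Penman–Monteith flux towers with known conductance, warming-experiment
syntheses with a planted effect slope, predictor tables with planted additive
laws, and mediation data with planted standardized paths. Every generator
records its truth for recovery testing.

## Worked example

```r
library(peatvpd)

# synthetic study region: 37 years, planted GPP~VPD partial correlation 0.07
g <- gen_gridded(grid_gen_config(n_lat = 10, n_lon = 20, seed = 42))
m <- pcor_map(g$cubes$gpp, g$cubes$vpd,
              list(g$cubes$ta, g$cubes$radiation, g$cubes$wind, g$cubes$precip))
region_summary(m, label = "all pixels")
#> region [all pixels]: mean r = 0.073 over 200 px | Neg* 0.5% Neg 30.0% Pos 63.5% Pos* 6.0%

# inverted canopy conductance from a synthetic tower (true Gc = 6 mm/s)
fx <- gen_flux_tower(flux_gen_config(seed = 1))$data
gc <- canopy_conductance(fx$le, fx$h, fx$vpd, fx$ws, fx$ustar, fx$ta)
round(median(gc, na.rm = TRUE), 2)
#> [1] 5.96

# neutral warming synthesis: growth response vs simulated VPD increase
w <- gen_warming_sites(seed = 1)$sites
vpd_effect_regression(growth_response(w$growth_c, w$growth_w),
                      synthesis_vpd_delta(w))
#> growth response ~ dVPD: slope = -0.545 +/- 0.337 (p = 0.11, n = 67, 95% CI [-1.218, 0.127])
```

The regional mean coefficient comes back near the planted 0.07 with most
pixels insignificantly positive; the inverted conductance matches the
generator's 6 mm s⁻¹ within flux-noise scatter; and the planted-zero warming
synthesis yields a slope whose confidence interval covers zero — the neutral
VPD effect.

`run_pipeline()` chains all stages from a YAML/list config into a directory
of CSV/JSON artifacts plus a manifest of seeds and checksums.

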