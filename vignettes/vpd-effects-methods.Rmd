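---
title: "Methods: quantifying VPD effects on vegetation growth in northern peatlands"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying VPD effects on vegetation growth in northern peatlands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peatvpd)
```

## The scientific problem

Vapor pressure deficit (VPD) — the gap between saturation and actual water
vapor pressure — is the atmosphere's drying power. When VPD rises, plants
usually close stomata to avoid xylem tension, sacrificing carbon uptake, and
large-scale productivity indices respond negatively. But VPD can rise by two
distinct routes: concurrent warming and drying of the air (the dominant
global pattern), or warming alone at roughly constant relative humidity,
which is what wet, moss-covered northern peatlands experience. `peatvpd`
implements a chain of analyses for separating these regimes and for asking
whether warming-driven VPD increases suppress growth where the surface can
keep resupplying atmospheric moisture: closed-form ecophysiology, per-pixel
detrended partial correlation, warming-experiment statistics, a
machine-learning sensitivity analysis, and mediation modelling, all
validated against synthetic data with planted truth.

## Meteorological and ecophysiological primitives

Saturation vapor pressure uses a Magnus-type formula anchored at
6.11 hPa at 0 °C, `SVP = 6.11·exp(17.27·Ta/(Ta+273.3))`. VPD follows either
as `SVP·(1 − RH/100)` or as `SVP − AVP`; the two are algebraically
identical when `AVP = SVP·RH/100`, and the test-suite holds them to machine
precision on a 10^4-point grid. VPD is carried in hPa everywhere internally;
the one surface that requires kPa — underlying water-use efficiency — takes
a `vpd_unit` tag and rejects anything else, because silent hPa/kPa mixing is
the leading failure mode in this kind of pipeline. Apparent supersaturation
(`AVP > SVP`, which gridded humidity products do produce) is retained and
flagged rather than clipped to zero, so regional means are not biased.

Canopy conductance comes from inverting the Penman–Monteith equation around
eddy-covariance fluxes,

$$G_c = \left[\left(\frac{\Delta}{\gamma}\frac{H}{LE} - 1\right)\gamma_a +
\frac{\rho C_p}{\gamma}\frac{VPD}{LE}\right]^{-1},$$

with the aerodynamic resistance
$\gamma_a = ws\,k^2 / \ln\!\big(e^{k\,ws/u_*} - 0.7\big)^2$, k = 0.4, and the
natural logarithm (the standard choice in Monin–Obukhov-derived
resistances). Two numerical honesty points. First, this resistance formula
produces values far below textbook canopy aerodynamic resistances
(≈0.03 s m⁻¹ at ws = 3 m s⁻¹, u\* = 0.3 m s⁻¹); it is implemented verbatim
and documented rather than "fixed", because the conductances it feeds are
used comparatively. A practical consequence is that the VPD term dominates
the bracket, so inverted conductance inherits flux noise roughly
proportionally. Second, inversion of noisy fluxes routinely drives the
bracket non-positive; those values are returned as missing and counted
(`n_rejected`), never clipped.

The supporting constants are not tabulated but computed: Δ as the analytic
derivative of the SVP curve (Pa K⁻¹), γ = Cp·P/(0.622·λv), and ρ from the
ideal gas law at (Ta, P). λv defaults to 2.44 MJ kg⁻¹ so that the LE→ET
conversion (`et_from_le`, dividing by 2.44 × 10⁶ J kg⁻¹ by default) and γ
share one latent-heat value. A literal mode dividing by 2.44 exists for
compatibility with analyses that applied the coefficient on a different
scale; the choice rescales ET by a constant and cannot affect
correlation-based results. The forward Penman–Monteith model is shipped
alongside the inversion, and a round-trip test (forward at known Gc, then
invert) holds to relative error below 1e−10 on 1,000 random met/flux draws.

The growing season is defined as months with mean air temperature strictly
above 0 °C, either month-by-month or from a multi-year climatology recycled
across years.

## Detrended partial-correlation mapping

The effect of VPD on gross primary productivity (GPP) is measured per pixel
as the partial correlation between detrended GPP and detrended VPD,
conditional on detrended temperature, radiation, wind speed and
precipitation. Detrending (OLS residuals against time) removes the shared
secular trends that would otherwise masquerade as sensitivity — a dedicated
test demonstrates the inflation when detrending is skipped on co-trending
series. The partial correlation is computed from the precision matrix of the
variable block, which is algebraically the correlation of the two
covariate-regression residual series; the test-suite checks the two routes
against each other to 1e−12. Significance is a two-sided t-test with
df = n − 2 − g. No multiple-testing correction is applied across pixels:
maps report raw p < 0.05, and the type-I-error calibration test verifies
the pixel-level rejection rate is ≈5% under a null generator.

Analyses run on annual growing-season aggregates, so the per-pixel sample
size is the year span (37 for 1982–2018). Annual resolution was chosen
because trends are naturally reported per year and the t-test degrees of
freedom then match year counts; the mapping functions accept any strictly
increasing time axis, so monthly-anomaly inputs work unchanged. Pixels need
80% of time steps present (configurable) or they are masked.

Regional aggregation reports the mean coefficient and the four-way
partition of pixels by sign × significance, with the measure-zero tie
r = 0 deterministically counted as positive. Peatland-extent stratification
uses left-closed bins at 10, 20, …, 70% with a closed terminal bin to 100%,
plus the ≥10% union; aridity stratification splits at AI = 0.65 with the
boundary value humid. Regional means are unweighted by default; a
cos-latitude weighting flag exists because the choice is not determined by
the method. Tower/grid agreement is summarised as the percentage of matched
coefficient signs plus the correlation of the coefficient vectors.

## Warming-experiment analysis

Treatment effects on temperature, humidity and VPD are paired t-tests on
warming-minus-control differences, screened by Shapiro–Wilk; when the
differences fail normality at p ≤ 0.05 a Wilcoxon signed-rank result is
attached (the 0.05 trigger is a package choice — any normality screen needs
a threshold, and 0.05 matches the test level used everywhere else).
Zero-variance differences make the t statistic undefined and are reported
as degenerate rather than silently dropped.

The temperature–VPD relationship is fitted as `VPD = a·exp(b·Ta)` by OLS on
log VPD — deterministic and closed-form, with a nonlinear least-squares
refinement behind a flag; the reported r is the correlation of fitted and
observed VPD on the original scale. The fitted law simulates the VPD
contrast for experiments that measured temperature but not humidity;
sites reporting RH are converted through the deficit formula, and sites
reporting VPD pass through. Per-site fits are the default (a pooled-fit
mode exists) since temperature–humidity coupling varies across sites.
Growth responses default to log response ratios, with raw-ratio and
difference modes available. The cross-site regression of response on VPD
contrast is plain OLS; "neutral effect" means its 95% CI covers zero.

## Random-forest perturbation sensitivity

The pixel-level GPP–VPD partial correlation is modelled with a random
forest over six predictors: available volumetric water content (VWC, %),
climate water deficit (CWD, mm), soil organic carbon (SOC, %), bulk density
(BD, g cm⁻³), uWUE, and the Et–VPD partial correlation. The model trains on
a random 60% of pixels and is validated by Pearson r on the held-out 40%;
sensitivities carry an interpretation gate of r > 0.8. Forest
hyperparameters are 500 trees with default feature subsampling, seeded —
unremarkable values, configurable.

Sensitivity of the response to predictor j perturbs the z-score-normalized
predictor by +1 (one standard deviation), re-predicts, and divides the mean
prediction change by the standard deviation of the raw (non-normalized)
response; this is repeated 15 times and the median taken. What varies
across repeats is bootstrap resampling of the prediction rows with the
model fixed (a refit-per-repeat mode exists); the perturbation is +1 SD,
with a symmetric ±1 SD averaged mode available. The raw-scale denominator
makes the measure scale-free in the response, which a rescaling test
asserts. On planted additive laws the procedure recovers coefficient signs
essentially always and magnitudes attenuated by roughly 10–15% — tree
ensembles flatten at the edge of the training distribution, so a
sensitivity of 1.0 is recovered as ≈0.85–0.95; sign and ordering, which is
what the analysis interprets, are robust. Partial-dependence-style profiles
expose the monotonicities; for predictors absent from the generative law
the profile is flat over the bulk of the range, though the extreme tails
are constrained by few training rows.

## Serial mediation

How water availability and soil hydraulics act on VPD effects through plant
water-use strategy is modelled as a serial two-mediator chain
X → M1 → M2 → Y with M1 = uWUE and M2 = the Et–VPD coupling (that ordering
is the drawn causal chain; it is configurable). Three OLS regressions on
z-standardized variables give paths a1, a2, d21, b1, b2 and the direct
effect; indirect effects are path products, and the decomposition
`c = c′ + a1·b1 + a2·b2 + a1·d21·b2` is an exact OLS identity the tests
hold to 1e−10. Uncertainty is a seeded percentile bootstrap (default 5,000
resamples; tests and pipeline use fewer), with significance read as the CI
excluding zero. Pixels are treated as exchangeable rows — no spatial
blocking — matching how such grids are usually analysed; that understates
uncertainty in the presence of spatial autocorrelation, which is a known
limitation, not a bug.

## The synthetic generators

The generators produce data with the statistical structure the analyses
assume, and nothing more: they are the package's ground-truth instrument,
not a climate emulator.

* `gen_gridded` builds annual growing-season cubes for 1982–2018 on a
  lat/lon grid. Temperature is baseline + trend + Gaussian noise, with the
  default trend 0.028 °C yr⁻¹ and essentially flat relative humidity — the
  warming-alone regime. VPD follows `a·exp(b·Ta)` with lognormal noise;
  defaults a = 2 hPa, b = 0.07 °C⁻¹ put implied RH near 65–75%, a realistic
  boreal range (an RH-trend knob applies the first-order adjustment
  −SVP·ΔRH/100). RH is recovered by exact inversion, with resampling of
  draws that would imply supersaturation. The GPP anomaly is built from the
  detrended, covariate-residualized, standardized VPD anomaly `u` as
  `ρ·u + √(1−ρ²)·e + Σβ_j z_j`, with `e` residualized into the same space —
  this makes the planted ρ exactly the population conditional correlation
  the mapping estimates, which the recovery tests confirm (ρ = 0 gives ≈5%
  rejections; ρ = 0.3 comes back within ±0.05 at 200 pixels). ρ defaults to
  0.07, the weakly-positive peatland regime, and may be a function of the
  peatland-extent field to plant gradients. Covariate anomalies share a 0.3
  cross-correlation so conditioning is exercised nontrivially.
* `gen_flux_tower` drives the forward Penman–Monteith model at known
  conductance through a seasonal meteorology, partitions available energy,
  and derives GPP from a configured uWUE law (default 1.23, a wet-peatland
  scale), so both the conductance inversion and the uWUE computation have
  exact targets. Flux noise is multiplicative lognormal, default 5%.
* `gen_warming_sites` emulates a 67-site synthesis: control temperatures
  N(8, 3) °C, warming offsets N(2.7, 1.0) °C, VPD from the exponential law
  in both treatments, and log response ratios `slope·ΔVPD + noise` with the
  planted slope defaulting to 0 (the neutral scenario). The response noise
  (sd 0.8) sizes the regression slope standard error near 0.27 so the
  simulated synthesis has the statistical texture of a real multi-site
  compilation of that size.
* `gen_predictor_table` and `gen_mediation_data` plant additive laws and
  standardized path models; the mediation generator solves each structural
  noise variance so every variable has unit population variance, making the
  planted coefficients exactly the standardized paths the estimator reports
  (e.g. the default serial product 0.5·0.4·0.6 = 0.12).

Every generator takes a mandatory seed, never touches global RNG state
beyond `set.seed`, and records its planted truth (`write_truth_sidecar`
serialises it to JSON) so recovery tests read truth from data, not code.

What the generators deliberately do not emulate: spatial autocorrelation,
non-Gaussian climate extremes, missing-data patterns of real satellite
products, disturbance history, or CO₂ fertilization. Passing recovery tests
therefore demonstrates that the estimators are correct and calibrated under
the stated statistical structure — not that real-world attribution is free
of confounding.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use deliberately modest problem
sizes chosen to exercise each property with adequate Monte-Carlo power:
2,500 pixels × 37 years for test size, 200 pixels for recovery, 1,600
pixels for the extent-ramp monotonicity (steep enough that bin-level noise
cannot reorder bins), 1,000 draws for round trips, 50 forest replicates at
1,000 pixels for sign recovery, and 200 mediation replicates at n = 300
with 500 bootstrap resamples for interval coverage. `run_pipeline()` writes
a manifest (package version, seed, config hash, artifact checksums) and
reruns of the same configuration are bit-identical.

## Known limitations

Nearest-neighbour grid alignment only (no regridding engine); no spatial
autocorrelation correction in either the significance maps or the
bootstrap; no energy-balance closure correction or gap-filling for fluxes;
no meta-analytic variance weighting in the warming synthesis; and the
mediation model is a linear path decomposition, not causal discovery —
its "effects" inherit the usual observational caveats.
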