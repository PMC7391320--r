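---
title: "Detecting trophic cascades from long-term reef monitoring series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting trophic cascades from long-term reef monitoring series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the method

Whether exploited reef ecosystems are governed from the top of the food web
(consumer-driven, "top-down") or from its base (resource-driven,
"bottom-up") can be read off long-term monitoring data in two complementary
ways:

1. **Forcing diagnosis by correlation sign.** For two adjacent trophic
   groups (predators and herbivores; herbivores and algae), the Pearson
   correlation between their annual density series at a location is positive
   when the groups rise and fall together — consistent with bottom-up
   forcing — and negative when they oppose each other — consistent with
   top-down forcing.
2. **Cascade detection by alternating trends.** A community-level trophic
   cascade signal is declared at a location when all three trophic groups
   change significantly over time with adjacent groups trending in opposite
   directions (predators up, herbivores down, algae up — or the mirror
   image), *conditional on* a statistically significant predator trend: only
   a real change at the top could propagate downward.

`reeftrends` implements both diagnostics over a hierarchical survey design
(transects within sites within locations), plus the cross-location models
that relate them to latitude and exploitation status, and a synthetic
tri-trophic data generator used to calibrate and stress-test the whole
chain. The `analysis/` scripts run the stages in order
(simulate, aggregate, trends, cascades, models); every computation they
perform lives in the package and is unit-tested.

## Data model and aggregation

The input is a long survey table: one row per transect-level trophic-group
total (`density` for predators and herbivores, `percent_cover` for algae) at
a site, year, and location, plus a location table with signed latitude
(negative south, so the equator sits at zero and "temperate left, tropics
right" axes emerge naturally) and one of four exploitation categories:
`early_reserve` (monitored from reserve implementation), `late_reserve`
(monitoring began 11–16 years after implementation), `always_fished`, and
`newly_fished`. Reserve locations start their trend window at the
implementation year; fished locations in the same geographic area use the
matched start year, supplied as `analysis_start_year`, to control for shared
temporal factors.

Aggregation follows the survey design: transect totals are averaged within
site and year, then site means are averaged (unweighted — no site-area
information exists) within location and year. Site is the unit of
replication because contiguous transects are not independent. Years with no
surveyed site are simply absent; nothing is imputed. Temperate percent cover
is a three-dimensional benthos-to-canopy measure and may exceed 100%; it is
deliberately not capped, since all comparisons are within-location.

Because density metrics differ between monitoring programs and groups, each
location × group series is standardized to mean 0 and sample standard
deviation 1 before trend fitting. The standardization constants are computed
from the **location-level annual means** and then applied to the site-level
values that serve as regression replicates, so replicates and series share a
scale. Whether the constants come from annual means or pooled site values is
immaterial downstream — Pearson correlations and t/p-values are invariant to
positive linear rescalings — and the test suite asserts exactly that
invariance. A constant series (zero variance across years) cannot be
standardized; it is flagged and its trend reported as zero and
non-significant rather than dropped.

A validator reports, per series, the number of yearly time points (at least
3 required), the number of site-by-year surveys (at least 12), constancy,
and uneven site sampling. It reports rather than excludes: exclusion
decisions stay visible to the analyst.

## Trend models

**OLS.** Standardized site-year values are regressed on centered calendar
year; the slope is tested two-sided at α = 0.05 with `n − 2` degrees of
freedom. No multiple-testing correction is applied — the downstream
excess-over-chance summary explicitly interprets counts of significant
trends against the per-test α. An exactly collinear series (zero residual
variance) is reported significant with p = 0 and an `exact_fit` flag; it
cannot arise under the continuous generator but can under hand-made inputs.

**AR(1) variant.** Year-to-year dependence makes OLS anti-conservative, so
a generalized least-squares variant places the autocorrelation where it
belongs: sites are nested within year, all observations of year *t* share a
latent year effect, and year effects decay as `rho^|t − s|` on top of
independent observation noise,

```
Sigma = sigma_y^2 * rho^|t_i - t_j| + sigma_e^2 * I .
```

No packaged correlation structure expresses "AR(1) across whole years with
site replicates inside each year plus a nugget", so the Gaussian likelihood
is written out and maximized directly, with `rho` bounded to [0, 0.95] and
the regression coefficients profiled out by GLS at each candidate
covariance. Two numerical choices matter:

- **REML, not unrestricted ML.** With the short series typical of this
  design (3–19 yearly points) and an estimated intercept and trend,
  unrestricted ML shrinks `rho` severely: in our Monte-Carlo checks at
  T = 19 and true `rho = 0.6`, ML centered near 0.32 (and `nlme::gls` ML
  reproduces the same value, confirming the likelihood implementation),
  while REML centers near 0.51. The package therefore uses the REML
  criterion, which is also the convention of the standard GLS tooling.
- **Applicability.** The structure requires the same site set in every
  year; uneven sampling returns an explicit not-applicable result, and the
  OLS call stands. Optimizer failure falls back to OLS with
  `converged = FALSE` recorded.

The two approaches agree overwhelmingly in slope sign on realistic data;
the acceptance suite checks ≥ 95% agreement on the default synthetic
dataset. Trend significance is read from the slope t test (for simple
regression this coincides with the test of the Pearson coefficient).

## Pair correlations and Fisher z

Adjacent-pair coefficients are computed between the two groups'
standardized **annual series** on their common years (at least 3), not
between fitted slopes — the series trajectories carry the year-to-year
covariation that the forcing diagnosis needs, and r is scale-invariant so
standardization does not affect it. For cross-location regression the
coefficients are mapped to Fisher's z = atanh(r), approximately normal with
variance 1/(n − 3), and weighted by the inverse variance. A 3-year overlap
has undefined variance and weight 0: such pairs are excluded from weighted
fits and counted. The toggle `min_years_weighted = 3` instead assigns them
unit weight so every location enters, mimicking fully inclusive behaviour
(an F statistic with 102 denominator degrees of freedom over 104 locations
implies such inclusivity); the default stays at 4 because an undefined
variance has no principled weight. Fitted z curves and their normal-theory
95% bands are mapped back through tanh for presentation, which keeps them
inside [−1, 1] by construction.

## Cascade classification and prevalence

`classify_location()` is a pure function of the three trend calls:
`alternating` requires the predator prerequisite, all three groups
significant, and opposite adjacent signs; both sign patterns (`P+H-A+`,
`P-H+A-`) qualify because the criterion is symmetric, even though published
field cases have involved increasing predators. Locations where predators
and herbivores oppose significantly but algae does not respond are tallied
separately as `partial_alternating`. Prevalence tables report counts and
the percentage of alternating locations among predator-significant ones —
exactly, plus an integer-rounded display figure; a group with no
predator-significant locations has an undefined percentage, not 0%.
`excess_over_chance()` compares the number of significant predator trends
with `n_tests × α`.

## Cross-location models

- **Fisher-z on latitude:** weighted linear regression as above, on signed
  latitude (the study system is single-hemisphere, so signed and absolute
  latitude are monotone equivalents; signed is used).
- **Trend slopes on covariates:** per trophic group, the standardized slope
  is regressed on latitude and, separately, on exploitation status,
  weighted by `1/se(slope)^2`; weighted category means with normal 95%
  intervals accompany the factor model.
- **Cascade occurrence:** a binomial GLM with logit link over the
  predator-significant subset, `alternating ~ latitude +
  exploitation_status`, treatment contrasts with `always_fished` as
  reference. Complete separation is detected and flagged, not corrected;
  categories with fewer than 5 locations trigger a warning.
- **Backward stepwise selection:** from the full model, among terms with
  p > 0.05 (multi-level factors tested as a block — likelihood-ratio for
  GLMs, F for linear models, since per-level Wald p-values cannot justify
  dropping a factor), the term whose removal lowers AIC most is dropped and
  the model refitted, until all remaining terms are significant or no
  removal lowers AIC. The trace of every step is returned; an
  intercept-only endpoint is valid.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes, not
reef dynamics. For group *g* at a location, the latent log mean in year *t*
is `alpha_g + beta_g * t_c + u_{g,t}` with centered year `t_c`; `u` is a
stationary AR(1) year effect shared by all sites that year (matching the
AR(1) model's year nesting); site offsets and transect noise are added and
the result exponentiated, so densities are positive by construction and the
per-series standardization makes the latent scale immaterial downstream.
Slopes come from the forcing regime: `(b, −λb, λ²b)` for a top-down
cascade (alternating signs, attenuating down the chain), `(λ²b, λb, b)`
all-positive for bottom-up, zeros for the null, iid Normal for the
`independent` regime. The herbivore–algae innovations can be correlated
(`ha_noise_cor`) to impose an adjacent-pair correlation that is not
mediated by trends, which is how the latitude-gradient recovery experiment
builds correlations drifting from +0.4 (tropical) to −0.4 (temperate).

Defaults are the package's own calibration choices (the source data carry
no published variance components) and are fixed once: `b = 0.2` per
centered year, attenuation `λ = 0.8`, `rho = 0.2`, `sigma_year = 0.15`,
`sigma_site = 0.3`, `sigma_obs = 0.2`; 104 locations (60 tropical at
14–24° S, 44 temperate at 28–43.5° S) with exploitation categories in
36/15/50/3 proportions and all late reserves tropical; series of 5–19
yearly points over 3–8 sites with 5 transects. Four locations carry the
cascade regime (three temperate, one tropical) and twenty the bottom-up
regime (16 tropical, 4 temperate), so that genuine predator trends
concentrate where the motivating study found them (~17 tropical and ~7
temperate) and cascade prevalence is temperate-skewed while exploitation is
unrelated to it. Per-location substreams are drawn from the master seed, so
datasets are byte-identical under a fixed seed and a ground-truth ledger
(regime, true slopes, realized year effects) accompanies every dataset for
recovery tests.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: coupled consumer–resource dynamics (the
regimes impose trends; nothing feeds back), species composition and
functional redundancy within groups, observation error that differs between
diver-census programs, missing years, and spatial correlation between
nearby locations. The null-calibration checks deserve a caveat of their
own: with hierarchical year/site variance present, the per-test level of
the site-replicate OLS t test is only approximate (shared year effects make
replicates non-independent — in the source methodology as much as here), so
the 5%-level calibration is asserted under an iid-noise configuration
(`sigma_year = sigma_site = 0`), where it is exact.

## Problem sizes and numerical tolerances

The test and acceptance suites run at deliberately chosen scales: the
study-scale default dataset (104 locations, 312 series) for end-to-end
properties; 1,000 null locations for the 5% calibration band (three
binomial standard errors); 10,000 null locations for the
alternating-false-positive ceiling (≤ 0.001; the theoretical rate is
roughly `2 α³/4 ≈ 6×10⁻⁵` at α = .05); 60-location batches for regime
recovery; 20 replicates for the latitude-gradient and stepwise-selection
experiments; 200 Monte-Carlo replicates for AR(1) `rho` recovery.
Closed-form oracles (normal equations, atanh, the logit MLE, GLM score
equations) are matched to 1e−10/1e−12/1e−8. Equality of standardized-series
moments is asserted to 1e−10.

## Known limitations

- Density, not biomass: trends in numbers can lag or understate biomass
  responses.
- The alternating-trend criterion is conservative by design (three
  simultaneous significance tests plus a sign pattern); its power at short
  series lengths is low, which is why the regime-recovery experiments use
  T ≥ 15.
- Separation in the cascade GLM is flagged but not penalized (no Firth
  correction), matching the scope of the original modelling.
- The AR(1) year-effect model assumes even site sampling; uneven designs
  fall back to OLS only.
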