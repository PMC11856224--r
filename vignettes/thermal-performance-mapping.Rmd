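---
title: "Thermal performance modeling and climate suitability mapping with epftherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal performance modeling and climate suitability mapping with epftherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epftherm)
```

## The problem

Entomopathogenic fungi such as *Cordyceps javanica* are applied as
biopesticides against the whitefly *Bemisia tabaci*, and temperature is the
dominant abiotic driver of how well they work. Mycelial growth, sporulation
and virulence all follow a unimodal thermal performance curve: zero below a
lower cardinal temperature `T1`, rising to an optimum, and collapsing to
zero again at an upper cardinal temperature `T2`. If that curve can be
estimated from laboratory bioassays, it can be applied cell by cell to
gridded monthly climate to predict where in a country the product will
perform well during the crop season.

`epftherm` implements that pipeline: Ratkowsky-family thermal response
models and their fitting, cumulative time-mortality models with median
lethal time (LT50) estimation, raster projection and performance
classification, and a synthetic-data module that generates bioassay and
climate inputs with known truth so that every stage can be validated
end to end.

## Thermal response models

Two square-root-type (Ratkowsky) forms are provided. Both are defined to be
exactly zero outside the biological range `[T1, T2]` — the squared algebraic
expression is positive there, but a negative-rate reading has no biological
meaning — and proportion-scale responses are additionally capped at 1 when
mapped to percent mortality.

* Ratkowsky 1 (proportion scale, used for virulence):
  `rT = cc * [k1 (T - T1) (1 - exp(k2 (T - T2)))]^2`
* Ratkowsky 2 (arbitrary growth-rate units):
  `rT = [cc (T - T1) (1 - exp(k (T - T2)))]^2`

The placement of the scale factor `cc` outside the square in Ratkowsky 1 is
a deliberate reading of an ambiguously typeset formula: with the published
virulence parameters (`cc` = 2.999, `k1` = 0.084, `k2` = 0.090,
`T1` = 16.502, `T2` = 36.051) the outer-`cc` form evaluates to 0.607 at
25 °C and 0.680 at 30 °C, matching the observed 7-day nymphal mortalities
(60.9% and 68.5%) the model was fitted to, whereas the inside-the-square
reading exceeds 1 — impossible for a mortality proportion. The package
treats `cc` and `k1` as jointly describing the slope (only `cc * k1^2` is
identifiable; see Fitting below).

```{r}
vir <- cjavanica_params("virulence")
eval_ratkowsky1(c(25, 30), vir)
thermal_optimum(vir)
```

`thermal_optimum()` is deterministic: a 0.1 °C coarse scan brackets the
maximum and Brent refinement locates it to the requested resolution
(0.01 °C by default). No randomness, so repeated calls agree exactly.

## Time-mortality curves and LT50

Cumulative mortality versus days post-inoculation is modeled by one of five
families — logistic, log-logistic, log-normal, Weibull, Gompertz — in a
shared `(b, d, e)` parameterization: steepness, plateau and location (see
`?time_course_params` for the closed forms). The published analyses name
these families without writing their formulas; the parameterizations chosen
here are the standard dose-response conventions, picked so that every
family inverts in closed form at the 50% level.

The LT50 is defined at **absolute** 50% mortality, not 50% of the plateau:
when the fitted plateau `d` stays below 0.5 the LT50 is reported as not
estimable, mirroring the convention of dashing out LT50 for treatments
whose cumulative mortality never reached half. This choice is forced by
that reporting rule.

Confidence intervals use a seeded two-stage percentile bootstrap:
replicates are resampled with replacement, and within each drawn replicate
each day's dead count is redrawn as Binomial(total, observed proportion).
The second stage reflects the assay design — each assessment day examines a
fresh leaf, so day-wise counts are independent binomials — and it matters
statistically: with only four replicates, a pure cluster bootstrap misses
the within-replicate binomial variance and its intervals undercover
substantially, while the two-stage interval is well calibrated (the test
suite checks that intervals contain the generating LT50 across simulated
datasets).
The original analyses used a dose-response package's delta-method interval,
which cannot be reproduced without the raw data; the bootstrap is the
package's replacement and is documented as such.

## Fitting and model comparison

All curves are fitted by bounded Levenberg–Marquardt least squares
(`minpack.lm`) from 20 deterministic Latin-hypercube starting points plus
one data-driven heuristic start, keeping the best local optimum. Ratkowsky
RSS surfaces are multimodal in `(T1, T2)`, which is what the multi-start
guards against; the hypercube seed is fixed (127), so fits are pure
functions of their inputs. Default bounds: `T1` in [0, 25] °C, `T2` in
[25, 45] °C, positive scale/rate parameters at most 100, plateau `d` in
[0, 1].

One numerical point deserves emphasis: in Ratkowsky 1, `cc` and `k1` enter
the response only through `cc * k1^2`, so fitting all five parameters is a
rank-deficient problem — in practice the optimizer's trajectory along the
ridge was so unstable that perturbing the data in the eighth decimal could
flip which basin it landed in. `fit_model()` therefore estimates the
identifiable slope with `cc` normalized to 1. Evaluating *published*
parameter sets is unaffected.

Goodness of fit follows the usual least-squares statistics: `R^2`,
adjusted `R^2`, RMSE, RSS, and the least-squares AIC
`n log(RSS/n) + 2(k+1)` (counting the error variance as a parameter).
`rank_models()` orders fits by ascending AIC, breaking ties by descending
adjusted `R^2` then ascending RSS, with non-converged fits last.

Two curves are compared by `compare_curves()`: a pooled fit (one curve for
both groups) against separate fits, with the Gaussian likelihood-ratio
statistic `n_total * log(RSS_pooled / RSS_separate)` referred to a
chi-square with as many degrees of freedom as parameters freed. The source
analyses state only that a "chi-square test" compared curves; the
pooled-versus-separate likelihood ratio is the standard such test and is
implemented as that interpretation. Proportions are fitted untransformed
(no arcsine or logit), matching apparent practice. The test assumes
independent errors — appropriate for fresh-leaf assessment counts, but it
would be anti-conservative on repeated counts of a single cohort, where
day-wise errors are strongly correlated.

## Spatial projection

`read_grid()`/`write_ascii_grid()`/`write_flt_grid()` handle the two flat
raster dialects used for monthly climate layers: ESRI ASCII (`.asc`) and
little-endian 4-byte-float flat binary (`.flt` + `.hdr`). Big-endian
(`MSBFIRST`) flat binaries are rejected explicitly rather than silently
misread; nodata defaults to -9999 and is held as `NA` through all
arithmetic. These readers and writers are part of the package because the
pipeline treats the formats as first-class contracts (header order, 6
significant digits, locale-independent decimal point, round-trip fidelity
are all tested).

`project_response()` evaluates a fitted model at every cell for every
selected month and averages the monthly responses. How the monthly minimum
and maximum combine into an evaluation temperature was never specified in
the source analyses, so it is a policy argument: the default evaluates at
the midpoint `(Tmin + Tmax)/2`, with `min`, `max` and `mean_response`
(average of the responses at the two extremes) as alternatives; the chosen
policy is recorded in the output object and in the CLI log. The month
subset defaults to October–March, the soybean growing season the analysis
targets. The season aggregate is the arithmetic mean of monthly responses.

`classify_performance()` cuts percent mortality into half-open bands
`[lo, hi)` at edges (10, 25, 60) by default, labeled low, moderate, high
and very high. Only two of those boundaries are published (10–25%
"low to moderate", >60% "high"); placing the high/very-high split at 60
with high = [25, 60) is this package's reading of the four-band map
legend, and both edges and labels are configurable rather than asserted as
ground truth.

`hours_in_ranges()` summarizes hourly temperature series as mean hours per
day in each temperature band per month. Bands are contiguous half-open
intervals `(lo, hi]`, so a reading of exactly 15 °C falls in the coldest
band; per-day counts always sum to the hours actually observed that day,
and gaps are simply missing.

## The synthetic-data module

`simulate_growth()`, `simulate_mortality()` and `simulate_climate()`
generate inputs with the statistical structure the analysis assumes, with
all randomness a pure function of (parameters, seed).

* **Growth**: colony area grows linearly at the thermal-response rate with
  additive Gaussian noise (default sd 5% of the peak response) floored at
  zero; length and width are emitted under the ellipse convention
  `area = pi L W / 4` (the conversion from the measured two axes to the
  reported areas is unstated in the source; the ellipse is this package's
  choice).
* **Mortality**: the cumulative curve is logistic with steepness 2 per day;
  its plateau is tied to the thermal response (treatment temperature for
  constant regimes; ambient mean for pulse/alternating regimes, emulating
  the observed temperature-insensitivity once infection is established)
  and its location to the regime's true LT50 (defaults 6.3 days at 25 °C
  and 5.4 days at 30 °C). Plateau and location are solved jointly so that
  expected mortality at the final assessment day equals the
  thermal-response value — that is the quantity the response model is
  fitted to — while the curve still crosses 50% exactly at the nominal
  LT50. Counts are independent Binomial(n, F(t)) draws per day per
  replicate (a fresh leaf per assessment day), with 60 nymphs per
  replicate and 4 replicates by default, mycosis confirmed on each dead
  nymph with probability 0.95, and an untreated control series with daily
  spontaneous mortality 0.005 (about 3.5% by day 7).
* **Climate**: 12 monthly Tmin/Tmax pairs with a latitudinal gradient
  (0.35 °C per degree southwards from a 28 °C equatorial-edge mean over a
  Brazil-like latitude span), a seasonal cosine peaking in January whose
  amplitude grows with latitude, monthly diurnal ranges drawn in 6–12 °C,
  optional nodata holes, and analytic generator-side truth classes for
  checking the projection pipeline.

What the generators deliberately do **not** emulate: humidity, solar
radiation and rainfall effects; between-replicate variance components
beyond binomial sampling (the real assays' replicate variance is unknown);
conidial decay; insect population dynamics. Passing recovery tests
therefore demonstrates that the estimation machinery is correct and well
calibrated under the stated model, not that the model captures every
source of variation in real bioassays.

## Problem sizes and numerical choices

The validation suite runs at desk scale by design: recovery loops use 20
seeds of 7-temperature bioassays (4 replicates x 60 nymphs), bootstrap
intervals use a few hundred refits in tests (999 by default in analysis
use), and the projection checks use grids up to 200 x 200 cells. These
sizes were chosen as the smallest at which the statistical properties under
test are stable.

Degenerate inputs are contracts, not accidents: all-zero responses yield a
flagged non-converged (or zero-scale) fit rather than an error;
insufficient data (fewer distinct x values than parameters plus one)
raises an error; `T1 >= T2` is rejected; a separate-fit RSS of exactly
zero with positive pooled RSS reports an infinite statistic with p = 0.
Ties in model ranking are broken deterministically as documented above.

## Known limitations

* The chi-square curve comparison is a Gaussian approximation on
  proportions; it ignores heteroscedasticity of binomial errors and will
  be anti-conservative for correlated repeated measurements.
* LT50 intervals are bootstrap percentiles, not the delta-method intervals
  of dose-response packages; with very few replicates the replicate-level
  resampling stage is coarse.
* Projection assumes all layers share geometry; there is no reprojection,
  resampling, or cartography.
* The response-to-mortality mapping treats the model output as a 7-day
  mortality proportion; extrapolating to other exposure durations is not
  supported.
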