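---
title: "Thermal niche tracking through breeding phenology: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal niche tracking through breeding phenology: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`phenotherm` asks whether phenological plasticity lets a seasonally
breeding population hold its thermal niche fixed while the climate
warms. This vignette documents the statistical models, the calendar and
data conventions, the synthetic-cohort generator that the package is
validated against, and the design decisions taken where more than one
reasonable choice existed.

## Calendar conventions

All calendar arithmetic runs on a 365-day grid with 29 February dropped
at ingest. The point of the analysis is to compare windows anchored to
month-day positions across years; dropping the leap day makes
"15 February" the same grid day in every year, at the cost of a one-day
offset for post-February dates in leap years (irrelevant at the
precision of multi-day window means). Breeding timing uses the April-day
scale standard in long-term tit studies: 1 = 1 April, 31 March = 0,
1 March = −30. The convention is fixed at the origin stated here and
used everywhere; `april_day_to_doy()` / `doy_to_april_day()` convert.

Daily temperature input is either a tidy CSV (`date`, `tmean_c`) or the
Met Office daily Central England Temperature layout (year, day-of-month,
twelve month columns in tenths of °C, −999 missing). Any value below
−90 °C after scaling is treated as a missing sentinel. Validation of
breeding tables is strict by default — a row violating
`n_fledged ≤ clutch_size ≤ …` is an error naming the row — with a
permissive mode that drops bad rows and attaches diagnostics.
Partially observed attempts are flagged, never imputed.

## Reproductive periods

The five relative windows are closed April-day intervals: laying runs
from the first egg to the day before incubation starts (one egg per day,
so `laying + clutch − 1` ends the period when the incubation start is
unrecorded — the standard field convention); incubation ends the day
before hatching, so the hatch day is counted once, in the hatching
period; hatching is hatch +0–7 d, nestling +8–15 d, fledging +16–21 d.
When all dates are present the five periods partition
`[laying, hatch + 21]` exactly. Without a hatch date the incubation
period's end is unknowable, so incubation (like the three post-hatch
periods) is reported undefined and only laying survives. A window mean
is reported when at least half its days have temperature data (the
missing count is recorded); this conservative default matters only for
gappy historical series.

## Trend models

Fixed-window trends are textbook OLS of annual means on year, reporting
the slope, its SE, `F = t²` on (1, n−2) df and a ±1.96·SE interval.
Attempt-level trends use the linear mixed model
`value ~ year + (1 | year) + (1 | female)` fitted by REML: continuous
year carries the trend, categorical year absorbs shared annual
deviations, and female identity absorbs repeated breeding by the same
individual. The slope test uses Satterthwaite denominator df (the
fractional df the field reports); a `ddf = "wald"` fast path skips the
df approximation where only the Wald interval is needed, as in the
large replicate batteries. Singular fits are reported with a flag, not
an error, because a zero variance component is a legitimate estimate.

The window-slope distribution refits the *annual* OLS model for every
calendar window of 8–15 consecutive days inside the season (804 windows
for the 111-day default span). Fitting on yearly window means — not at
attempt level — mirrors the fixed-interval model structure, which is
what the comparison is about. Years missing any day inside a window are
dropped for that window only.

## Fitness response surfaces

Each success measure is modelled against one period's temperature
through a natural cubic spline with year and female random intercepts,
by Laplace-approximate ML (glmmTMB). Families follow the data: Poisson
for clutch size (laying period only — the other periods postdate clutch
completion), zero-inflated Poisson for fledged and recruit counts
(broods fail wholesale through predation or desertion, producing
structural zeros; the inflation component is intercept-only because
nothing in the data model says failure probability varies with the
covariates), and binomial successes-out-of-clutch for fledging success.
Laying date and neighbor count (plus clutch size for fledging success,
plus absolute mismatch in the mediation fits) enter standardized to
mean 0, SD 1.

Spline df counts basis columns excluding the intercept; df = 7 is the
default, with interior knots at equally spaced quantiles of the observed
temperatures and natural (linear-beyond-boundary) tails, so
extrapolation at extreme temperatures stays linear. The basis always
contains constants and linear functions exactly.

The thermal optimum is the argmax of the population-level fitted curve
on a 0.1 °C grid spanning the observed range (the grid always includes
the endpoints; ties break toward the lower temperature for determinism;
an argmax at the grid edge is flagged `at_boundary`). Uncertainty comes
from a cluster bootstrap over years: resample years with replacement,
refit, re-locate, take the percentile interval (default 500 resamples;
a Bayesian posterior would be the main alternative, and the bootstrap
substitutes for it at desk-scale runtime). Two deliberate shortcuts:
bootstrap refits use the fixed-effect structure only (GLM / weighted
IRLS / a direct ML zero-inflated Poisson fitter), because resampling
whole years already propagates the between-year variance that the year
random intercept represents, and refitting the full GLMM hundreds of
times per peak would cost hours for no change in the resampled argmax;
and rank-deficient resamples (degenerate temperature ranges) are
skipped rather than patched. A curve whose range is numerically zero is
reported non-identifiable instead of yielding an arbitrary minimizer.

Pre/post-peak trends refit the same family and covariates on the
subsets below and above the peak with temperature as a linear term,
standardized *within* each subset (the natural scale for "effect per SD
of temperature seen on that side"; whether to standardize within or
globally was open, and within-subset is the logged choice).
Observations exactly at the peak join the pre side. Sides with fewer
than 30 observations are flagged; empty sides are absent.

## Trophic synchrony

The half-fall date is the earliest date whose cumulative trap count
reaches 50% of the seasonal total — a threshold on counts, not days,
with ties resolving to the earliest qualifying date by construction.
Dates are integers; interpolating fractional half-fall dates between
trap visits would be the alternative, but integer dates match how trap
data are recorded. Years with zero totals are unusable and flagged at
ingest. Temperature at half-fall averages ±7 days around HF by default,
with ±15 and ±20 supported for sensitivity.

Per nest, `match = (hatch + 10) − HF`: nestling energetic demand peaks
near day 10, so zero means the hungriest brood days coincide with peak
food. Mismatch curves (Gaussian spline GLMMs of |match| on period
temperature, same random effects and bootstrap machinery) are fitted
for laying, incubation, hatching and nestling only — the fledging
period falls mostly after the food peak. The mediation comparison
refits a fitness model with and without standardized |match| and
reports the ratio of post-peak slope magnitudes.

The cue-window search regresses annual mean laying date on each
candidate window's annual mean temperature and ranks candidates by
AICc — equivalent to R² ranking for fixed n and a single predictor, but
a standard, documented criterion.

## The synthetic cohort generator

The generator is first-class, tested code: it produces climate,
breeding and caterpillar data with the statistical structure the
analysis assumes, and records its parameters (`generator_truth`) as the
oracle for recovery tests.

**Climate.** Daily temperature = seasonal expectation + linear warming
(default 0.032 °C/yr anchored at the first cohort year) + a whole-year
anomaly (SD 0.45 °C) + a late-spring anomaly (SD 1.0 °C, ramping in
over grid days 85–95 and holding thereafter) + AR(1) daily noise
(marginal SD 2 °C, lag-1 correlation 0.6 — autocorrelated noise gives
multi-day window means realistic variance). The seasonal expectation is
a sinusoid whose spring flank is spliced to its tangent line across the
breeding span (grid days 84–168, cosine-tapered joins): real long-run
spring records are themselves near-linear from late winter to early
summer, and the exactly linear ramp makes the full-compensation
arithmetic below hold identically in every reproductive period. The
default amplitude (6.6411 °C) sets that ramp to
0.032 / 0.28 ≈ 0.1143 °C per day. The two anomaly components play
distinct biological roles: the whole-year anomaly is visible in the
laying cue window, so plastic females track it; the late-spring anomaly
arrives after laying decisions are made, cannot be tracked, and is
shared by all five relative windows of a year — it is what the year
random intercepts in the trend models absorb. The noise defaults were
anchored to the uncertainty scale of six-decade field studies (trend
SEs near 0.005 °C/yr for the fixed window, ~0.04 d/yr for laying date,
~0.05 d/yr for half-fall).

**Breeding.** Each year carries `n_females` slots; a slot holds one
female for a geometric run of seasons (mean 2.5), so female identity is
a real grouping factor. Laying date =
`baseline − γ·(cue-window mean − reference) + N(0, 5 d)`, rounded; the
default γ = 8.75 d/°C times the spring ramp slope equals 1, so plastic
females cancel both the warming trend and whole-year anomalies —
exactly the full-compensation scenario. Clutch size is Poisson around a
Gaussian hump in early-laying temperature (optimum 11.8 °C, width 3 °C,
floor one egg); one egg per day, so incubation starts the day after the
last egg; incubation lasts round(N(13, 1)) days with floor 10. Fledged
young are Binomial(clutch, p(T)) with p peaking at the optimum,
multiplied by a wholesale brood-failure event with probability 0.1 (the
zero-inflation the ZIP family fits); recruits are Binomial(fledged, s)
with yearly logit-normal survival around 0.1, giving realistic
zero-heavy recruit counts. With `fledging_driver = "mismatch"` the
fledging probability instead decays with |match| against the year's
expected caterpillar peak (0.25 logits per day), so temperature affects
fitness only through synchrony — the construction used to validate the
mediation analysis.

**Caterpillars.** The expected peak advances by 8.4375 d per °C of
spring-cue anomaly (times 0.032 °C/yr ≈ −0.27 d/yr); each year's
seasonal total of 1000 is spread multinomially around the peak with a
5-day Gaussian.

**What the generator does not emulate** — and hence what passing
recovery tests do not certify for real data: density dependence and
double broods; spatial microclimate among nest boxes; observation error
in nest records; evolution of the plastic response; the tree/bud-burst
trophic level beneath the caterpillars; non-stationary warming;
fractional/interpolated half-fall reporting. The plasticity
parameterization per °C of cue temperature is a modeling choice, not an
empirical claim about any real population.

## Recovery properties and a known joint-coverage ceiling

The package's test suite validates the chain by recovery at these
problem sizes: unit checks on 20-year × 40-female cohorts; 100
replicate 59-year × 200-female cohorts for the homeostasis battery; 100
cohorts of n = 2000 for bootstrap peak coverage; 1000 random series for
the half-fall oracle; n = 2000 constructions for mediation and
planted-window recovery. Bootstrap sizes are 150–500 resamples.

One property deserves a frank note. In the homeostasis battery each of
the five relative-interval 95% CIs covers zero at its nominal rate
(≥90%, empirically ~93–95% per period, residual bias below
0.001 °C/yr), and the fixed-interval CI essentially always excludes
zero. The *joint* event — all five intervals covering at once — runs
near its theoretical joint-coverage rate: with the measured
cross-period error correlation (~0.8, induced by the shared late-spring
anomaly), five simultaneous 95% intervals cover jointly about 85% of
the time, not 95%. This is a property of unadjusted multiple intervals,
not of the estimators; pushing the joint rate higher would require
multiplicity-adjusted (wider) intervals or an unrealistically
deterministic climate, and the package reports plain per-interval 95%
intervals as the field does.

## Known limitations

No autocorrelation-robust standard errors for the annual trends (plain
linear models are the field's standard here). The zero-inflation
component is intercept-only. Spline df is configurable but not selected
by the package. The bootstrap peak interval pairs a GLMM point estimate
with fixed-effect resample refits — coherent in coverage tests, but the
two curves can differ slightly in small samples. Half-fall dates are
integers. The pipeline's fitness stage defaults to the laying period
(the strongest and always-defined window); other periods are one config
line away.
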