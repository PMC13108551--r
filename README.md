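# phenotherm

Does plasticity in breeding phenology buy a wild population **thermal
homeostasis**? When springs warm and birds lay earlier, the temperature
measured in a fixed calendar window rises year after year — but the
temperature each nest actually experiences, measured in windows anchored
to its own timing, may not change at all. `phenotherm` implements the
full inference chain for testing that idea in seasonally breeding birds
(built around the great tit / winter moth study system), plus an
individual-based synthetic-cohort generator with recorded ground truth so
that every step of the chain can be validated by parameter recovery.

The package is aimed at population ecologists working with long-term
nest-record data, daily temperature series and invertebrate phenology
monitoring.

## The analysis chain

1. **Fixed vs relative thermal trends.** Annual means of daily
   temperature T(d) in a fixed window (15 Feb–5 Jun) are regressed on
   year by OLS: `T̄_y = α + β·year`, with F = t² on 1 and n−2 df. The
   same trend is then estimated for the five windows anchored to each
   nest's own timing — egg laying, incubation, hatching (0–7 d
   post-hatch), nestling (8–15 d) and fledging (16–21 d) — with the
   attempt-level mixed model
   `T_i = α + β·year + u_year + v_female + ε_i`
   (year also as a categorical random intercept, Satterthwaite df).
   Plastic thermal tracking predicts β > 0 for the fixed window and
   β ≈ 0 for all five relative windows.
2. **Window-slope distribution.** To show the contrast is not an
   artefact of interval length, the annual-trend model is refitted for
   every calendar window of 8–15 consecutive days inside the season
   (804 windows for the 111-day span), giving a slope distribution to
   compare with the relative-interval slopes.
3. **Temperature–fitness response surfaces.** Each reproductive-success
   measure is modelled against period temperature through a natural
   cubic spline (7 df) in a GLMM with year and female random intercepts:
   clutch size (Poisson, laying period only), fledged and recruit counts
   (zero-inflated Poisson), fledging success (binomial
   successes-out-of-clutch); laying date and neighbor count (plus clutch
   size for fledging success) enter as standardized covariates. The
   thermal optimum T\* is the argmax of the fitted curve, with a 95%
   interval from a cluster bootstrap over years, and linear pre/post-peak
   slopes quantify the fitness cost of breeding off-optimum.
4. **Trophic synchrony.** The caterpillar **half-fall date** HF is the
   earliest date by which cumulative trap counts reach 50% of the
   seasonal total; its trend and the trend of temperature at HF ± 7 days
   test thermal tracking by the prey. Per nest,
   `match = (hatch + 10) − HF` (nestling demand peaks near day 10);
   spline models of |match| on period temperature locate the
   mismatch-minimizing temperature, and refitting the fitness models
   with |match| as a covariate measures how much of the temperature
   effect is mediated by synchrony.
5. **Cue-window search.** The calendar window whose mean temperature
   best predicts annual mean laying date is found by sliding-window
   model comparison (AICc).

## Worked example

Simulate a six-decade cohort at the default study conditions (warming
0.032 °C/yr, plasticity 8.75 d/°C so laying advances −0.28 d/yr, fitness
optimum 11.8 °C, caterpillar sensitivity −0.27 d/yr) and run the chain:

```r
library(phenotherm)

truth <- generator_truth(seed = 42)
cohort <- simulate_cohort(truth)

fit_annual_trend(fixed_interval_annual_means(cohort$climate))
#> <trend_fit> slope 0.0307 +/- 0.0063 per yr, F(1,57) = 23.58, p = 9.72e-06, n = 59

fit_attempt_level_trend(cohort$attempts, "laying_april_day")
#> <mixed_trend_fit> slope -0.2366 +/- 0.0543 per yr, t df (Satterthwaite) 57.0, p = 5.47e-05

it <- relative_period_temperatures(cohort$attempts, cohort$climate)
rel <- subset(it, period == "laying")
rel$female_id <- cohort$attempts$female_id[match(rel$attempt_id,
                                                 cohort$attempts$attempt_id)]
fit_attempt_level_trend(rel, "mean_temp")
#> <mixed_trend_fit> slope 0.0021 +/- 0.0099 per yr, t df (Satterthwaite) 57.0, p = 0.836

sliding_window_slope_distribution(cohort$climate, enumerate_calendar_windows())
#> <window_slopes> 804 windows: mean slope 0.0304 +/- 0.0074 (SD) per yr
```

The fixed window warms significantly (0.031 °C/yr — and so does every
8–15-day calendar window, mean 0.030), laying advances by −0.24 d/yr, and
the temperature the birds actually experience during laying is flat
(0.002 ± 0.010 °C/yr): thermal homeostasis through plasticity, exactly
the planted structure.

```r
fit <- fit_fitness_response(cohort$attempts, it, "clutch_size", "laying")
locate_peak_with_interval(fit, n_boot = 200, seed = 1)
#> <peak_estimate> peak 11.97 degC [11.36, 12.47] (95% cluster bootstrap, 200/200 resamples)

hf <- half_fall_table(cohort$caterpillars)
half_fall_trend(hf)
#> <trend_fit> slope -0.2260 +/- 0.0558 per yr, F(1,57) = 16.43, p = 0.000155, n = 59
```

The clutch-size optimum is recovered near the planted 11.8 °C, and
caterpillar half-fall advances in step with its thermal cue. The whole
chain (plus report and CSV outputs) also runs as one call:

```r
res <- run_pipeline(list(truth = list(), seed = 42, out_dir = "out"))
```

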