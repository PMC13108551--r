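#' Ground-truth parameters for the synthetic cohort generator
#'
#' Bundles every parameter of the individual-based generator together with
#' the seed, so that a simulated dataset always carries the values the
#' downstream pipeline should recover. Defaults echo the magnitudes of the
#' six-decade Wytham-style study system the package is built around:
#' warming of 0.032 degC per year on a seasonal cycle, a plastic laying-date
#' response that fully compensates it (-0.28 d/yr), hump-shaped fitness with
#' an optimum near 11.8 degC, and temperature-driven caterpillar phenology
#' advancing about -0.27 d/yr.
#'
#' The seasonal cycle is a sinusoid whose spring flank is spliced to its
#' tangent line across the breeding span (real spring records are
#' near-linear from late winter to early summer), and the default
#' amplitude (6.6411 degC) makes that ramp exactly
#' 0.032 / 0.28 = 0.1143 degC per day: the rate at which a -0.28 d/yr
#' phenological advance offsets 0.032 degC/yr of secular warming
#' identically in every reproductive period. With the default plasticity
#' (8.75 d/degC) the product gamma * ramp equals 1, so plastic females
#' also cancel whole-year temperature anomalies exactly, not just the
#' trend. The full-compensation geometry is internally consistent rather
#' than tuned per run.
#'
#' @param warming_rate_b Secular trend, degC per year.
#' @param seasonal_amplitude,seasonal_mean Sinusoidal seasonal cycle (degC);
#'   phase fixed with the seasonal maximum in mid July.
#' @param ar1_rho,daily_sd AR(1) autocorrelation and marginal SD of daily
#'   temperature noise (degC); autocorrelated noise gives multi-day window
#'   means realistic variance.
#' @param annual_sd SD (degC) of a year-level temperature anomaly present
#'   from 1 January (warm and cold years as a whole). It is visible in the
#'   laying cue window, so plastic females track it.
#' @param late_spring_sd SD (degC) of an independent year-level anomaly
#'   that develops over March (ramping in over grid days 85-95) and holds
#'   through the season: late-spring warmth or cold that arrives after
#'   laying decisions are made, so no plastic response can track it. It is
#'   shared by all five relative reproductive windows of a year and is what
#'   the year random intercept of the trend models absorbs. Together the
#'   two anomalies and the AR(1) noise reproduce the interannual scatter of
#'   long-run spring records (annual fixed-window means with residual SD
#'   near 0.65 degC, i.e. a 59-year trend SE near 0.005 degC/yr).
#' @param plasticity_gamma Laying-date advance per degC of cue-window
#'   temperature (days/degC).
#' @param cue_window Month-day pair (`"MM-DD"`) the females integrate
#'   temperature over when timing laying.
#' @param baseline_laying Mean April-day of laying at reference temperature.
#' @param laying_sd Between-female SD of laying date (days).
#' @param clutch_base Poisson mean clutch size at the thermal optimum.
#' @param fitness_optimum_Topt Temperature (degC) maximizing clutch size and
#'   fledging probability.
#' @param fitness_width Gaussian width (degC) of the fitness hump.
#' @param incubation_mean Mean incubation duration (days; SD 1, floor 10).
#' @param caterpillar_sensitivity_c Half-fall advance per degC of spring cue
#'   anomaly (days/degC).
#' @param caterpillar_peak_base Baseline caterpillar peak (April-day).
#' @param caterpillar_cue_window Month-day pair of the larval thermal cue.
#' @param fall_spread_sd SD (days) of the Gaussian fall curve.
#' @param caterpillar_total Seasonal total trapped per year.
#' @param zero_inflation_pi Probability that a brood fails wholesale
#'   (predation/desertion), producing structural zeros in fledged counts.
#' @param fledge_p_max Per-egg fledging probability at the optimum.
#' @param recruit_survival Mean per-fledgling recruitment probability; the
#'   yearly value is drawn around it on the logit scale (SD 0.3), giving
#'   realistic zero-heavy recruit counts.
#' @param fledging_driver `"temperature"` (direct thermal effect) or
#'   `"mismatch"` (fledging depends on temperature only through trophic
#'   mismatch; used for mediation analyses).
#' @param mismatch_cost Logit-scale fledging penalty per day of absolute
#'   mismatch when `fledging_driver = "mismatch"`.
#' @param n_females Breeding slots per year.
#' @param years Integer vector of cohort years.
#' @param seed Root seed; all stage seeds derive from it.
#' @return A `generator_truth` list.
#' @export
generator_truth <- function(warming_rate_b = 0.032,
                            seasonal_amplitude = 6.6411,
                            seasonal_mean = 12.5,
                            ar1_rho = 0.6,
                            daily_sd = 2.0,
                            annual_sd = 0.45,
                            late_spring_sd = 1.0,
                            plasticity_gamma = 8.75,
                            cue_window = c("02-15", "03-25"),
                            baseline_laying = 25,
                            laying_sd = 5,
                            clutch_base = 8.5,
                            fitness_optimum_Topt = 11.8,
                            fitness_width = 3.0,
                            incubation_mean = 13,
                            caterpillar_sensitivity_c = 8.4375,
                            caterpillar_peak_base = 56,
                            caterpillar_cue_window = c("03-01", "04-25"),
                            fall_spread_sd = 5,
                            caterpillar_total = 1000L,
                            zero_inflation_pi = 0.1,
                            fledge_p_max = 0.85,
                            recruit_survival = 0.1,
                            fledging_driver = c("temperature", "mismatch"),
                            mismatch_cost = 0.25,
                            n_females = 200L,
                            years = 1965:2023,
                            seed = 1L) {
  truth <- list(warming_rate_b = warming_rate_b,
                seasonal_amplitude = seasonal_amplitude,
                seasonal_mean = seasonal_mean,
                ar1_rho = ar1_rho, daily_sd = daily_sd,
                annual_sd = annual_sd, late_spring_sd = late_spring_sd,
                plasticity_gamma = plasticity_gamma,
                cue_window = cue_window,
                baseline_laying = baseline_laying, laying_sd = laying_sd,
                clutch_base = clutch_base,
                fitness_optimum_Topt = fitness_optimum_Topt,
                fitness_width = fitness_width,
                incubation_mean = incubation_mean,
                caterpillar_sensitivity_c = caterpillar_sensitivity_c,
                caterpillar_peak_base = caterpillar_peak_base,
                caterpillar_cue_window = caterpillar_cue_window,
                fall_spread_sd = fall_spread_sd,
                caterpillar_total = as.integer(caterpillar_total),
                zero_inflation_pi = zero_inflation_pi,
                fledge_p_max = fledge_p_max,
                recruit_survival = recruit_survival,
                fledging_driver = match.arg(fledging_driver),
                mismatch_cost = mismatch_cost,
                n_females = as.integer(n_females),
                years = as.integer(years),
                seed = as.integer(seed))
  stopifnot(truth$seasonal_amplitude > 0, truth$daily_sd > 0,
            truth$annual_sd >= 0, truth$late_spring_sd >= 0,
            truth$laying_sd > 0, truth$fitness_width > 0,
            truth$fall_spread_sd > 0, truth$incubation_mean >= 10,
            truth$clutch_base > 0, truth$caterpillar_total > 0,
            truth$n_females >= 1L, length(truth$years) >= 2L)
  if (truth$ar1_rho < 0 || truth$ar1_rho >= 1)
    stop("ar1_rho must lie in [0, 1)")
  if (truth$zero_inflation_pi < 0 || truth$zero_inflation_pi >= 1)
    stop("zero_inflation_pi must lie in [0, 1)")
  if (truth$fledge_p_max <= 0 || truth$fledge_p_max >= 1)
    stop("fledge_p_max must lie in (0, 1)")
  for (w in list(truth$cue_window, truth$caterpillar_cue_window)) {
    d <- vapply(w, md_to_doy, integer(1))
    if (d[1L] > d[2L]) stop("cue window start after end")
  }
  class(truth) <- "generator_truth"
  truth
}

#' @export
print.generator_truth <- function(x, ...) {
  cat(sprintf(paste0(
    "<generator_truth> %d years x %d females, seed %d\n",
    "  warming %.3f degC/yr | plasticity %.2f d/degC ",
    "(laying trend %+.3f d/yr)\n",
    "  fitness optimum %.1f degC (width %.1f) | caterpillar sensitivity ",
    "%.2f d/degC (half-fall trend %+.3f d/yr)\n"),
    length(x$years), x$n_females, x$seed,
    x$warming_rate_b, x$plasticity_gamma,
    -x$plasticity_gamma * x$warming_rate_b,
    x$fitness_optimum_Topt, x$fitness_width,
    x$caterpillar_sensitivity_c,
    -x$caterpillar_sensitivity_c * x$warming_rate_b))
  invisible(x)
}

# Deterministic seasonal expectation (no warming, no noise). A sinusoid
# with its inflection (steepest ascent) at grid day 130.75, the midpoint
# of the breeding season, except that across the breeding span itself the
# curve follows the tangent line exactly (cosine-tapered splice), so the
# spring ramp is strictly linear where the reproductive windows sit. The
# ramp slope is amplitude * 2 * pi / 365 degC per day; at the default
# amplitude that is 0.1143 degC/d, the rate at which a -0.28 d/yr
# phenological advance offsets 0.032 degC/yr of warming identically in
# every reproductive period - the premise of the full-compensation
# scenario. Real long-run spring records are themselves near-linear from
# late winter to early summer, which is what this shape emulates.
seasonal_expectation <- function(truth, doy) {
  th <- 2 * pi * (doy - 130.75) / 365
  sine <- truth$seasonal_amplitude * sin(th)
  lin <- truth$seasonal_amplitude * th
  # weight 1 on grid days 84..168 (every reproductive window of every
  # study year), cosine taper over 15 d on each side
  w <- ifelse(doy >= 84 & doy <= 168, 1,
       ifelse(doy >= 69 & doy < 84, 0.5 - 0.5 * cos(pi * (doy - 69) / 15),
       ifelse(doy > 168 & doy <= 183, 0.5 + 0.5 * cos(pi * (doy - 168) / 15),
              0)))
  truth$seasonal_mean + sine + w * (lin - sine)
}

# Expected mean of the seasonal cycle over a month-day window (the cue
# reference temperature at the start of the study).
cue_reference <- function(truth, window) {
  doys <- md_to_doy(window[1L]):md_to_doy(window[2L])
  mean(seasonal_expectation(truth, doys))
}

#' Simulate a daily temperature series with seasonal cycle, warming and
#' AR(1) noise
#'
#' Daily mean temperature is the seasonal sinusoid plus a linear secular
#' trend of `warming_rate_b` degC per year (anchored at the first cohort
#' year), a whole-year anomaly (SD `annual_sd`), a late-spring anomaly
#' (SD `late_spring_sd`, ramping in over grid days 85-95 and holding for
#' the rest of the year), and stationary AR(1) noise with marginal SD
#' `daily_sd` and lag-1 correlation `ar1_rho`, simulated as one continuous
#' stream across years. Bit-identical output for identical `truth` and
#' `seed`.
#'
#' @param truth A [generator_truth] object.
#' @param seed Seed for this stage; defaults to a stream derived from
#'   `truth$seed`.
#' @return A [daily_temps] series covering every day of `truth$years`.
#' @export
simulate_climate <- function(truth, seed = derive_seed(truth$seed, 1L)) {
  stopifnot(inherits(truth, "generator_truth"))
  years <- truth$years
  n_days <- length(years) * 365L
  doy <- rep(1:365, times = length(years))
  year <- rep(years, each = 365L)
  det <- seasonal_expectation(truth, doy) +
    truth$warming_rate_b * (year - years[1L])
  noise <- with_seed(seed, {
    innov_sd <- truth$daily_sd * sqrt(1 - truth$ar1_rho^2)
    ar1 <- as.numeric(stats::arima.sim(list(ar = truth$ar1_rho),
                                       n = n_days, sd = innov_sd))
    a_year <- rep(stats::rnorm(length(years), 0, truth$annual_sd),
                  each = 365L)
    ramp <- pmin(pmax((1:365 - 85) / 10, 0), 1)   # in place by 5 April
    a_spring <- rep(stats::rnorm(length(years), 0, truth$late_spring_sd),
                    each = 365L) * rep(ramp, length(years))
    ar1 + a_year + a_spring
  })
  daily_temps(year, doy, det + noise,
              provenance = sprintf("synthetic (seed %d)", as.integer(seed)))
}

# Yearly mean temperature over a month-day window, from the dense matrix.
window_year_means <- function(m, window) {
  doys <- md_to_doy(window[1L]):md_to_doy(window[2L])
  rowMeans(m[, doys, drop = FALSE])
}

#' Deterministic expected caterpillar peak dates under a climate
#'
#' The expected peak (April-day) for each year is the baseline shifted
#' earlier by `caterpillar_sensitivity_c` days per degC of spring-cue
#' anomaly relative to the seasonal reference.
#'
#' @param climate A [daily_temps] series.
#' @param truth A [generator_truth] object.
#' @return Data frame with `year` and `peak_april_day`.
#' @export
expected_caterpillar_peaks <- function(climate, truth) {
  m <- temp_matrix(climate)
  cue <- window_year_means(m, truth$caterpillar_cue_window)
  ref <- cue_reference(truth, truth$caterpillar_cue_window)
  data.frame(year = as.integer(rownames(m)),
             peak_april_day = truth$caterpillar_peak_base -
               truth$caterpillar_sensitivity_c * (cue - ref))
}

#' Simulate an individual-based breeding cohort
#'
#' Each year carries `n_females` breeding slots; a slot is held by one
#' female for a geometric run of consecutive years (mean tenure 2.5
#' seasons), so female identity is a meaningful grouping factor. Per
#' attempt: laying date responds plastically to the cue-window temperature
#' (`baseline - gamma * (cue - reference) + Normal(0, laying_sd)`, rounded);
#' clutch size is Poisson around a Gaussian hump in early-laying-period
#' temperature with optimum `fitness_optimum_Topt` (floor 1 egg); one egg is
#' laid per day so incubation starts the day after the last egg; hatching
#' follows a Normal(13, 1) incubation (floor 10 days); fledged young are
#' Binomial(clutch, p(T)) with p maximized at the optimum, zeroed wholesale
#' with probability `zero_inflation_pi`; recruits are Binomial(fledged, s)
#' with a yearly logit-normal survival around `recruit_survival`. With
#' `fledging_driver = "mismatch"` the fledging probability depends on
#' temperature only through the absolute mismatch between (hatch + 10) and
#' the year's expected caterpillar peak.
#'
#' @inheritParams simulate_climate
#' @param climate A [daily_temps] series covering all cohort years.
#' @return A `breeding_attempts` data frame; every biological invariant
#'   holds by construction.
#' @export
simulate_breeding_cohort <- function(climate, truth,
                                     seed = derive_seed(truth$seed, 2L)) {
  stopifnot(inherits(climate, "daily_temps"),
            inherits(truth, "generator_truth"))
  years <- truth$years
  if (!all(years %in% climate$year))
    stop("climate does not cover all cohort years")
  m <- temp_matrix(climate)
  yr_idx <- match(years, as.integer(rownames(m)))
  cue <- window_year_means(m, truth$cue_window)[yr_idx]
  ref <- cue_reference(truth, truth$cue_window)
  mu_lay <- truth$baseline_laying - truth$plasticity_gamma * (cue - ref)
  peaks <- expected_caterpillar_peaks(climate, truth)
  peak_ad <- peaks$peak_april_day[match(years, peaks$year)]

  with_seed(seed, {
    n_yr <- length(years); n_f <- truth$n_females
    # slot tenure: each slot is a chain of females with geometric tenures
    female <- matrix(NA_character_, nrow = n_yr, ncol = n_f)
    counter <- 0L
    for (s in seq_len(n_f)) {
      y <- 1L
      while (y <= n_yr) {
        counter <- counter + 1L
        tenure <- 1L + stats::rgeom(1L, 0.4)
        female[y:min(y + tenure - 1L, n_yr), s] <- sprintf("F%05d", counter)
        y <- y + tenure
      }
    }
    s_year <- stats::plogis(stats::qlogis(truth$recruit_survival) +
                              stats::rnorm(n_yr, 0, 0.3))

    rows <- vector("list", n_yr)
    for (i in seq_len(n_yr)) {
      lay <- as.integer(round(mu_lay[i] + stats::rnorm(n_f, 0, truth$laying_sd)))
      # clutch responds to temperature over a provisional 9-day laying span
      t_prov <- .window_means_ad(m, yr_idx[i], lay, lay + 8L)
      lambda <- truth$clutch_base *
        exp(-0.5 * ((t_prov - truth$fitness_optimum_Topt) /
                      truth$fitness_width)^2)
      clutch <- pmax(1L, stats::rpois(n_f, lambda))
      inc_start <- lay + clutch              # one egg per day
      inc_dur <- pmax(10L, as.integer(round(stats::rnorm(
        n_f, truth$incubation_mean, 1))))
      hatch <- inc_start + inc_dur
      t_lay <- .window_means_ad(m, yr_idx[i], lay, inc_start - 1L)
      if (truth$fledging_driver == "temperature") {
        p <- stats::plogis(stats::qlogis(truth$fledge_p_max) -
                             ((t_lay - truth$fitness_optimum_Topt) /
                                truth$fitness_width)^2)
      } else {
        mis <- abs(hatch + 10L - peak_ad[i])
        p <- stats::plogis(stats::qlogis(truth$fledge_p_max) -
                             truth$mismatch_cost * mis)
      }
      fail <- stats::rbinom(n_f, 1L, truth$zero_inflation_pi) == 1L
      fledged <- ifelse(fail, 0L, stats::rbinom(n_f, clutch, p))
      recruits <- stats::rbinom(n_f, fledged, s_year[i])
      rows[[i]] <- data.frame(
        attempt_id = sprintf("Y%d_%03d", years[i], seq_len(n_f)),
        year = years[i],
        female_id = female[i, ],
        laying_april_day = lay,
        clutch_size = clutch,
        incubation_start_april_day = inc_start,
        hatch_april_day = hatch,
        n_fledged = as.integer(fledged),
        n_recruits = as.integer(recruits),
        n_neighbors = stats::rpois(n_f, 5))
    }
    breeding_attempts(do.call(rbind, rows))
  })
}

# Mean temperature over per-row April-day windows within one matrix row.
.window_means_ad <- function(m, row, start_ad, end_ad) {
  start <- april_day_to_doy(start_ad); end <- april_day_to_doy(end_ad)
  vapply(seq_along(start), function(j)
    mean(m[row, start[j]:end[j]]), numeric(1))
}

#' Simulate yearly caterpillar water-trap count series
#'
#' Per year, the expected peak date comes from
#' [expected_caterpillar_peaks]; the seasonal total `caterpillar_total` is
#' spread multinomially over days around the peak with Gaussian weights
#' (SD `fall_spread_sd`).
#'
#' @inheritParams simulate_breeding_cohort
#' @return A `caterpillar_falls` table.
#' @export
simulate_caterpillar_falls <- function(climate, truth,
                                       seed = derive_seed(truth$seed, 3L)) {
  stopifnot(inherits(climate, "daily_temps"),
            inherits(truth, "generator_truth"))
  peaks <- expected_caterpillar_peaks(climate, truth)
  peaks <- peaks[peaks$year %in% truth$years, , drop = FALSE]
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(peaks)), function(i) {
      mu <- peaks$peak_april_day[i]
      ads <- seq.int(floor(mu - 3.5 * truth$fall_spread_sd),
                     ceiling(mu + 3.5 * truth$fall_spread_sd))
      w <- stats::dnorm(ads, mu, truth$fall_spread_sd)
      cnt <- as.integer(stats::rmultinom(1L, truth$caterpillar_total,
                                         w / sum(w)))
      data.frame(year = peaks$year[i],
                 date = grid_to_date(peaks$year[i], april_day_to_doy(ads)),
                 count = cnt)
    })
    caterpillar_falls(do.call(rbind, rows))
  })
}

#' Simulate a full synthetic cohort (climate, breeding, caterpillars)
#'
#' Convenience wrapper running the three generators with stage seeds
#' derived from `truth$seed`.
#'
#' @param truth A [generator_truth] object.
#' @return List with elements `climate`, `attempts`, `caterpillars`,
#'   `truth`, of class `synthetic_cohort`.
#' @export
simulate_cohort <- function(truth = generator_truth()) {
  climate <- simulate_climate(truth)
  structure(list(climate = climate,
                 attempts = simulate_breeding_cohort(climate, truth),
                 caterpillars = simulate_caterpillar_falls(climate, truth),
                 truth = truth),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk in the package's CSV formats
#'
#' Emits `temperature.csv`, `breeding.csv`, `caterpillar.csv` and
#' `truth.json` (the recovery-test oracle) under `dir`.
#'
#' @param cohort A `synthetic_cohort` list.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_daily_temperature(cohort$climate, file.path(dir, "temperature.csv"))
  write_breeding_table(cohort$attempts, file.path(dir, "breeding.csv"))
  write_caterpillar_counts(cohort$caterpillars,
                           file.path(dir, "caterpillar.csv"))
  jsonlite::write_json(unclass(cohort$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
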