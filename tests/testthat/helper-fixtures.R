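# Shared fixtures, generated in code and cached across test files.
.fixture_env <- new.env(parent = emptyenv())

# A 20-year x 40-female cohort with defaults otherwise; interval temps and
# half-fall table precomputed.
small_cohort <- function() {
  if (is.null(.fixture_env$co)) {
    tr <- generator_truth(years = 1965:1984, n_females = 40, seed = 7)
    co <- simulate_cohort(tr)
    co$interval_temps <- relative_period_temperatures(co$attempts,
                                                      co$climate)
    co$half_fall <- half_fall_table(co$caterpillars)
    co$mismatch <- compute_match(co$attempts, co$half_fall)
    .fixture_env$co <- co
  }
  .fixture_env$co
}

# Constant-temperature series: `value` degC every day of `years`.
constant_series <- function(value = 10, years = 1965:1970) {
  daily_temps(rep(years, each = 365L), rep(1:365, length(years)),
              rep(value, 365L * length(years)))
}

# Deterministic seasonal + linear-trend series (no noise).
deterministic_series <- function(years = 1965:1984, slope = 0.03,
                                 amplitude = 6.8, mean_t = 9.5) {
  doy <- rep(1:365, length(years))
  yr <- rep(years, each = 365L)
  temp <- mean_t + amplitude * sin(2 * pi * (doy - 105.75) / 365) +
    slope * (yr - years[1L])
  daily_temps(yr, doy, temp)
}

# One valid breeding row as a list (overridable fields).
breeding_row <- function(attempt_id = "a1", year = 1970L,
                         female_id = "f1", laying_april_day = 20L,
                         clutch_size = 8L,
                         incubation_start_april_day = 28L,
                         hatch_april_day = 41L, n_fledged = 6L,
                         n_recruits = 1L, n_neighbors = 4L) {
  data.frame(attempt_id = attempt_id, year = year, female_id = female_id,
             laying_april_day = laying_april_day,
             clutch_size = clutch_size,
             incubation_start_april_day = incubation_start_april_day,
             hatch_april_day = hatch_april_day, n_fledged = n_fledged,
             n_recruits = n_recruits, n_neighbors = n_neighbors)
}
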