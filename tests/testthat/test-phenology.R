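make_falls <- function(counts, year = 1970L, start = "1970-05-01") {
  caterpillar_falls(data.frame(year = year,
                               date = as.Date(start) + seq_along(counts) - 1L,
                               count = counts))
}

test_that("half-fall date follows the cumulative 50% rule", {
  # all counts on one date
  one <- make_falls(c(0L, 25L, 0L))
  expect_equal(half_fall_date(one)$date, as.Date("1970-05-02"))
  # cumulative 10, 40, 80, 100: the 50-count threshold falls on day 3
  hf <- half_fall_date(make_falls(c(10L, 30L, 40L, 20L)))
  expect_equal(hf$date, as.Date("1970-05-03"))
  expect_equal(hf$total_count, 100L)
  # cumulative exactly 50% at day 2 -> day 2 (earliest >= half)
  expect_equal(half_fall_date(make_falls(c(30L, 20L, 50L)))$date,
               as.Date("1970-05-02"))
})

test_that("half-fall equals a brute-force oracle on random series", {
  set.seed(9)
  for (r in 1:200) {
    counts <- rpois(sample(3:30, 1), sample(1:20, 1))
    if (sum(counts) == 0) counts[1] <- 1L
    hf <- half_fall_date(make_falls(as.integer(counts)))
    oracle <- which(cumsum(counts) >= sum(counts) / 2)[1]
    expect_equal(hf$date, as.Date("1970-05-01") + oracle - 1L)
  }
})

test_that("half-fall trend equals closed-form OLS on a hand fixture", {
  hf <- data.frame(year = c(1970, 1975, 1981, 1990, 2000),
                   april_day = c(60, 58, 55, 52, 49))
  tf <- half_fall_trend(hf)
  xc <- hf$year - mean(hf$year)
  slope <- sum(xc * hf$april_day) / sum(xc^2)
  expect_equal(tf$slope, slope, tolerance = 1e-12)
  expect_equal(tf$n, 5L)
})

test_that("temperature around half-fall equals brute force at all halfwidths", {
  co <- small_cohort()
  m <- phenotherm:::temp_matrix(co$climate)
  hf <- co$half_fall
  for (hw in c(7L, 15L, 20L)) {
    got <- temperature_at_half_fall(co$climate, hf, hw)
    expect_equal(got$n_days, rep(2L * hw + 1L, nrow(hf)))
    for (i in c(1L, nrow(hf))) {
      doy <- april_day_to_doy(hf$april_day[i])
      oracle <- mean(m[as.character(hf$year[i]), (doy - hw):(doy + hw)])
      expect_equal(got$value[i], oracle, tolerance = 1e-12)
    }
  }
  # constant series gives the constant
  sc <- constant_series(9, 1970)
  hf1 <- data.frame(year = 1970L, april_day = 50L)
  expect_equal(temperature_at_half_fall(sc, hf1, 7L)$value, 9)
})

test_that("match is (hatch + 10) - half-fall, antisymmetric, abs >= 0", {
  att <- breeding_attempts(breeding_row(year = 1970L,
                                        hatch_april_day = 30L))
  hf <- data.frame(year = 1970L, april_day = 42L)
  mm <- compute_match(att, hf)
  expect_equal(mm$match_days, -2L)
  expect_equal(mm$abs_mismatch, 2L)
  # hatch + 10 equal to half-fall -> zero match
  hf0 <- data.frame(year = 1970L, april_day = 40L)
  expect_equal(compute_match(att, hf0)$match_days, 0L)
  # swapping the two dates flips the sign
  att2 <- breeding_attempts(breeding_row(year = 1970L,
                                         hatch_april_day = 32L))
  hf2 <- data.frame(year = 1970L, april_day = 40L)  # hatch+10 = 42
  expect_equal(compute_match(att2, hf2)$match_days,
               -compute_match(att, hf)$match_days)
  # attempts without hatch or half-fall are dropped with a count
  att3 <- breeding_attempts(rbind(breeding_row("x1"),
                                  breeding_row("x2", year = 1971L)))
  mm3 <- compute_match(att3, hf)
  expect_equal(nrow(mm3), 1L)
  expect_equal(attr(mm3, "n_dropped"), 1L)
  expect_true(all(compute_match(small_cohort()$attempts,
                                small_cohort()$half_fall)$abs_mismatch >= 0))
})

test_that("mismatch curve recovers a quadratic thermal minimum", {
  # attempts whose absolute mismatch is ~(T - 10.5)^2 plus noise
  set.seed(14)
  n_yr <- 25L; n_f <- 80L
  yrs <- rep(1985:2009, each = n_f)
  att <- breeding_attempts(data.frame(
    attempt_id = sprintf("m%04d", seq_len(n_yr * n_f)),
    year = yrs, female_id = sprintf("f%03d", rep(1:n_f, n_yr)),
    laying_april_day = 20L, clutch_size = 8L,
    incubation_start_april_day = 28L, hatch_april_day = 41L,
    n_fledged = 6L, n_recruits = 0L, n_neighbors = 4L))
  tmp <- rnorm(n_yr * n_f, 10.5, 1.8) + rnorm(n_yr, 0, 0.5)[rep(1:n_yr, each = n_f)]
  it <- data.frame(attempt_id = att$attempt_id, year = att$year,
                   period = "laying", start_april_day = 20L,
                   end_april_day = 27L, mean_temp = tmp,
                   n_days = 8L, n_missing = 0L)
  mm <- data.frame(attempt_id = att$attempt_id,
                   match_days = 0L,
                   abs_mismatch = 2 * (tmp - 10.5)^2 +
                     abs(rnorm(n_yr * n_f, 0, 2)))
  mc <- mismatch_temperature_curve(att, it, mm, "laying", n_boot = 100,
                                   seed = 2)
  expect_equal(mc$minimum$direction, "min")
  expect_lt(abs(mc$minimum$peak_temp - 10.5), 0.5)
  expect_false(mc$minimum$at_boundary)
})

test_that("constant mismatch yields a non-identifiable flat curve", {
  co <- small_cohort()
  mm <- co$mismatch
  mm$abs_mismatch <- 5L
  mc <- suppressWarnings(mismatch_temperature_curve(
    co$attempts, co$interval_temps, mm, "laying", n_boot = 0))
  expect_false(mc$minimum$identifiable)
  expect_true(all(is.na(mc$minimum$interval)))
})

test_that("the fledging period is not an admissible mismatch period", {
  co <- small_cohort()
  expect_error(mismatch_temperature_curve(co$attempts, co$interval_temps,
                                          co$mismatch, "fledging"))
  for (p in c("laying", "incubation", "hatching", "nestling"))
    expect_no_error(match.arg(p, c("laying", "incubation", "hatching",
                                   "nestling")))
})

test_that("cue-window search structure: single candidate wins, rows match", {
  co <- small_cohort()
  lay <- annual_laying_means(co$attempts)
  one <- enumerate_calendar_windows("02-15", "03-25", 39L, 39L)
  got <- cue_window_search(lay, co$climate, one)
  expect_equal(nrow(got$support), 1L)
  expect_equal(got$best$start_md, "02-15")
  many <- enumerate_calendar_windows("02-01", "04-15", 30L, 32L)
  got2 <- cue_window_search(lay, co$climate, many)
  expect_equal(nrow(got2$support), nrow(many))
  expect_equal(got2$support$delta_aicc[1], 0)
  expect_true(!is.unsorted(got2$support$aicc))
})
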