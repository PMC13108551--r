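test_that("noiseless linear series recovers its slope exactly", {
  yrs <- 1965:1980
  tf <- suppressWarnings(   # summary.lm warns on an exact fit
    fit_annual_trend(data.frame(year = yrs,
                                value = 2 + 0.03 * (yrs - 1965))))
  expect_equal(tf$slope, 0.03, tolerance = 1e-10)
  expect_lt(tf$slope_se, 1e-8)
  expect_equal(tf$r_squared, 1, tolerance = 1e-10)
})

test_that("annual OLS equals the closed-form normal equations", {
  yrs <- c(1965, 1967, 1970, 1971, 1975, 1980)
  vals <- c(4.2, 3.9, 5.1, 4.8, 5.9, 5.4)
  tf <- fit_annual_trend(data.frame(year = yrs, value = vals))
  # independent normal-equations oracle
  xc <- yrs - mean(yrs)
  slope <- sum(xc * vals) / sum(xc^2)
  resid <- vals - mean(vals) - slope * xc
  se <- sqrt(sum(resid^2) / (length(yrs) - 2) / sum(xc^2))
  expect_equal(tf$slope, slope, tolerance = 1e-12)
  expect_equal(tf$slope_se, se, tolerance = 1e-12)
  expect_equal(tf$F_stat, (slope / se)^2, tolerance = 1e-10)
  expect_equal(tf$df, c(1L, 4L))
  expect_equal(tf$n, 6L)
})

test_that("OLS slope is invariant to centering year and shifting values", {
  set.seed(31)
  yrs <- 1965:1990
  vals <- 5 + 0.02 * yrs + rnorm(26, 0, 0.5)
  a <- fit_annual_trend(data.frame(year = yrs, value = vals))
  b <- fit_annual_trend(data.frame(year = yrs - 1977, value = vals))
  d <- fit_annual_trend(data.frame(year = yrs, value = vals + 100))
  expect_equal(a$slope, b$slope, tolerance = 1e-12)
  expect_equal(a$slope, d$slope, tolerance = 1e-12)
  expect_equal(a$slope_se, d$slope_se, tolerance = 1e-12)
})

test_that("degenerate annual input is rejected", {
  expect_error(fit_annual_trend(data.frame(year = 1:2, value = 1:2)),
               "at least 3")
  expect_error(fit_annual_trend(data.frame(year = rep(1970, 5),
                                           value = rnorm(5))),
               "constant")
})

test_that("mixed trend collapses to OLS when group variance is zero", {
  set.seed(42)
  yrs <- rep(1965:1984, each = 30)
  df <- data.frame(year = yrs,
                   female_id = sprintf("f%02d", rep(1:60, 10)),
                   value = 3 + 0.05 * (yrs - 1965) +
                     rnorm(length(yrs), 0, 0.01))
  mx <- fit_attempt_level_trend(df)
  ols <- coef(lm(value ~ year, df))[["year"]]
  expect_equal(mx$fixed_slope, ols, tolerance = 1e-6)
  expect_true(mx$singular)   # variance components at the 0 boundary
})

test_that("mixed model reports exactly two random-intercept components", {
  co <- small_cohort()
  mx <- fit_attempt_level_trend(co$attempts, "laying_april_day")
  expect_setequal(names(mx$variance_components),
                  c("year", "female", "residual"))
  expect_true(all(mx$variance_components >= 0))
  expect_equal(unname(mx$n_groups["year"]), 20L)
  expect_true(is.finite(mx$satterthwaite_df))
  # Wald path agrees on the slope and skips the df approximation
  mw <- fit_attempt_level_trend(co$attempts, "laying_april_day",
                                ddf = "wald")
  expect_equal(mw$fixed_slope, mx$fixed_slope, tolerance = 1e-8)
  expect_true(is.na(mw$satterthwaite_df))
})

test_that("known variance components are recovered in simulation", {
  recover <- function(rep) {
    set.seed(600 + rep)
    n_yr <- 25L; n_f <- 80L
    yr <- rep(1:n_yr, each = n_f)
    fem <- rep(sprintf("f%03d", 1:n_f), n_yr)
    u_yr <- rnorm(n_yr, 0, 1)          # year variance 1
    u_f <- rnorm(n_f, 0, sqrt(0.5))    # female variance 0.5
    df <- data.frame(year = yr + 1964, female_id = fem,
                     value = u_yr[yr] + u_f[rep(1:n_f, n_yr)] +
                       rnorm(n_yr * n_f))
    fit_attempt_level_trend(df, ddf = "wald")$variance_components
  }
  comps <- vapply(1:50, recover, numeric(3))
  expect_lt(abs(median(comps["year", ]) - 1), 0.25)
  expect_lt(abs(median(comps["female", ]) - 0.5), 0.125)
})

test_that("every window slope equals the trend on a deterministic climate", {
  s <- deterministic_series(1965:1984, slope = 0.03)
  w <- enumerate_calendar_windows()
  d <- sliding_window_slope_distribution(s, w)
  expect_equal(nrow(d$slopes), 804L)
  expect_true(all(abs(d$slopes$slope - 0.03) < 1e-10))
  expect_equal(d$mean_slope, 0.03, tolerance = 1e-10)
})

test_that("window slopes agree with per-window annual OLS", {
  co <- small_cohort()
  w <- enumerate_calendar_windows("02-15", "03-10", 8L, 10L)
  d <- sliding_window_slope_distribution(co$climate, w)
  m <- phenotherm:::temp_matrix(co$climate)
  for (i in c(1L, nrow(w))) {
    means <- rowMeans(m[, w$start_doy[i]:w$end_doy[i]])
    tf <- fit_annual_trend(data.frame(year = as.integer(rownames(m)),
                                      value = means))
    expect_equal(d$slopes$slope[i], tf$slope, tolerance = 1e-10)
    expect_equal(d$slopes$se[i], tf$slope_se, tolerance = 1e-10)
  }
})

test_that("year-shuffled series centre the slope distribution on zero", {
  co <- small_cohort()
  m <- phenotherm:::temp_matrix(co$climate)
  w <- enumerate_calendar_windows(min_len = 10L, max_len = 10L)
  set.seed(8)
  means <- vapply(1:20, function(s) {
    perm <- sample(nrow(m))
    shuffled <- daily_temps(rep(as.integer(rownames(m)), each = 365L),
                            rep(1:365, nrow(m)), as.numeric(t(m[perm, ])))
    sliding_window_slope_distribution(shuffled, w)$mean_slope
  }, numeric(1))
  expect_lt(abs(mean(means)), 2 * sd(means) / sqrt(20) + 0.01)
})
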