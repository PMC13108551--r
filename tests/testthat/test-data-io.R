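test_that("tidy temperature CSV parses directly", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,tmean_c", "1965-02-15,4.1", "1965-02-16,3.9"), f)
  s <- read_daily_temperature(f, "tidy_csv")
  expect_equal(nrow(s), 2L)
  expect_equal(s$temp, c(4.1, 3.9))
  expect_equal(s$doy, c(46L, 47L))
})

test_that("CET daily dialect parses, scales tenths, drops sentinels", {
  # two Februaries of a constructed fixed-width block; -999 on 10 Feb 1966
  set.seed(41)
  tenths <- matrix(sample(-50:150, 56, replace = TRUE), nrow = 28)
  tenths[10, 2] <- -999
  lines <- vapply(1:28, function(d) {
    paste(c(1965, d, tenths[d, 1], rep(-999, 11)), collapse = " ")
  }, character(1))
  lines2 <- vapply(1:28, function(d) {
    paste(c(1966, d, tenths[d, 2], rep(-999, 11)), collapse = " ")
  }, character(1))
  f <- withr::local_tempfile(fileext = ".dat")
  # CET files label month columns; a header line must be tolerated
  writeLines(c(paste(c("year", "day", month.abb), collapse = " "),
               lines, lines2), f)
  s <- read_daily_temperature(f, "cet_daily")
  # independent hand-built mapping, value by value
  expected <- data.frame(year = rep(c(1965L, 1966L), each = 28L),
                         doy = rep(1:28, 2L),
                         temp = c(tenths[, 1], tenths[, 2]) / 10)
  expected <- expected[expected$temp > -90, ]
  expect_equal(nrow(s), 55L)          # 56 minus one sentinel
  expect_equal(s$year, expected$year)
  expect_equal(s$doy, expected$doy)
  expect_equal(s$temp, expected$temp)
  expect_false(any(s$year == 1966L & s$doy == 10L))
})

test_that("a 1965-2023 fixture covers 59 distinct years", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,tmean_c",
               sprintf("%d-05-01,%0.1f", 1965:2023, 10)), f)
  s <- read_daily_temperature(f, "tidy_csv")
  expect_identical(length(unique(s$year)), 59L)
})

test_that("temperature series round-trips through write/read", {
  co <- small_cohort()
  f <- withr::local_tempfile(fileext = ".csv")
  write_daily_temperature(co$climate, f)
  back <- read_daily_temperature(f, "tidy_csv")
  expect_equal(back$year, co$climate$year)
  expect_equal(back$doy, co$climate$doy)
  expect_equal(back$temp, co$climate$temp, tolerance = 1e-12)
})

test_that("series constructor rejects duplicates and non-finite values", {
  expect_error(daily_temps(c(1970, 1970), c(5, 5), c(1, 2)), "duplicate")
  expect_error(daily_temps(1970, 5, NaN), "non-finite")
})

test_that("breeding table reads valid rows and rejects invariant breakers", {
  rows <- rbind(breeding_row("a1"), breeding_row("a2", female_id = "f2"),
                breeding_row("a3", female_id = "f3"))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(rows, f, row.names = FALSE, na = "")
  expect_equal(nrow(read_breeding_table(f)), 3L)

  bad <- breeding_row("bad1", clutch_size = 8L, n_fledged = 9L)
  write.csv(rbind(rows, bad), f, row.names = FALSE, na = "")
  expect_error(read_breeding_table(f), "n_fledged > clutch_size")
  expect_error(read_breeding_table(f), "bad1")
  # permissive mode drops the bad row with diagnostics
  got <- suppressWarnings(read_breeding_table(f, strict = FALSE))
  expect_equal(nrow(got), 3L)
  expect_equal(attr(got, "rejected")$attempt_id, "bad1")

  write.csv(rows[, -4], f, row.names = FALSE, na = "")
  expect_error(read_breeding_table(f), "missing mandatory column")
})

test_that("attempts with absent hatch date load; late periods undefined", {
  row <- breeding_row("nh", incubation_start_april_day = NA,
                      hatch_april_day = NA)
  att <- breeding_attempts(row)
  expect_equal(nrow(att), 1L)
  per <- relative_period_bounds(att[1, ])
  expect_null(per$hatching); expect_null(per$nestling)
  expect_null(per$fledging); expect_null(per$incubation)
  expect_equal(per$laying, c(20L, 27L))  # egg-a-day fallback, clutch 8
})

test_that("breeding table round-trips through write/read", {
  co <- small_cohort()
  f <- withr::local_tempfile(fileext = ".csv")
  write_breeding_table(co$attempts, f)
  back <- read_breeding_table(f)
  expect_equal(as.data.frame(back), as.data.frame(co$attempts))
})

test_that("caterpillar counts load per year and flag zero-total years", {
  df <- data.frame(year = 1970L,
                   date = as.Date("1970-05-20") + 0:3,
                   count = c(5L, 10L, 3L, 0L))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  got <- read_caterpillar_counts(f)
  expect_equal(nrow(got), 4L)
  expect_equal(usable_years(got), 1970L)

  df2 <- rbind(df, data.frame(year = 1971L,
                              date = as.Date("1971-05-20") + 0:1,
                              count = c(0L, 0L)))
  write.csv(df2, f, row.names = FALSE)
  got2 <- read_caterpillar_counts(f)
  expect_equal(usable_years(got2), 1970L)
  expect_error(half_fall_date(got2, 1971L), "unusable")

  df$count[1] <- -2L
  write.csv(df, f, row.names = FALSE)
  expect_error(read_caterpillar_counts(f), "negative")
})

test_that("removing the unavailable study years leaves 45 usable years", {
  missing_years <- c(1972:1974, 1976:1982, 1989:1992)
  years <- setdiff(1965:2023, missing_years)
  df <- data.frame(year = years,
                   date = as.Date(sprintf("%d-05-25", years)),
                   count = 100L)
  got <- caterpillar_falls(df)
  expect_identical(length(usable_years(got)), 45L)
})
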