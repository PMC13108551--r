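test_that("natural spline basis has df columns and contains linearity", {
  set.seed(5)
  x <- rnorm(300, 10, 2)
  B <- natural_cubic_spline_basis(x, spline_spec(df = 7))
  expect_equal(ncol(B), 7L)
  # linear functions lie in the span of intercept + basis
  fit <- lm(x ~ B)
  expect_lt(max(abs(residuals(fit))), 1e-8)
  # natural boundary: second differences vanish beyond the boundary knots
  bk <- attr(B, "Boundary.knots")
  grid <- seq(bk[2] + 0.5, bk[2] + 5, by = 0.01)
  Bg <- phenotherm:::basis_eval(grid, B)
  second_diff <- diff(Bg, differences = 2)
  expect_lt(max(abs(second_diff)), 1e-8)
  expect_error(natural_cubic_spline_basis(rep(1, 50), spline_spec(7)),
               "distinct")
})

test_that("ZIP log-likelihood reduces to Poisson at zero inflation", {
  set.seed(6)
  X <- cbind(1, rnorm(500))
  beta <- c(1.2, 0.4)
  y <- rpois(500, exp(drop(X %*% beta)))
  ll_zip <- phenotherm:::zip_loglik(beta, qlogis(1e-12), X, y)
  ll_pois <- sum(dpois(y, exp(drop(X %*% beta)), log = TRUE))
  expect_equal(ll_zip, ll_pois, tolerance = 1e-6)
})

test_that("the direct ZIP fitter recovers rates and inflation", {
  set.seed(7)
  n <- 4000
  X <- cbind(1, rnorm(n))
  beta <- c(1.5, 0.3); pi0 <- 0.25
  y <- ifelse(runif(n) < pi0, 0L, rpois(n, exp(drop(X %*% beta))))
  fit <- phenotherm:::zip_fit(X, y)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$beta - beta)), 0.05)
  expect_lt(abs(fit$pi - pi0), 0.03)
  # on pure Poisson data the fitted mixture matches the Poisson glm
  y2 <- rpois(n, exp(drop(X %*% beta)))
  fit2 <- phenotherm:::zip_fit(X, y2)
  glm2 <- glm.fit(X, y2, family = poisson())$coefficients
  expect_lt(max(abs(fit2$beta - glm2)), 0.02)
  expect_lt(fit2$pi, 0.05)
})

test_that("clutch-size spline model recovers a planted optimum", {
  tr <- generator_truth(years = 1985:2009, n_females = 80, seed = 12)
  co <- simulate_cohort(tr)
  it <- relative_period_temperatures(co$attempts, co$climate)
  fit <- fit_fitness_response(co$attempts, it, "clutch_size", "laying")
  expect_s3_class(fit, "fitness_fit")
  expect_equal(fit$n_obs, 2000L)
  peak <- locate_peak_with_interval(fit, n_boot = 200, seed = 4)
  expect_false(peak$at_boundary)
  # planted optimum 11.8 inside the bootstrap interval
  expect_lte(peak$interval[1], 11.8)
  expect_gte(peak$interval[2], 11.8)
  expect_lt(abs(peak$peak_temp - 11.8), 1.5)
})

test_that("clutch size is refused outside the laying period", {
  co <- small_cohort()
  expect_error(fit_fitness_response(co$attempts, co$interval_temps,
                                    "clutch_size", "nestling"),
               "laying-period")
})

test_that("binomial model predicts ~1 when every nest fledges its clutch", {
  co <- small_cohort()
  at <- co$attempts
  at$n_fledged <- at$clutch_size
  at$n_recruits <- pmin(at$n_recruits, at$n_fledged)
  fit <- suppressWarnings(fit_fitness_response(at, co$interval_temps,
                                               "fledging_success", "laying"))
  expect_true(all(fit$curve$pred > 0.97))
  expect_true(all(fit$curve$pred <= 1))
})

test_that("fitted curves respect their family ranges", {
  co <- small_cohort()
  fb <- fit_fitness_response(co$attempts, co$interval_temps,
                             "fledging_success", "laying")
  expect_true(all(fb$curve$pred >= 0 & fb$curve$pred <= 1))
  fz <- fit_fitness_response(co$attempts, co$interval_temps,
                             "n_fledged", "laying")
  expect_true(all(fz$curve$pred >= 0))
  expect_equal(fz$family, "zip")
  expect_gt(fz$zi_prob, 0.02)   # generator plants 10% brood failure
  # model object methods behave
  expect_length(predict(fz, c(9, 10, 11)), 3L)
  expect_length(residuals(fz), fz$n_obs)
  expect_true("(Intercept)" %in% names(coef(fz)))
})

test_that("pre/post-peak slopes mirror the generator's symmetric hump", {
  # optimum placed at the laying-temperature mean so the design is
  # symmetric around the peak, per the symmetric-hump construction
  tr <- generator_truth(years = 1985:2009, n_females = 80, seed = 12,
                        fitness_optimum_Topt = 10.9)
  co <- simulate_cohort(tr)
  it <- relative_period_temperatures(co$attempts, co$climate)
  fit <- fit_fitness_response(co$attempts, it, "clutch_size", "laying")
  peak <- locate_peak_with_interval(fit, n_boot = 0)
  pw <- fit_prepost_peak_trends(co$attempts, it, "clutch_size", "laying",
                                peak)
  expect_gt(pw$prepeak$slope, 0)
  expect_lt(pw$postpeak$slope, 0)
  # symmetric hump: |pre| ~ |post| within the joint interval
  se <- sqrt(pw$prepeak$se^2 + pw$postpeak$se^2)
  expect_lt(abs(pw$prepeak$slope + pw$postpeak$slope), 2.5 * se)
  expect_false(pw$flagged_pre); expect_false(pw$flagged_post)
})

test_that("temperature is standardized within each peak side", {
  co <- small_cohort()
  it <- co$interval_temps
  lay <- it[it$period == "laying", ]
  peak <- median(lay$mean_temp)
  pre <- lay$mean_temp[lay$mean_temp <= peak]
  z <- phenotherm:::zscale(pre)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("a monotone response flags the boundary peak and one-sided fit", {
  co <- small_cohort()
  it <- co$interval_temps
  lay <- it[it$period == "laying", ]
  # plant a strictly increasing response in temperature
  at <- co$attempts
  tmp <- lay$mean_temp[match(at$attempt_id, lay$attempt_id)]
  at$clutch_size <- 1L + as.integer(round(2 * (tmp - min(tmp, na.rm = TRUE))))
  at$n_fledged <- pmin(at$n_fledged, at$clutch_size)
  at$n_recruits <- pmin(at$n_recruits, at$n_fledged)
  fit <- suppressWarnings(fit_fitness_response(at, it, "clutch_size",
                                               "laying",
                                               spec = spline_spec(4)))
  peak <- locate_peak_with_interval(fit, n_boot = 0)
  expect_true(peak$at_boundary)
  pw <- suppressWarnings(fit_prepost_peak_trends(at, it, "clutch_size",
                                                 "laying", peak))
  expect_equal(pw$n_post, 0L)
  expect_null(pw$postpeak)
  expect_true(pw$flagged_post)
})

test_that("mediation comparison returns two curves and one attenuation", {
  co <- small_cohort()
  med <- compare_with_mismatch_covariate(co$attempts, co$interval_temps,
                                         co$mismatch, "fledging_success")
  expect_named(med$curves, c("without", "with"))
  expect_length(med$attenuation, 1L)
  expect_true(is.finite(med$attenuation))
  # generator's mismatch is independent of fledging here: no attenuation
  expect_gt(med$attenuation, 0.5)
})
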