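#' Locate the extremum of a fitted response curve with a bootstrap interval
#'
#' The point estimate is the argmax (or argmin, for mismatch curves) of the
#' fitted population-level curve on its 0.1 degC grid, ties broken toward
#' the lower temperature. The 95% interval comes from a cluster bootstrap
#' over years: years are resampled with replacement, the fixed-effect
#' structure of the model is refitted on the stacked resample (Poisson /
#' binomial / Gaussian by weighted least squares or IRLS, zero-inflated
#' Poisson by the package's direct ML fitter), the curve is re-located on
#' the same grid, and the percentile interval of the resampled extrema is
#' reported. Resampling whole years carries the between-year variance that
#' the random intercept absorbs in the full fit, so the bootstrap refits do
#' not re-estimate the random effects.
#'
#' @param fit A `fitness_fit` (from [fit_fitness_response] or the Gaussian
#'   mismatch-curve machinery).
#' @param n_boot Bootstrap resamples (default 500); `0` skips the interval.
#' @param seed Seed for the resampling.
#' @param level Interval coverage (default 0.95).
#' @param direction `"max"` for fitness peaks, `"min"` for mismatch
#'   minima.
#' @return A `peak_estimate`: `peak_temp`, `interval`, `at_boundary`,
#'   `identifiable`, `n_boot_ok`, and the vector of bootstrap extrema.
#' @export
locate_peak_with_interval <- function(fit, n_boot = 500L, seed = 1L,
                                      level = 0.95,
                                      direction = c("max", "min")) {
  stopifnot(inherits(fit, "fitness_fit"))
  direction <- match.arg(direction)
  pick <- if (direction == "max") which.max else which.min
  curve <- fit$curve
  identifiable <- diff(range(curve$pred)) >
    1e-6 * (1 + abs(mean(curve$pred)))
  i <- pick(curve$pred)
  peak <- curve$temp[i]
  at_boundary <- i == 1L || i == nrow(curve)
  boot_peaks <- numeric(0)
  if (n_boot > 0L && identifiable) {
    rows_by_year <- split(seq_len(nrow(fit$X)), fit$year)
    years <- names(rows_by_year)
    Bg <- basis_eval(curve$temp, fit$basis)
    ns_cols <- match(colnames(Bg), colnames(fit$X))
    boot_peaks <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      idx <- unlist(rows_by_year[sample(years, replace = TRUE)],
                    use.names = FALSE)
      beta <- tryCatch(.refit_fixed(fit, idx), error = function(e) NULL)
      # rank-deficient resamples (degenerate temperature range) are skipped
      if (is.null(beta) || anyNA(beta[ns_cols])) return(NA_real_)
      g <- drop(Bg %*% beta[ns_cols])
      if (!any(is.finite(g))) return(NA_real_)
      curve$temp[pick(g)]
    }, numeric(1)))
    boot_peaks <- boot_peaks[is.finite(boot_peaks)]
  }
  interval <- if (length(boot_peaks) >= 20L) {
    stats::quantile(boot_peaks, c((1 - level) / 2, 1 - (1 - level) / 2),
                    names = FALSE)
  } else c(NA_real_, NA_real_)
  structure(list(peak_temp = peak, interval = interval,
                 at_boundary = at_boundary, identifiable = identifiable,
                 direction = direction, level = level,
                 n_boot = n_boot, n_boot_ok = length(boot_peaks),
                 boot_peaks = boot_peaks),
            class = "peak_estimate")
}

# Fixed-effect refit of a fitness_fit's design on a row subset; returns
# the coefficient vector aligned with colnames(fit$X).
.refit_fixed <- function(fit, idx) {
  X <- fit$X[idx, , drop = FALSE]
  switch(fit$family,
         poisson = stats::glm.fit(X, fit$y[idx],
                                  family = stats::poisson())$coefficients,
         binomial = stats::glm.fit(X, fit$y[idx] / fit$trials[idx],
                                   weights = fit$trials[idx],
                                   family = stats::binomial())$coefficients,
         zip = zip_fit(X, fit$y[idx])$beta,
         gaussian = stats::lm.fit(X, fit$y[idx])$coefficients)
}

#' @export
print.peak_estimate <- function(x, digits = 2, ...) {
  what <- if (x$direction == "max") "peak" else "minimum"
  if (!x$identifiable) {
    cat(sprintf("<peak_estimate> %s not identifiable (flat curve)\n", what))
    return(invisible(x))
  }
  cat(sprintf("<peak_estimate> %s %.2f degC [%s, %s] (%d%% cluster ",
              what, x$peak_temp,
              formatC(x$interval[1L], digits = digits, format = "f"),
              formatC(x$interval[2L], digits = digits, format = "f"),
              round(100 * x$level)))
  cat(sprintf("bootstrap, %d/%d resamples)%s\n", x$n_boot_ok, x$n_boot,
              if (x$at_boundary) " [at grid boundary]" else ""))
  invisible(x)
}

#' Linear temperature trends on either side of a fitness peak
#'
#' Refits the response model below and above the estimated optimum with
#' temperature as a linear term, standardized within each subset (so the
#' slopes are per-SD, link-scale effects), keeping the family, covariates
#' and random intercepts of the main model. Observations exactly at the
#' peak go to the pre side. A side with fewer than `min_side` observations
#' is flagged; an empty side is absent.
#'
#' @inheritParams fit_fitness_response
#' @param peak A `peak_estimate` (or a single temperature).
#' @param min_side Minimum observations per side before flagging
#'   (default 30).
#' @return A `piecewise_trend`: per-side slope, SE, 95% Wald interval, n,
#'   and flags.
#' @export
fit_prepost_peak_trends <- function(attempts, interval_temps, response,
                                    period, peak, mismatch = NULL,
                                    min_side = 30L) {
  response <- match.arg(response, names(.FITNESS_FAMILIES))
  period <- match.arg(period, .PERIODS)
  peak_temp <- if (inherits(peak, "peak_estimate")) peak$peak_temp
               else as.numeric(peak)
  df <- .assemble_model_data(attempts, interval_temps, period, mismatch)
  family_name <- .FITNESS_FAMILIES[[response]]
  side <- function(sub) {
    if (!nrow(sub)) return(NULL)
    .linear_glmm_slope(sub, response, family_name,
                       use_mismatch = !is.null(mismatch))
  }
  pre <- side(df[df$mean_temp <= peak_temp, , drop = FALSE])
  post <- side(df[df$mean_temp > peak_temp, , drop = FALSE])
  structure(list(prepeak = pre, postpeak = post,
                 n_pre = sum(df$mean_temp <= peak_temp),
                 n_post = sum(df$mean_temp > peak_temp),
                 flagged_pre = sum(df$mean_temp <= peak_temp) < min_side,
                 flagged_post = sum(df$mean_temp > peak_temp) < min_side,
                 peak_temp = peak_temp, response = response,
                 period = period),
            class = "piecewise_trend")
}

# Slope of standardized temperature in a linear-term GLMM on one subset.
.linear_glmm_slope <- function(df, response, family_name, use_mismatch) {
  md <- data.frame(z_temp = zscale(df$mean_temp),
                   z_laydate = zscale(df$laying_april_day),
                   z_neighbors = zscale(df$n_neighbors),
                   year_f = df$year_f, female = df$female)
  covs <- c("z_temp", "z_laydate", "z_neighbors")
  if (family_name == "binomial") {
    md$z_clutch <- zscale(df$clutch_size)
    covs <- c(covs, "z_clutch")
    md$n_fledged <- df$n_fledged; md$clutch_size <- df$clutch_size
    lhs <- "cbind(n_fledged, clutch_size - n_fledged)"
  } else {
    md[[response]] <- df[[response]]
    lhs <- response
  }
  if (use_mismatch) {
    md$z_mismatch <- zscale(df$abs_mismatch)
    covs <- c(covs, "z_mismatch")
  }
  rhs <- paste(c(covs, "(1 | year_f)", "(1 | female)"), collapse = " + ")
  fam <- if (family_name == "binomial") stats::binomial()
         else stats::poisson()
  zif <- if (family_name == "zip") ~1 else ~0
  fit <- tryCatch(
    glmmTMB::glmmTMB(stats::as.formula(paste(lhs, "~", rhs)), data = md,
                     family = fam, ziformula = zif),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  co <- stats::coef(summary(fit))$cond
  list(slope = co["z_temp", "Estimate"],
       se = co["z_temp", "Std. Error"],
       ci = co["z_temp", "Estimate"] +
         c(-1, 1) * 1.96 * co["z_temp", "Std. Error"],
       p_value = co["z_temp", "Pr(>|z|)"],
       n = nrow(md))
}

#' @export
print.piecewise_trend <- function(x, ...) {
  cat(sprintf("<piecewise_trend> %s vs %s-period temperature, peak %.2f degC\n",
              x$response, x$period, x$peak_temp))
  show <- function(lbl, s, n, flag) {
    if (is.null(s)) cat(sprintf("  %s: absent (n = %d)\n", lbl, n))
    else cat(sprintf("  %s: %.3f [%.3f, %.3f] (n = %d%s)\n", lbl, s$slope,
                     s$ci[1L], s$ci[2L], n,
                     if (flag) ", flagged: small side" else ""))
  }
  show("prepeak ", x$prepeak, x$n_pre, x$flagged_pre)
  show("postpeak", x$postpeak, x$n_post, x$flagged_post)
  invisible(x)
}

#' Does trophic mismatch mediate the temperature-fitness association?
#'
#' Fits the spline response model with and without standardized absolute
#' mismatch as a covariate (on the attempts that have a mismatch record,
#' i.e. years with caterpillar half-fall data), and compares the post-peak
#' linear slopes of the two fits. The attenuation factor is
#' `|post-peak slope with mismatch| / |post-peak slope without|`; values
#' near zero mean the temperature association runs through synchrony with
#' the food peak.
#'
#' @inheritParams fit_fitness_response
#' @param mismatch Mismatch table from [compute_match] (required here).
#' @return A `mediation_comparison`: both fitted curves, both post-peak
#'   slopes, the attenuation factor and the shared peak estimate.
#' @export
compare_with_mismatch_covariate <- function(attempts, interval_temps,
                                            mismatch,
                                            response = c("n_fledged",
                                                         "fledging_success"),
                                            period = "laying",
                                            spec = spline_spec()) {
  response <- match.arg(response)
  keep <- attempts$attempt_id %in% mismatch$attempt_id
  att <- attempts[keep, , drop = FALSE]
  class(att) <- class(attempts)
  base <- fit_fitness_response(att, interval_temps, response, period, spec)
  adj <- fit_fitness_response(att, interval_temps, response, period, spec,
                              mismatch = mismatch)
  peak <- locate_peak_with_interval(base, n_boot = 0L)
  pw_base <- fit_prepost_peak_trends(att, interval_temps, response, period,
                                     peak)
  pw_adj <- fit_prepost_peak_trends(att, interval_temps, response, period,
                                    peak, mismatch = mismatch)
  s0 <- pw_base$postpeak; s1 <- pw_adj$postpeak
  attenuation <- if (!is.null(s0) && !is.null(s1) && abs(s0$slope) > 0)
    abs(s1$slope / s0$slope) else NA_real_
  structure(list(curves = list(without = base$curve, with = adj$curve),
                 post_without = s0, post_with = s1,
                 attenuation = attenuation, peak = peak,
                 response = response, period = period,
                 n_obs = base$n_obs),
            class = "mediation_comparison")
}

#' @export
print.mediation_comparison <- function(x, ...) {
  cat(sprintf(
    "<mediation_comparison> %s vs %s temperature, n = %d (half-fall years)\n",
    x$response, x$period, x$n_obs))
  f <- function(s) if (is.null(s)) "absent"
    else sprintf("%.3f [%.3f, %.3f]", s$slope, s$ci[1L], s$ci[2L])
  cat("  post-peak slope without mismatch:", f(x$post_without), "\n")
  cat("  post-peak slope with mismatch:   ", f(x$post_with), "\n")
  cat(sprintf("  attenuation factor |with/without| = %.3f\n",
              x$attenuation))
  invisible(x)
}
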