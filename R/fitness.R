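# Merge attempts with the period temperatures (and optionally mismatch)
# into one model frame.
.assemble_model_data <- function(attempts, interval_temps, period,
                                 mismatch = NULL) {
  stopifnot(period %in% .PERIODS)
  it <- interval_temps[interval_temps$period == period,
                       c("attempt_id", "mean_temp")]
  df <- merge(as.data.frame(attempts), it, by = "attempt_id")
  if (!is.null(mismatch)) {
    df <- merge(df, as.data.frame(mismatch)[, c("attempt_id",
                                                "abs_mismatch")],
                by = "attempt_id")
  }
  df <- df[is.finite(df$mean_temp), , drop = FALSE]
  if (!nrow(df)) stop("no attempts with a temperature for period ", period)
  df$year_f <- factor(df$year)
  df$female <- factor(df$female_id)
  df
}

.FITNESS_FAMILIES <- c(clutch_size = "poisson", n_fledged = "zip",
                       fledging_success = "binomial", n_recruits = "zip")

#' Spline response model of reproductive success versus period temperature
#'
#' The package's central model: a generalized linear mixed model of one
#' reproductive-success measure on the mean temperature of one relative
#' reproductive period, with the temperature entering through a natural
#' cubic spline (default 7 df), laying date and neighbor count (plus
#' clutch size for fledging success, plus absolute trophic mismatch when
#' supplied) as standardized linear covariates, and random intercepts for
#' year and female. Families follow the nature of each response: clutch
#' size is Poisson; fledged and recruit counts are zero-inflated Poisson
#' with an intercept-only inflation component (wholesale brood failure);
#' fledging success is binomial successes-out-of-clutch. Fitting is
#' Laplace-approximate maximum likelihood via glmmTMB.
#'
#' Clutch size is only meaningful against laying-period temperature (the
#' other periods fall after clutch completion), and the function enforces
#' that restriction.
#'
#' @param attempts A `breeding_attempts` table.
#' @param interval_temps Output of [relative_period_temperatures].
#' @param response One of `"clutch_size"`, `"n_fledged"`,
#'   `"fledging_success"`, `"n_recruits"`.
#' @param period One of the five relative periods.
#' @param spec A [spline_spec] (default 7 df).
#' @param mismatch Optional mismatch table (from [compute_match]); adds
#'   standardized absolute mismatch as a covariate and restricts the data
#'   to attempts with a mismatch record.
#' @param grid_step Temperature grid resolution for the predicted curve
#'   (degC, default 0.1).
#' @return A `fitness_fit` object with the fitted model, the predicted
#'   population-level curve on the temperature grid (with a 95% Wald band
#'   on the conditional mean), and the design information reused by the
#'   cluster bootstrap.
#' @seealso [locate_peak_with_interval], [fit_prepost_peak_trends],
#'   [compare_with_mismatch_covariate]
#' @export
fit_fitness_response <- function(attempts, interval_temps,
                                 response = names(.FITNESS_FAMILIES),
                                 period = .PERIODS,
                                 spec = spline_spec(),
                                 mismatch = NULL,
                                 grid_step = 0.1) {
  response <- match.arg(response)
  period <- match.arg(period)
  if (response == "clutch_size" && period != "laying")
    stop("clutch size is analyzed only against laying-period temperature")
  df <- .assemble_model_data(attempts, interval_temps, period, mismatch)
  family_name <- .FITNESS_FAMILIES[[response]]
  .fit_spline_glmm(df, response, family_name, spec, period, grid_step,
                   use_mismatch = !is.null(mismatch))
}

# Shared by fitness responses (counts/binomial) and the Gaussian mismatch
# curve; `response` names the y construction.
.fit_spline_glmm <- function(df, response, family_name, spec, period,
                             grid_step, use_mismatch = FALSE) {
  B <- natural_cubic_spline_basis(df$mean_temp, spec)
  md <- data.frame(B, z_laydate = zscale(df$laying_april_day),
                   z_neighbors = zscale(df$n_neighbors),
                   year_f = df$year_f, female = df$female,
                   year = df$year)
  covs <- c("z_laydate", "z_neighbors")
  if (family_name == "binomial") {
    md$z_clutch <- zscale(df$clutch_size)
    covs <- c(covs, "z_clutch")
  }
  if (use_mismatch) {
    md$z_mismatch <- zscale(df$abs_mismatch)
    covs <- c(covs, "z_mismatch")
  }
  if (family_name == "gaussian") covs <- character(0)  # mismatch curve
  lhs <- switch(family_name,
                binomial = "cbind(n_fledged, clutch_size - n_fledged)",
                gaussian = "abs_mismatch",
                response)
  if (lhs %in% c("clutch_size", "n_fledged", "n_recruits", "abs_mismatch"))
    md[[lhs]] <- df[[if (family_name == "gaussian") "abs_mismatch"
                     else response]]
  if (family_name == "binomial") {
    md$n_fledged <- df$n_fledged
    md$clutch_size <- df$clutch_size
  }
  rhs <- paste(c(colnames(B), covs, "(1 | year_f)", "(1 | female)"),
               collapse = " + ")
  fam <- switch(family_name,
                poisson = stats::poisson(),
                zip = stats::poisson(),
                binomial = stats::binomial(),
                gaussian = stats::gaussian())
  zif <- if (family_name == "zip") ~1 else ~0
  model <- glmmTMB::glmmTMB(stats::as.formula(paste(lhs, "~", rhs)),
                            data = md, family = fam, ziformula = zif)
  if (!isTRUE(model$sdr$pdHess)) {
    gr <- tryCatch(max(abs(model$obj$gr(model$fit$par))),
                   error = function(e) NA_real_)
    warning("spline GLMM did not reach a positive-definite Hessian ",
            "(max |gradient| ", signif(gr, 3),
            "); treat the curve with caution")
  }

  beta <- glmmTMB::fixef(model)$cond
  V <- as.matrix(stats::vcov(model)$cond)
  zi_prob <- if (family_name == "zip")
    stats::plogis(glmmTMB::fixef(model)$zi[[1L]]) else 0
  grid <- seq(min(df$mean_temp), max(df$mean_temp), by = grid_step)
  if (grid[length(grid)] < max(df$mean_temp))
    grid <- c(grid, max(df$mean_temp))   # grid always reaches the extremes
  Xg <- cbind(1, basis_eval(grid, B),
              matrix(0, length(grid), length(covs)))
  colnames(Xg) <- c("(Intercept)", colnames(B), covs)
  Xg <- Xg[, names(beta), drop = FALSE]
  eta <- drop(Xg %*% beta)
  se <- sqrt(rowSums((Xg %*% V) * Xg))
  linkinv <- fam$linkinv
  scale_mean <- if (family_name == "zip") (1 - zi_prob) else 1
  curve <- data.frame(temp = grid,
                      pred = scale_mean * linkinv(eta),
                      lo = scale_mean * linkinv(eta - 1.96 * se),
                      hi = scale_mean * linkinv(eta + 1.96 * se))
  # design retained for the year-cluster bootstrap
  X <- cbind(1, B, as.matrix(md[covs]))
  colnames(X) <- c("(Intercept)", colnames(B), covs)
  y <- switch(family_name,
              binomial = df$n_fledged,
              gaussian = df$abs_mismatch,
              df[[response]])
  structure(list(model = model, response = response, period = period,
                 family = family_name, spec = spec, basis = B,
                 curve = curve, X = X, y = y,
                 trials = if (family_name == "binomial") df$clutch_size,
                 year = as.character(df$year_f),
                 zi_prob = zi_prob, n_obs = nrow(df),
                 covariates = covs),
            class = "fitness_fit")
}

#' @export
print.fitness_fit <- function(x, ...) {
  i <- which.max(x$curve$pred)
  cat(sprintf(
    "<fitness_fit> %s ~ ns(%s-period temperature, df = %d), family %s\n",
    x$response, x$period, x$spec$df, x$family))
  cat(sprintf("  n = %d; covariates: %s\n", x$n_obs,
              paste(x$covariates, collapse = ", ")))
  if (x$family == "zip")
    cat(sprintf("  zero-inflation probability %.3f\n", x$zi_prob))
  cat(sprintf("  curve maximum %.3f at %.1f degC (grid %d points)\n",
              x$curve$pred[i], x$curve$temp[i], nrow(x$curve)))
  invisible(x)
}

#' @export
summary.fitness_fit <- function(object, ...) {
  print(object)
  summary(object$model)
}

#' @export
coef.fitness_fit <- function(object, ...) glmmTMB::fixef(object$model)$cond

#' @export
residuals.fitness_fit <- function(object, type = "pearson", ...) {
  stats::residuals(object$model, type = type)
}

#' Predict the population-level response at new temperatures
#'
#' Covariates are held at their (standardized) means and random effects at
#' zero; for zero-inflated families the prediction is the unconditional
#' mean `(1 - pi) * lambda`.
#'
#' @param object A `fitness_fit`.
#' @param newtemps Numeric temperatures (degC); defaults to the fitted
#'   grid.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.fitness_fit <- function(object, newtemps = NULL, ...) {
  if (is.null(newtemps)) return(object$curve$pred)
  beta <- glmmTMB::fixef(object$model)$cond
  Xg <- cbind(1, basis_eval(newtemps, object$basis),
              matrix(0, length(newtemps), length(object$covariates)))
  colnames(Xg) <- c("(Intercept)", paste0("ns", seq_len(object$spec$df)),
                    object$covariates)
  eta <- drop(Xg[, names(beta), drop = FALSE] %*% beta)
  fam <- switch(object$family, binomial = stats::binomial(),
                gaussian = stats::gaussian(), stats::poisson())
  scale_mean <- if (object$family == "zip") 1 - object$zi_prob else 1
  scale_mean * fam$linkinv(eta)
}

#' @export
plot.fitness_fit <- function(x, peak = NULL, ...) {
  cv <- x$curve
  graphics::plot(cv$temp, cv$pred, type = "n",
                 ylim = range(cv$lo, cv$hi),
                 xlab = sprintf("%s-period temperature (degC)", x$period),
                 ylab = x$response, ...)
  graphics::polygon(c(cv$temp, rev(cv$temp)), c(cv$lo, rev(cv$hi)),
                    col = grDevices::adjustcolor("grey60", 0.4),
                    border = NA)
  graphics::lines(cv$temp, cv$pred, lwd = 2)
  if (!is.null(peak)) {
    graphics::abline(v = peak$peak_temp, lty = 2)
    if (all(is.finite(peak$interval)))
      graphics::abline(v = peak$interval, lty = 3, col = "grey40")
  }
  invisible(x)
}
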