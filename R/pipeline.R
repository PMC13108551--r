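.PIPELINE_DEFAULTS <- list(
  fixed_window = list(start = "02-15", end = "06-05"),
  window_lengths = list(min = 8L, max = 15L),
  cue_window_lengths = list(min = 25L, max = 35L),
  cue_span = list(start = "02-01", end = "05-15"),
  spline_df = 7L,
  n_boot = 200L,
  halfwidth = 7L,
  fitness_responses = c("clutch_size", "n_fledged", "fledging_success",
                        "n_recruits"),
  fitness_periods = "laying",
  mismatch_periods = "laying",
  seed = 1L,
  verbose = TRUE)

#' Build and validate a pipeline configuration
#'
#' A configuration either names the three input files (`inputs:` with
#' `temperature`, `temperature_dialect`, `breeding` and optionally
#' `caterpillar`) or carries a `truth:` block of [generator_truth]
#' overrides for a synthetic cohort - one of the two, never neither. All
#' randomness (generator, bootstrap) flows from the single root `seed`.
#'
#' @param x A named list, or the path of a YAML file holding one.
#' @return A validated `pipeline_config` list with defaults filled in.
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  unknown <- setdiff(names(x),
                     c(names(.PIPELINE_DEFAULTS), "inputs", "truth",
                       "out_dir"))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.PIPELINE_DEFAULTS, x)
  has_inputs <- !is.null(cfg$inputs); has_truth <- !is.null(cfg$truth)
  if (!has_inputs && !has_truth)
    stop("config must carry either an `inputs` block or a `truth` block")
  if (has_inputs && has_truth)
    stop("config carries both `inputs` and `truth`; pick one")
  if (has_inputs && is.null(cfg$inputs$temperature))
    stop("inputs block must name a `temperature` file")
  if (has_inputs && is.null(cfg$inputs$breeding))
    stop("inputs block must name a `breeding` file")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full thermal-niche-tracking analysis
#'
#' Executes the stages in the order of the underlying inference chain:
#' ingest or simulate; relative and fixed interval temperatures; trends
#' (fixed-window OLS, laying-date and per-period mixed models, calendar
#' window-slope distribution); fitness response surfaces with peak
#' localization and pre/post-peak trends; phenological match (half-fall
#' dates and trend, half-fall-window temperature trend, mismatch, mismatch
#' curves, cue-window search); and a markdown report. Every stage writes
#' its CSV outputs under `out_dir`, each stamped with the configuration
#' hash; rerunning with an identical configuration reproduces identical
#' files. A stage failure halts the run naming the stage, keeping the
#' outputs already written.
#'
#' @param config A [pipeline_config] (or list/path coercible to one).
#' @param out_dir Output directory (default `config$out_dir`).
#' @return A `pipeline_result` bundle of all fitted objects and paths,
#'   invisibly.
#' @export
run_pipeline <- function(config, out_dir = config$out_dir) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  if (is.null(out_dir)) stop("no output directory configured")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(unclass(config)[setdiff(names(config), "out_dir")])
  say <- function(...) if (isTRUE(config$verbose)) message(...)
  stage <- function(name, expr) {
    say("[", name, "]")
    tryCatch(expr, error = function(e)
      stop("stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
  }
  res <- list(config = config, hash = hash, out_dir = out_dir)

  res$data <- stage("ingest", {
    if (!is.null(config$truth)) {
      truth_args <- config$truth
      truth_args$seed <- derive_seed(config$seed, 10L)
      truth <- do.call(generator_truth, truth_args)
      cohort <- simulate_cohort(truth)
      jsonlite::write_json(unclass(truth), file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      cohort
    } else {
      list(climate = read_daily_temperature(
             config$inputs$temperature,
             config$inputs$temperature_dialect %||% "tidy_csv"),
           attempts = read_breeding_table(config$inputs$breeding),
           caterpillars = if (!is.null(config$inputs$caterpillar))
             read_caterpillar_counts(config$inputs$caterpillar),
           truth = NULL)
    }
  })
  climate <- res$data$climate; attempts <- res$data$attempts

  res$intervals <- stage("intervals", {
    it <- relative_period_temperatures(attempts, climate)
    fx <- fixed_interval_annual_means(climate, config$fixed_window$start,
                                      config$fixed_window$end)
    .write_csv(it, file.path(out_dir, "interval_temps.csv"), hash)
    list(interval_temps = it, fixed_annual = fx)
  })

  res$trends <- stage("trends", {
    fixed <- fit_annual_trend(res$intervals$fixed_annual)
    laying <- fit_attempt_level_trend(attempts, "laying_april_day")
    rel <- lapply(stats::setNames(.PERIODS, .PERIODS), function(p) {
      sub <- res$intervals$interval_temps
      sub <- sub[sub$period == p, , drop = FALSE]
      sub$female_id <- attempts$female_id[match(sub$attempt_id,
                                                attempts$attempt_id)]
      fit_attempt_level_trend(sub, "mean_temp")
    })
    wins <- enumerate_calendar_windows(config$fixed_window$start,
                                       config$fixed_window$end,
                                       config$window_lengths$min,
                                       config$window_lengths$max)
    wdist <- sliding_window_slope_distribution(climate, wins)
    summary_df <- rbind(
      data.frame(trend = "fixed_interval_temperature", model = "ols",
                 slope = fixed$slope, se = fixed$slope_se,
                 ci_lo = fixed$ci[1L], ci_hi = fixed$ci[2L], n = fixed$n),
      data.frame(trend = "laying_date", model = "lmm",
                 slope = laying$fixed_slope, se = laying$fixed_slope_se,
                 ci_lo = laying$ci[1L], ci_hi = laying$ci[2L],
                 n = laying$n_obs),
      do.call(rbind, lapply(.PERIODS, function(p) {
        f <- rel[[p]]
        data.frame(trend = paste0("relative_", p, "_temperature"),
                   model = "lmm", slope = f$fixed_slope,
                   se = f$fixed_slope_se, ci_lo = f$ci[1L],
                   ci_hi = f$ci[2L], n = f$n_obs)
      })))
    .write_csv(summary_df, file.path(out_dir, "trend_summary.csv"), hash)
    .write_csv(wdist$slopes, file.path(out_dir, "window_slopes.csv"), hash)
    list(fixed = fixed, laying = laying, relative = rel, windows = wdist,
         summary = summary_df)
  })

  res$fitness <- stage("fitness", {
    spec <- spline_spec(df = config$spline_df)
    combos <- expand.grid(response = config$fitness_responses,
                          period = config$fitness_periods,
                          stringsAsFactors = FALSE)
    combos <- combos[!(combos$response == "clutch_size" &
                         combos$period != "laying"), , drop = FALSE]
    fits <- vector("list", nrow(combos))
    rows <- vector("list", nrow(combos)); curves <- vector("list", nrow(combos))
    for (i in seq_len(nrow(combos))) {
      rsp <- combos$response[i]; per <- combos$period[i]
      fit <- fit_fitness_response(attempts, res$intervals$interval_temps,
                                  rsp, per, spec)
      peak <- locate_peak_with_interval(fit, n_boot = config$n_boot,
                                        seed = derive_seed(config$seed,
                                                           20L + i))
      pw <- fit_prepost_peak_trends(attempts, res$intervals$interval_temps,
                                    rsp, per, peak)
      fits[[i]] <- list(fit = fit, peak = peak, prepost = pw)
      rows[[i]] <- data.frame(
        response = rsp, period = per, family = fit$family,
        peak_temp = peak$peak_temp, peak_lo = peak$interval[1L],
        peak_hi = peak$interval[2L], at_boundary = peak$at_boundary,
        prepeak = if (is.null(pw$prepeak)) NA else pw$prepeak$slope,
        postpeak = if (is.null(pw$postpeak)) NA else pw$postpeak$slope,
        n = fit$n_obs)
      curves[[i]] <- data.frame(response = rsp, period = per, fit$curve)
    }
    names(fits) <- paste(combos$response, combos$period, sep = ".")
    .write_csv(do.call(rbind, rows),
               file.path(out_dir, "fitness_fits.csv"), hash)
    .write_csv(do.call(rbind, curves),
               file.path(out_dir, "predicted_curves.csv"), hash)
    list(fits = fits, summary = do.call(rbind, rows))
  })

  res$phenology <- stage("phenology_match", {
    if (is.null(res$data$caterpillars)) {
      say("  no caterpillar data; match analyses unavailable")
      NULL
    } else {
      hf <- half_fall_table(res$data$caterpillars)
      hf_trend <- half_fall_trend(hf)
      hf_temp <- temperature_at_half_fall(climate, hf, config$halfwidth)
      hf_temp_trend <- fit_annual_trend(hf_temp)
      mm <- compute_match(attempts, hf)
      curves <- lapply(stats::setNames(config$mismatch_periods,
                                       config$mismatch_periods),
                       function(p)
        mismatch_temperature_curve(attempts, res$intervals$interval_temps,
                                   mm, p, spline_spec(config$spline_df),
                                   n_boot = config$n_boot,
                                   seed = derive_seed(config$seed, 40L)))
      cue <- tryCatch(
        cue_window_search(
          annual_laying_means(attempts), climate,
          enumerate_calendar_windows(config$cue_span$start,
                                     config$cue_span$end,
                                     config$cue_window_lengths$min,
                                     config$cue_window_lengths$max)),
        error = function(e) {
          say("  cue-window search unavailable: ", conditionMessage(e))
          NULL
        })
      .write_csv(cbind(hf["year"], date = format(hf$date),
                       april_day = hf$april_day,
                       total_count = hf$total_count),
                 file.path(out_dir, "half_fall.csv"), hash)
      .write_csv(mm, file.path(out_dir, "mismatch.csv"), hash)
      if (!is.null(cue))
        .write_csv(cue$support,
                   file.path(out_dir, "cue_window_support.csv"), hash)
      list(half_fall = hf, hf_trend = hf_trend, hf_temp = hf_temp,
           hf_temp_trend = hf_temp_trend, mismatch = mm,
           mismatch_curves = curves, cue = cue)
    }
  })

  res$summary <- .run_summary(res)
  jsonlite::write_json(res$summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  stage("report", render_report(res, file.path(out_dir, "report.md")))
  class(res) <- "pipeline_result"
  invisible(res)
}

.write_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash ", hash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

.run_summary <- function(res) {
  tr <- res$trends
  out <- list(
    config_hash = res$hash,
    seed = res$config$seed,
    n_attempts = nrow(res$data$attempts),
    n_years = length(unique(res$data$attempts$year)),
    fixed_interval_slope = tr$fixed$slope,
    fixed_interval_slope_se = tr$fixed$slope_se,
    laying_date_slope = tr$laying$fixed_slope,
    window_slope_mean = tr$windows$mean_slope,
    window_slope_sd = tr$windows$sd_slope,
    relative_slopes = lapply(tr$relative, function(f)
      list(slope = f$fixed_slope, ci = f$ci)))
  if (!is.null(res$phenology)) {
    out$half_fall_slope <- res$phenology$hf_trend$slope
    out$half_fall_temp_slope <- res$phenology$hf_temp_trend$slope
    out$n_half_fall_years <- nrow(res$phenology$half_fall)
    if (!is.null(res$phenology$cue))
      out$cue_window <- res$phenology$cue$best$start_md
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> hash", x$hash, "->", x$out_dir, "\n")
  cat(sprintf("  %d attempts, %d years; fixed slope %.4f; window mean %.4f\n",
              x$summary$n_attempts, x$summary$n_years,
              x$summary$fixed_interval_slope, x$summary$window_slope_mean))
  invisible(x)
}
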