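#' Daily temperature series
#'
#' Container for a calendar-indexed series of daily mean temperatures in
#' degrees Celsius on the 365-day grid (29 February dropped on ingest, so
#' month-day-anchored windows are identical across years). Gaps are allowed
#' and queryable; duplicate days and non-finite temperatures are rejected.
#'
#' @param year,doy,temp Parallel vectors: year, grid day-of-year (1..365)
#'   and mean temperature (deg C).
#' @param provenance Free-text origin note.
#' @return A `daily_temps` data frame with columns `year`, `doy`, `temp`.
#' @export
daily_temps <- function(year, doy, temp, provenance = "unspecified") {
  year <- as.integer(year); doy <- as.integer(doy); temp <- as.numeric(temp)
  stopifnot(length(year) == length(doy), length(doy) == length(temp))
  if (any(doy < 1L | doy > 365L)) stop("day-of-year outside 1..365")
  if (any(!is.finite(temp))) stop("non-finite temperatures in series")
  key <- year * 1000L + doy
  if (anyDuplicated(key)) stop("duplicate calendar days in series")
  o <- order(key)
  out <- data.frame(year = year[o], doy = doy[o], temp = temp[o])
  class(out) <- c("daily_temps", "data.frame")
  attr(out, "provenance") <- provenance
  out
}

#' @export
print.daily_temps <- function(x, ...) {
  yrs <- range(x$year)
  cat(sprintf(
    "<daily_temps> %d days, years %d-%d (%d years), %.1f to %.1f degC\n",
    nrow(x), yrs[1L], yrs[2L], length(unique(x$year)),
    min(x$temp), max(x$temp)))
  cat("provenance:", attr(x, "provenance"), "\n")
  invisible(x)
}

# Dense year x 365 matrix (NA = missing day); the workhorse layout for
# window means.
temp_matrix <- function(series) {
  stopifnot(inherits(series, "daily_temps"))
  years <- sort(unique(series$year))
  m <- matrix(NA_real_, nrow = length(years), ncol = 365L,
              dimnames = list(as.character(years), NULL))
  m[cbind(match(series$year, years), series$doy)] <- series$temp
  m
}

#' Read a daily mean temperature file
#'
#' Two layouts are supported. `"tidy_csv"` is a two-column CSV with
#' ISO-8601 `date` and `tmean_c` in deg C. `"cet_daily"` is the Met Office
#' Hadley Centre daily Central England Temperature layout: whitespace-
#' separated rows of year, day-of-month and twelve month columns holding
#' temperatures in tenths of a degree, with -999 marking missing slots.
#' In both dialects missing values are dropped, 29 February is dropped so
#' every year maps to the 365-day grid, and any value below -90 deg C after
#' scaling is treated as a missing sentinel.
#'
#' @param path File path.
#' @param dialect `"tidy_csv"` or `"cet_daily"`.
#' @return A [daily_temps] series.
#' @export
read_daily_temperature <- function(path, dialect = c("tidy_csv", "cet_daily")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  out <- switch(dialect,
                tidy_csv = .read_tidy_temperature(path),
                cet_daily = .read_cet_daily(path))
  # warn about years that were entirely missing
  tab <- table(out$year)
  if (length(tab) && any(tab == 0L)) {
    warning("years with no usable days dropped: ",
            paste(names(tab)[tab == 0L], collapse = ", "))
  }
  out
}

.read_tidy_temperature <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("date", "tmean_c")
  if (!all(need %in% names(df)))
    stop("tidy temperature CSV must have columns ",
         paste(need, collapse = ", "))
  dates <- as.Date(df$date)
  if (anyNA(dates)) stop("unparseable ISO dates in ", path)
  g <- date_to_grid(dates)
  keep <- !is.na(g$doy) & is.finite(df$tmean_c) & df$tmean_c > -90
  daily_temps(g$year[keep], g$doy[keep], df$tmean_c[keep],
              provenance = paste0("tidy_csv:", basename(path)))
}

.read_cet_daily <- function(path) {
  raw <- utils::read.table(path, header = FALSE, fill = TRUE,
                           stringsAsFactors = FALSE)
  # drop a header line if present (non-numeric first field)
  num1 <- suppressWarnings(as.numeric(raw[[1L]]))
  raw <- raw[!is.na(num1), , drop = FALSE]
  if (ncol(raw) != 14L)
    stop("CET daily layout needs 14 columns (year, day, 12 months), got ",
         ncol(raw))
  raw[] <- lapply(raw, function(col) suppressWarnings(as.numeric(col)))
  year <- as.integer(raw[[1L]]); dom <- as.integer(raw[[2L]])
  if (any(dom < 1L | dom > 31L, na.rm = TRUE))
    stop("CET day-of-month column outside 1..31; wrong layout?")
  rec <- vector("list", 12L)
  for (month in 1:12) {
    vals <- raw[[month + 2L]] / 10          # tenths of degC
    valid <- dom <= .MONTH_LEN[month]       # drops 29-31 Feb incl. leap day
    keep <- valid & !is.na(vals) & vals > -90
    rec[[month]] <- data.frame(year = year[keep],
                               doy = .MONTH_OFFSET[month] + dom[keep],
                               temp = vals[keep])
  }
  rec <- do.call(rbind, rec)
  if (!nrow(rec)) stop("no usable values parsed from CET file ", path)
  daily_temps(rec$year, rec$doy, rec$temp,
              provenance = paste0("cet_daily:", basename(path)))
}

#' Write a daily temperature series as tidy CSV
#'
#' @param series A [daily_temps] series.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_daily_temperature <- function(series, path) {
  stopifnot(inherits(series, "daily_temps"))
  df <- data.frame(date = format(grid_to_date(series$year, series$doy)),
                   tmean_c = series$temp)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
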