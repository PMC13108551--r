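#' @keywords internal
"_PACKAGE"

# Cumulative days before each month on the 365-day (no 29 Feb) grid.
.MONTH_OFFSET <- c(0L, 31L, 59L, 90L, 120L, 151L, 181L, 212L, 243L, 273L,
                   304L, 334L)
.MONTH_LEN <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

#' Convert a month-day anchor to a day-of-year on the 365-day grid
#'
#' All calendar arithmetic in this package runs on a 365-day grid with
#' 29 February removed, so a month-day anchor (e.g. "02-15") denotes the
#' same grid day in every year.
#'
#' @param md Month-day string `"MM-DD"`, or an integer vector `c(month, day)`.
#' @return Integer day-of-year in 1..365.
#' @examples
#' md_to_doy("02-15")  # 46
#' md_to_doy("06-05")  # 156
#' @export
md_to_doy <- function(md) {
  if (is.character(md)) {
    parts <- as.integer(strsplit(md, "-", fixed = TRUE)[[1L]])
    if (length(parts) != 2L || anyNA(parts))
      stop("month-day anchor must look like 'MM-DD', got '", md, "'")
    month <- parts[1L]; day <- parts[2L]
  } else {
    month <- as.integer(md[1L]); day <- as.integer(md[2L])
  }
  if (month < 1L || month > 12L) stop("month out of range: ", month)
  if (month == 2L && day == 29L)
    stop("29 February does not exist on the 365-day grid")
  if (day < 1L || day > .MONTH_LEN[month])
    stop("day out of range for month ", month, ": ", day)
  .MONTH_OFFSET[month] + day
}

#' Convert a grid day-of-year back to a month-day string
#' @param doy Integer day-of-year in 1..365.
#' @return Character `"MM-DD"`.
#' @export
doy_to_md <- function(doy) {
  doy <- as.integer(doy)
  if (any(doy < 1L | doy > 365L)) stop("day-of-year out of 1..365")
  month <- findInterval(doy - 1L, .MONTH_OFFSET)
  day <- doy - .MONTH_OFFSET[month]
  sprintf("%02d-%02d", month, day)
}

# April-day scale: 1 = 1 April (31 March = 0, 1 March = -30).
# 1 April is grid day 91, so april_day = doy - 90.

#' April-day scale conversions
#'
#' Breeding timing is recorded on an April-day scale where 1 = 1 April
#' (so 31 March = 0 and 1 March = -30), the standard convention in
#' long-term tit studies. The grid day-of-year of April-day `d` is
#' `d + 90` on the 365-day grid.
#'
#' @param april_day,doy Integer vectors.
#' @return Integer vector on the other scale.
#' @export
april_day_to_doy <- function(april_day) as.integer(april_day) + 90L

#' @rdname april_day_to_doy
#' @export
doy_to_april_day <- function(doy) as.integer(doy) - 90L

# Date -> (year, grid doy). 29 Feb maps to NA and is dropped by callers.
date_to_grid <- function(dates) {
  dates <- as.Date(dates)
  lt <- as.POSIXlt(dates)
  year <- lt$year + 1900L
  yday <- lt$yday + 1L                       # 1-based
  leap <- (year %% 4L == 0L & year %% 100L != 0L) | year %% 400L == 0L
  doy <- ifelse(leap & yday == 60L, NA_integer_,       # 29 Feb
         ifelse(leap & yday > 60L, yday - 1L, yday))
  data.frame(year = year, doy = as.integer(doy))
}

# (year, grid doy) -> Date, reinserting the leap offset.
grid_to_date <- function(year, doy) {
  leap <- (year %% 4L == 0L & year %% 100L != 0L) | year %% 400L == 0L
  yday <- ifelse(leap & doy >= 60L, doy + 1L, doy)
  as.Date(yday - 1L, origin = as.Date(paste0(year, "-01-01")))
}
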