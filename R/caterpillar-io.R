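#' Construct a table of caterpillar water-trap counts
#'
#' Daily counts of final-instar caterpillars caught in water traps as they
#' descend to pupate, one series per year. Years whose seasonal total is
#' zero cannot yield a half-fall date and are flagged unusable rather than
#' dropped.
#'
#' @param df Data frame with columns `year`, `date` (ISO-8601) and
#'   `count` (non-negative integers).
#' @return A `caterpillar_falls` data frame with added grid columns `doy`
#'   and `april_day`, and attribute `"usable_years"`.
#' @export
caterpillar_falls <- function(df) {
  need <- c("year", "date", "count")
  if (!all(need %in% names(df)))
    stop("caterpillar table must have columns ", paste(need, collapse = ", "))
  df$year <- as.integer(df$year)
  df$date <- as.Date(df$date)
  df$count <- as.integer(round(as.numeric(df$count)))
  if (anyNA(df$year) || anyNA(df$date) || anyNA(df$count))
    stop("unparseable year/date/count in caterpillar table")
  if (any(df$count < 0L)) {
    stop("negative caterpillar count(s) at row(s): ",
         paste(utils::head(which(df$count < 0L), 5L), collapse = ", "))
  }
  g <- date_to_grid(df$date)
  if (anyNA(g$doy)) stop("caterpillar counts dated 29 February unsupported")
  if (any(g$year != df$year))
    stop("caterpillar `date` disagrees with `year` column")
  df$doy <- g$doy
  df$april_day <- doy_to_april_day(g$doy)
  df <- df[order(df$year, df$doy), c("year", "date", "doy", "april_day",
                                     "count")]
  rownames(df) <- NULL
  totals <- tapply(df$count, df$year, sum)
  class(df) <- c("caterpillar_falls", "data.frame")
  attr(df, "usable_years") <- as.integer(names(totals))[totals > 0L]
  df
}

#' @export
print.caterpillar_falls <- function(x, ...) {
  cat(sprintf(
    "<caterpillar_falls> %d daily counts, %d years (%d usable)\n",
    nrow(x), length(unique(x$year)), length(usable_years(x))))
  invisible(x)
}

#' Years of a caterpillar series with a positive seasonal total
#' @param falls A `caterpillar_falls` table.
#' @return Integer vector of usable years.
#' @export
usable_years <- function(falls) {
  stopifnot(inherits(falls, "caterpillar_falls"))
  attr(falls, "usable_years")
}

#' Read a caterpillar trap-count CSV (`year,date,count`)
#' @param path File path.
#' @return A `caterpillar_falls` table.
#' @export
read_caterpillar_counts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  caterpillar_falls(df)
}

#' Write a caterpillar trap-count table as CSV
#' @param falls A `caterpillar_falls` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_caterpillar_counts <- function(falls, path) {
  stopifnot(inherits(falls, "caterpillar_falls"))
  utils::write.csv(data.frame(year = falls$year, date = format(falls$date),
                              count = falls$count),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
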