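.BREEDING_COLS <- c("attempt_id", "year", "female_id", "laying_april_day",
                    "clutch_size", "incubation_start_april_day",
                    "hatch_april_day", "n_fledged", "n_recruits",
                    "n_neighbors")

#' Construct and validate a table of breeding attempts
#'
#' One row per nest. Timing fields are on the April-day scale (1 = 1 April);
#' `incubation_start_april_day` and `hatch_april_day` may be `NA` (partially
#' observed attempts are flagged downstream, never imputed). The biological
#' invariants are enforced: `clutch_size >= 1`,
#' `0 <= n_fledged <= clutch_size`, `n_recruits <= n_fledged`, and
#' `laying <= incubation_start <= hatch` where present.
#'
#' @param df Data frame with the columns named in the breeding CSV schema
#'   (see [read_breeding_table]).
#' @param strict If `TRUE` (default) any invalid row is an error naming the
#'   offending rows; if `FALSE` invalid rows are dropped with a warning and
#'   the row-level diagnostics are attached as attribute `"rejected"`.
#' @return A `breeding_attempts` data frame.
#' @export
breeding_attempts <- function(df, strict = TRUE) {
  missing_cols <- setdiff(.BREEDING_COLS, names(df))
  if (length(missing_cols))
    stop("breeding table missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- df[.BREEDING_COLS]
  int_cols <- setdiff(.BREEDING_COLS, c("attempt_id", "female_id"))
  df[int_cols] <- lapply(df[int_cols], function(x) as.integer(round(as.numeric(x))))
  df$attempt_id <- as.character(df$attempt_id)
  df$female_id <- as.character(df$female_id)

  problems <- character(nrow(df))
  bad <- function(cond, msg) {
    cond[is.na(cond)] <- FALSE
    problems[cond] <<- ifelse(nzchar(problems[cond]),
                              paste0(problems[cond], "; ", msg), msg)
  }
  bad(is.na(df$year) | is.na(df$laying_april_day) | is.na(df$clutch_size) |
        is.na(df$n_fledged) | is.na(df$n_recruits) | is.na(df$n_neighbors),
      "missing mandatory field")
  bad(df$clutch_size < 1L, "clutch_size < 1")
  bad(df$n_fledged < 0L | df$n_recruits < 0L | df$n_neighbors < 0L,
      "negative count")
  bad(df$n_fledged > df$clutch_size, "n_fledged > clutch_size")
  bad(df$n_recruits > df$n_fledged, "n_recruits > n_fledged")
  bad(!is.na(df$incubation_start_april_day) &
        df$laying_april_day > df$incubation_start_april_day,
      "laying after incubation start")
  bad(!is.na(df$incubation_start_april_day) & !is.na(df$hatch_april_day) &
        df$incubation_start_april_day > df$hatch_april_day,
      "incubation start after hatch")

  invalid <- nzchar(problems)
  if (any(invalid)) {
    diag <- data.frame(row = which(invalid),
                       attempt_id = df$attempt_id[invalid],
                       problem = problems[invalid])
    if (strict) {
      stop("invalid breeding rows:\n",
           paste(sprintf("  row %d (%s): %s", diag$row, diag$attempt_id,
                         diag$problem), collapse = "\n"))
    }
    warning(sum(invalid), " invalid breeding row(s) dropped")
    df <- df[!invalid, , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "rejected") <- diag
  }
  if (anyDuplicated(df$attempt_id)) stop("duplicate attempt_id values")
  class(df) <- c("breeding_attempts", "data.frame")
  df
}

#' @export
print.breeding_attempts <- function(x, ...) {
  cat(sprintf(
    "<breeding_attempts> %d attempts, %d years (%d-%d), %d females\n",
    nrow(x), length(unique(x$year)), min(x$year), max(x$year),
    length(unique(x$female_id))))
  invisible(x)
}

#' Read a breeding-attempt CSV
#'
#' Expected columns:
#' `attempt_id,year,female_id,laying_april_day,clutch_size,`
#' `incubation_start_april_day,hatch_april_day,n_fledged,n_recruits,`
#' `n_neighbors`, empty cells meaning "not observed".
#'
#' @inheritParams breeding_attempts
#' @param path File path.
#' @return A `breeding_attempts` data frame.
#' @export
read_breeding_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        na.strings = c("", "NA"))
  breeding_attempts(df, strict = strict)
}

#' Write a breeding-attempt table as CSV
#' @param attempts A `breeding_attempts` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_breeding_table <- function(attempts, path) {
  stopifnot(inherits(attempts, "breeding_attempts"))
  utils::write.csv(as.data.frame(attempts), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}
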