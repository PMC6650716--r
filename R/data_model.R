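#' Define a study period
#'
#' A study period is a closed interval of integer day indices. All downstream
#' code works in 0-based day indices within the study interval rather than
#' calendar dates, which keeps the association machinery free of calendar
#' arithmetic.
#'
#' @param label Character label for the period (e.g. `"A"`).
#' @param start_day,end_day Integer day indices (inclusive).
#' @return An object of class `study_period` with fields `label`,
#'   `start_day`, `end_day` and `n_days`.
#' @export
study_period <- function(label, start_day, end_day) {
  start_day <- as.integer(start_day)
  end_day <- as.integer(end_day)
  if (end_day < start_day) stop("end_day must be >= start_day")
  structure(
    list(label = as.character(label), start_day = start_day,
         end_day = end_day, n_days = end_day - start_day + 1L),
    class = "study_period"
  )
}

#' @export
print.study_period <- function(x, ...) {
  cat(sprintf("study period '%s': days %d-%d (%d days)\n",
              x$label, x$start_day, x$end_day, x$n_days))
  invisible(x)
}

#' Build a study period from calendar dates
#'
#' Converts a calendar interval to day indices relative to an origin date
#' (day 0). Used to reproduce designs such as splitting a multi-year record
#' into consecutive 2-year datasets.
#'
#' @param label Period label.
#' @param start,end Dates (or strings parseable by [as.Date()]), inclusive.
#' @param origin Date corresponding to day index 0; defaults to `start`.
#' @return A `study_period`.
#' @export
study_period_from_dates <- function(label, start, end, origin = start) {
  start <- as.Date(start); end <- as.Date(end); origin <- as.Date(origin)
  study_period(label,
               as.integer(start - origin),
               as.integer(end - origin))
}

#' Read visit records from CSV
#'
#' Expects columns `unit_id` and `date`. Dates may be ISO-8601 calendar dates
#' or non-negative integer day indices; calendar dates are converted once to
#' 0-based day indices relative to `origin` (default: the earliest date in
#' the file). Duplicate (unit, day) rows collapse to a single record with a
#' message giving the count, since associations are defined at day
#' resolution.
#'
#' @param path Path to a CSV file.
#' @param origin Optional origin date for calendar input.
#' @return A data frame of visit records with columns `unit_id` (character)
#'   and `day` (integer, 0-based), sorted by (day, unit_id). The origin date,
#'   when calendar input was parsed, is attached as attribute `"origin"`.
#' @export
read_visits <- function(path, origin = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  for (col in c("unit_id", "date")) {
    if (!col %in% names(df))
      stop(sprintf("visits file is missing required column '%s'", col))
  }
  if (nrow(df) == 0L) {
    out <- data.frame(unit_id = character(0), day = integer(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  raw <- trimws(df$date)
  if (all(grepl("^[0-9]+$", raw))) {
    day <- as.integer(raw)
  } else {
    parsed <- as.Date(raw, format = "%Y-%m-%d")
    bad <- which(is.na(parsed))
    if (length(bad) > 0L)
      stop(sprintf("unparseable date(s) in visits file at data row(s): %s",
                   paste(utils::head(bad, 10L), collapse = ", ")))
    if (is.null(origin)) origin <- min(parsed)
    origin <- as.Date(origin)
    day <- as.integer(parsed - origin)
  }
  out <- data.frame(unit_id = df$unit_id, day = day, stringsAsFactors = FALSE)
  n_raw <- nrow(out)
  out <- unique(out)
  n_dup <- n_raw - nrow(out)
  if (n_dup > 0L)
    message(sprintf("collapsed %d duplicate unit-day visit row(s)", n_dup))
  out <- out[order(out$day, out$unit_id), , drop = FALSE]
  rownames(out) <- NULL
  if (exists("origin", inherits = FALSE) && !is.null(origin) &&
      inherits(origin, "Date"))
    attr(out, "origin") <- origin
  out
}

#' Write visit records to CSV
#'
#' Inverse of [read_visits()] for day-index data: writes columns
#' `unit_id,date` with `date` holding the integer day index.
#'
#' @param visits Visit record data frame (`unit_id`, `day`).
#' @param path Output path.
#' @export
write_visits <- function(visits, path) {
  write.csv(data.frame(unit_id = visits$unit_id, date = visits$day),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read unit metadata from CSV
#'
#' Expects columns `unit_id`, `kind` (`group` or `solitary`),
#' `n_individuals`, and optionally `silverback_id`. Solitary units must have
#' `n_individuals == 1`.
#'
#' @param path Path to a CSV file.
#' @return Data frame of unit metadata.
#' @export
read_units <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("unit_id", "kind", "n_individuals")) {
    if (!col %in% names(df))
      stop(sprintf("units file is missing required column '%s'", col))
  }
  if (!all(df$kind %in% c("group", "solitary")))
    stop("unit kind must be 'group' or 'solitary'")
  df$n_individuals <- as.integer(df$n_individuals)
  if (any(df$n_individuals < 1L)) stop("n_individuals must be >= 1")
  if (any(df$kind == "solitary" & df$n_individuals != 1L))
    stop("solitary units must have n_individuals == 1")
  if (!"silverback_id" %in% names(df)) df$silverback_id <- NA_character_
  df
}

#' Read pairwise binary kinship data from CSV
#'
#' Expects columns `silverback_a`, `silverback_b`, `related` with
#' `related` in {0, 1} (1 meaning estimated relatedness at or above the
#' half-sibling threshold).
#'
#' @param path Path to a CSV file.
#' @return Data frame of silverback pairs with binary relatedness.
#' @export
read_kinship <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("silverback_a", "silverback_b", "related")) {
    if (!col %in% names(df))
      stop(sprintf("kinship file is missing required column '%s'", col))
  }
  if (!all(df$related %in% c(0L, 1L)))
    stop("kinship 'related' must be binary 0/1")
  df
}

#' Build a unit-by-day presence matrix
#'
#' The presence matrix is the raw material of every association index: a
#' binary matrix with one row per social unit and one column per observation
#' day of the period. Days with no attendance are retained as all-zero
#' columns, because the total number of observation days enters the
#' binomial-probability index.
#'
#' @param visits Visit record data frame (`unit_id`, `day`).
#' @param period A `study_period`; defaults to the span of the data.
#' @return Binary integer matrix with unit ids as row names and day indices
#'   (as characters) as column names.
#' @export
build_presence <- function(visits, period = NULL) {
  if (is.null(period)) {
    if (nrow(visits) == 0L) stop("cannot infer a period from zero records")
    period <- study_period("all", min(visits$day), max(visits$day))
  }
  outside <- visits$day < period$start_day | visits$day > period$end_day
  if (any(outside))
    stop(sprintf("%d visit record(s) fall outside period '%s'",
                 sum(outside), period$label))
  units <- sort(unique(visits$unit_id))
  days <- period$start_day:period$end_day
  pm <- matrix(0L, nrow = length(units), ncol = length(days),
               dimnames = list(units, as.character(days)))
  if (nrow(visits) > 0L) {
    pm[cbind(match(visits$unit_id, units),
             match(visits$day, days))] <- 1L
  }
  attr(pm, "period") <- period
  pm
}

#' Drop rarely observed units from a presence matrix
#'
#' Units seen fewer than `min_visits` times within the period are removed;
#' day columns are untouched so the observation-day count is preserved. The
#' operation is idempotent.
#'
#' @param pm Presence matrix from [build_presence()].
#' @param min_visits Minimum visit count to retain a unit (default 8,
#'   matching the convention of dropping units seen fewer than eight times
#'   in a 2-year window).
#' @return Filtered presence matrix.
#' @export
filter_min_visits <- function(pm, min_visits = 8L) {
  stopifnot(min_visits >= 0L)
  keep <- rowSums(pm) >= min_visits
  if (!any(keep))
    stop(sprintf(
      "all units have fewer than %d visits; lower min_visits", min_visits))
  out <- pm[keep, , drop = FALSE]
  attr(out, "period") <- attr(pm, "period")
  out
}

#' Split visit records into study periods
#'
#' Each record is assigned to the period whose closed day interval contains
#' it; the periods must be non-overlapping and ordered. Records outside all
#' periods are dropped with a message.
#'
#' @param visits Visit record data frame.
#' @param periods List of `study_period` objects.
#' @return Named list (by period label) of lists with elements `period` and
#'   `presence`.
#' @export
split_periods <- function(visits, periods) {
  starts <- vapply(periods, function(p) p$start_day, integer(1))
  ends <- vapply(periods, function(p) p$end_day, integer(1))
  ord <- order(starts)
  s <- starts[ord]; e <- ends[ord]
  if (length(s) > 1L && any(s[-1] <= e[-length(e)]))
    stop("study periods overlap")
  out <- list()
  assigned <- rep(FALSE, nrow(visits))
  for (p in periods) {
    in_p <- visits$day >= p$start_day & visits$day <= p$end_day
    assigned <- assigned | in_p
    out[[p$label]] <- list(
      period = p,
      presence = build_presence(visits[in_p, , drop = FALSE], p)
    )
  }
  if (any(!assigned))
    message(sprintf("%d record(s) fall outside all periods and were dropped",
                    sum(!assigned)))
  out
}

#' Export a presence matrix to CSV
#'
#' @param pm Presence matrix.
#' @param path Output path.
#' @export
write_presence <- function(pm, path) {
  write.csv(as.data.frame(pm), path, row.names = TRUE)
  invisible(path)
}
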