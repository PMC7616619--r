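# Index months and calendar-month window arithmetic.
#
# Every monthly measure is anchored on an index month: the search date is
# the last day of that month and the test lookback covers the named month
# plus the two preceding calendar months (a closed interval). Month
# subtraction clamps to the end of shorter months (31 May - 3 months ->
# 28/29 Feb), so windows are reproducible calendar windows, not 91-day
# approximations.

#' Create an index month
#'
#' An index month fixes the search date for one monthly measure: the
#' `index_date` is the last day of the named month, and `lookback_start`
#' the first day of the month two months earlier, so that
#' `[lookback_start, index_date]` spans exactly three calendar months.
#'
#' @param year,month calendar year and month (integers).
#' @return An object of class `index_month` with fields `year`, `month`,
#'   `index_date`, `lookback_start` and a `label` of the form `"2020-05"`.
#' @examples
#' index_month(2020, 5) # lookback 2020-03-01 .. 2020-05-31
#' @export
index_month <- function(year, month) {
  if (!is.numeric(year) || !is.numeric(month) || length(year) != 1L ||
      length(month) != 1L || is.na(year) || is.na(month) ||
      month < 1 || month > 12) {
    abort("index_month() needs a single valid year and month",
          class = "dmardmon_config_error")
  }
  first <- make_date(year, month, 1L)
  structure(
    list(
      year = as.integer(year), month = as.integer(month),
      index_date = (first %m+% months(1)) - 1L,
      lookback_start = first %m-% months(2),
      label = format(first, "%Y-%m")
    ),
    class = "index_month"
  )
}

#' Coerce to an index month
#'
#' Accepts an `index_month`, a `"YYYY-MM"` string, or a `Date` (whose
#' month is used).
#'
#' @param x object to coerce.
#' @return an `index_month`.
#' @export
as_index_month <- function(x) {
  if (inherits(x, "index_month")) return(x)
  if (inherits(x, "Date")) {
    return(index_month(as.integer(format(x, "%Y")), as.integer(format(x, "%m"))))
  }
  if (is.character(x) && length(x) == 1L && grepl("^\\d{4}-\\d{2}$", x)) {
    parts <- as.integer(strsplit(x, "-", fixed = TRUE)[[1]])
    return(index_month(parts[1], parts[2]))
  }
  abort(paste0("cannot interpret ", deparse(x), " as an index month"),
        class = "dmardmon_config_error")
}

#' @export
print.index_month <- function(x, ...) {
  cat("<index_month>", x$label,
      " lookback:", format(x$lookback_start), "..", format(x$index_date), "\n")
  invisible(x)
}

#' @export
format.index_month <- function(x, ...) x$label

#' Sequence of index months
#'
#' @param start,end anything accepted by [as_index_month()]; inclusive.
#' @return a list of `index_month` objects, one per calendar month.
#' @export
seq_index_months <- function(start, end) {
  start <- as_index_month(start)
  end <- as_index_month(end)
  s <- make_date(start$year, start$month, 1L)
  e <- make_date(end$year, end$month, 1L)
  if (s > e) abort("start month is after end month", class = "dmardmon_argument_error")
  firsts <- seq(s, e, by = "month")
  lapply(firsts, function(d) {
    index_month(as.integer(format(d, "%Y")), as.integer(format(d, "%m")))
  })
}

# round half away from zero at `digits` decimals; used for all reported
# percentages so 31.05 prints as 31.1 (base round() would give 31.0).
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
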