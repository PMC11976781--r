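#' Calendar-month utilities
#'
#' Months are represented throughout as ISO `"YYYY-MM"` strings, which sort
#' chronologically as plain strings and make pre/post splits unambiguous.
#'
#' @param x character vector of `"YYYY-MM"` strings.
#' @return `parse_month()` returns the input, validated and normalized;
#'   `month_index()` returns a 0-based integer month offset from `origin`;
#'   `month_seq()` returns a character vector of consecutive months.
#' @examples
#' month_seq("2017-01", 3)
#' month_index("2020-04", origin = "2017-01")
#' @export
parse_month <- function(x) {
  x <- as.character(x)
  ok <- grepl("^[0-9]{4}-(0[1-9]|1[0-2])$", x)
  if (!all(ok)) {
    stop("unparseable month value(s): ",
         paste(unique(x[!ok]), collapse = ", "), call. = FALSE)
  }
  x
}

#' @rdname parse_month
#' @param origin month the index is counted from (index 0).
#' @export
month_index <- function(x, origin) {
  x <- parse_month(x)
  origin <- parse_month(origin)
  yr <- as.integer(substr(x, 1, 4))
  mo <- as.integer(substr(x, 6, 7))
  yr0 <- as.integer(substr(origin, 1, 4))
  mo0 <- as.integer(substr(origin, 6, 7))
  (yr - yr0) * 12L + (mo - mo0)
}

#' @rdname parse_month
#' @param start first month of the sequence.
#' @param n number of consecutive months.
#' @export
month_seq <- function(start, n) {
  start <- parse_month(start)
  yr <- as.integer(substr(start, 1, 4))
  mo <- as.integer(substr(start, 6, 7))
  tot <- (yr * 12L + mo - 1L) + seq_len(n) - 1L
  sprintf("%04d-%02d", tot %/% 12L, tot %% 12L + 1L)
}

#' Average calendar-month length in days
#'
#' The divisor used to turn monthly bed-day totals into occupancy rates:
#' 365.25 / 12 = 30.4375 days per month.
#'
#' @return a single number, 30.4375.
#' @examples
#' month_length_days()
#' @export
month_length_days <- function() 365.25 / 12
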