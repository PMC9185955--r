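#' Calendar-month utilities
#'
#' Months are the atomic time unit of the ledger. A month token is an ISO
#' `"YYYY-MM"` string; internally each token maps to a serial index
#' (`year * 12 + month - 1`) so that interval arithmetic is plain integer
#' arithmetic. Dates inside a month are only used by the hospitalisation
#' episode bookkeeping.
#'
#' @param x character vector of `"YYYY-MM"` tokens.
#' @return `month_index()` returns an integer vector; `month_token()` the
#'   inverse mapping; `month_add()` and `month_diff()` operate on tokens;
#'   `month_seq()` returns the inclusive token sequence; `days_in_month()`
#'   the calendar day count of each month.
#' @examples
#' month_add("2018-06", 3)   # "2018-09"
#' month_diff("2018-10", "2018-06")  # 4
#' days_in_month("2020-02")  # 29
#' @name months
NULL

#' @rdname months
#' @export
month_index <- function(x) {
  ok <- grepl("^\\d{4}-(0[1-9]|1[0-2])$", x)
  if (any(!ok)) {
    stop("malformed month token(s): ", paste(unique(x[!ok]), collapse = ", "),
         " (expected \"YYYY-MM\")", call. = FALSE)
  }
  yr <- as.integer(substr(x, 1L, 4L))
  mo <- as.integer(substr(x, 6L, 7L))
  yr * 12L + mo - 1L
}

#' @rdname months
#' @param i integer serial month index.
#' @export
month_token <- function(i) {
  sprintf("%04d-%02d", i %/% 12L, i %% 12L + 1L)
}

#' @rdname months
#' @param m,a,b month tokens.
#' @param k integer number of months to add (may be negative).
#' @export
month_add <- function(m, k) month_token(month_index(m) + as.integer(k))

#' @rdname months
#' @export
month_diff <- function(a, b) month_index(a) - month_index(b)

#' @rdname months
#' @export
month_seq <- function(a, b) {
  ia <- month_index(a); ib <- month_index(b)
  if (ib < ia) stop("month_seq: end month precedes start month", call. = FALSE)
  month_token(seq.int(ia, ib))
}

#' @rdname months
#' @export
days_in_month <- function(m) {
  i <- month_index(m)
  first <- as.Date(paste0(month_token(i), "-01"))
  nxt <- as.Date(paste0(month_token(i + 1L), "-01"))
  as.integer(nxt - first)
}
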