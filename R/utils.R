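# Calendar-month arithmetic. A "ym" is the integer year*12 + (month-1), so
# consecutive calendar months differ by exactly 1 regardless of year breaks.

#' Parse a "YYYY-MM" string into a month index
#'
#' @param x character vector like "2015-01".
#' @return integer month index (year * 12 + month - 1).
#' @keywords internal
parse_ym <- function(x) {
  ok <- grepl("^\\d{4}-\\d{2}$", x)
  if (!all(ok)) stop("period must be 'YYYY-MM', got: ", paste(x[!ok], collapse = ", "))
  y <- as.integer(substr(x, 1, 4))
  m <- as.integer(substr(x, 6, 7))
  if (any(m < 1 | m > 12)) stop("month out of range in: ", paste(x[m < 1 | m > 12], collapse = ", "))
  y * 12L + m - 1L
}

#' Format a month index back to "YYYY-MM"
#' @param ym integer month index.
#' @keywords internal
format_ym <- function(ym) {
  sprintf("%04d-%02d", ym %/% 12L, ym %% 12L + 1L)
}

#' Calendar month (1-12) of a month index
#' @keywords internal
month_of <- function(ym) ym %% 12L + 1L

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(name, " must be a single finite number")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
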