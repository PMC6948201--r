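`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Shift a calendar date by whole months
#'
#' Deterministic calendar-month arithmetic: the day of month is preserved,
#' clamped to the last day of the target month when it would overflow
#' (e.g. 31 March minus one month gives 28/29 February).
#'
#' @param date a `Date` vector.
#' @param months integer number of months to add (negative to subtract).
#' @return a `Date` vector of the same length.
#' @export
#' @examples
#' add_months(as.Date("2013-01-01"), -12)
add_months <- function(date, months) {
  date <- as.Date(date)
  lt <- as.POSIXlt(date)
  total <- lt$year * 12L + lt$mon + as.integer(months)
  y <- total %/% 12L + 1900L
  m <- total %% 12L + 1L
  nxt_first <- as.Date(ifelse(m == 12L,
                              sprintf("%04d-01-01", y + 1L),
                              sprintf("%04d-%02d-01", y, m + 1L)))
  days_in_month <- as.integer(format(nxt_first - 1L, "%d"))
  as.Date(sprintf("%04d-%02d-%02d", y, m, pmin(lt$mday, days_in_month)))
}

# Row-wise softmax with overflow guard; eta is n x K on the log-odds scale.
softmax_rows <- function(eta) {
  rmax <- eta[, 1L]
  for (j in seq_len(ncol(eta))[-1L]) rmax <- pmax(rmax, eta[, j])
  p <- exp(eta - rmax)
  p / rowSums(p)
}

# Draw one category index per row from row-wise probabilities.
sample_categories <- function(p, u) {
  K <- ncol(p)
  cum <- p %*% outer(seq_len(K), seq_len(K), `<=`)
  # numerical safety: the last cumulative must dominate u
  cum[, K] <- 1
  as.integer(rowSums(u > cum) + 1L)
}
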