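# Shared helpers: reporting rounding, NYHA labels, date arithmetic.

DAYS_PER_YEAR <- 365.25

NYHA_LEVELS <- c("I", "II", "III", "IV")

#' Round half away from zero
#'
#' Reporting convention used throughout: 0.5 always rounds up (so 17.945
#' prints as 17.95), unlike [base::round()]'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @examples
#' round_half_up(c(0.5, 1.25, 17.945), c(0, 1, 2))
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# percentage of n over d at dp decimal places (half-up); NA where d == 0
pct_of <- function(n, d, dp = 1) {
  out <- round_half_up(100 * n / d, dp)
  out[rep_len(d <= 0, length(out))] <- NA_real_
  out
}

#' NYHA class labels
#'
#' Convert integer classes 1-4 to Roman-numeral labels I-IV (as an ordered
#' factor) and back.
#'
#' @param x Integer vector in 1..4 (`nyha_label`) or character/factor of
#'   labels (`nyha_class_int`).
#' @return Ordered factor of labels, or integer vector.
#' @export
nyha_label <- function(x) {
  factor(NYHA_LEVELS[as.integer(x)], levels = NYHA_LEVELS, ordered = TRUE)
}

#' @rdname nyha_label
#' @export
nyha_class_int <- function(x) {
  match(as.character(x), NYHA_LEVELS)
}

# interval length in years from a day count
days_to_years <- function(days) as.numeric(days) / DAYS_PER_YEAR

# stopifnot with a friendlier message
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# merge sorted half-open intervals [start, end), joining when the gap between
# a span and its successor is <= join_gap. Returns a list(start=, end=).
merge_intervals <- function(start, end, join_gap = 0) {
  if (length(start) == 0L) {
    return(list(start = start, end = end))
  }
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  out_s <- start[1L]
  out_e <- end[1L]
  k <- 1L
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= out_e[k] + join_gap) {
      out_e[k] <- max(out_e[k], end[i])
    } else {
      k <- k + 1L
      out_s[k] <- start[i]
      out_e[k] <- end[i]
    }
  }
  list(start = out_s, end = out_e)
}

# number of intervals [s_i, e_i) covering each query point q (half-open)
count_covering <- function(q, s, e) {
  if (length(s) == 0L) {
    return(integer(length(q)))
  }
  findInterval(q, sort(s)) - findInterval(q, sort(e))
}
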