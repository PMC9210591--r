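# Study calendar: integer day offsets on a global axis, day 0 = first day of
# month 1.  Months are equal-width bins of mean Gregorian length (365.25/12 =
# 30.4375 days) so that 12 months span exactly 365.25 days; real calendar
# month lengths are never needed because the models treat month as an
# integer index.

DAYS_PER_MONTH <- 30.4375

#' Month bin boundaries on the global day axis
#'
#' Month `m` (1-based) covers days `[boundaries[m], boundaries[m + 1])`.
#'
#' @param n_months Number of calendar months in the study window.
#' @return Integer vector of length `n_months + 1`.
#' @export
month_boundaries <- function(n_months) {
  as.integer(round(DAYS_PER_MONTH * (0:n_months)))
}

#' Map global day offsets to month indices
#'
#' @param day Integer vector of day offsets (day 0 = start of month 1).
#' @param n_months Number of months; days at or past the end of month
#'   `n_months` return `NA`.
#' @return Integer vector of month indices in `1:n_months` (or `NA`).
#' @export
day_to_month <- function(day, n_months) {
  b <- month_boundaries(n_months)
  m <- findInterval(day, b)
  m[m < 1L | m > n_months] <- NA_integer_
  as.integer(m)
}

MED_CLASSES <- c("statin", "beta_blocker", "angiotensin_system_inhibitor",
                 "secondary_antiplatelet")

# sample() treats a length-1 numeric x as 1:x; draw by index instead
sample_from <- function(values, n, probs = NULL) {
  values[sample.int(length(values), n, replace = TRUE, prob = probs)]
}
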