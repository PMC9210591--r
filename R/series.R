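# Aggregation of patient-level adherence results to group x calendar-month
# proportion series, the unit of analysis for segmented regression.

#' Aggregate patient-level flags to group-month proportions
#'
#' Patients are binned by their month of discharge (not of index fill) and
#' counted within hospital group.  The outcome is any logical column of the
#' wide results table, e.g. `adherent` (the primary outcome),
#' `prolonged_average`, or a per-class flag such as `adherent_statin`.
#' For per-class flags, only patients with that class at index (non-`NA`
#' flag) enter the denominator.  Group-months with no retained patients are
#' kept as rows with denominator 0 and `NA` proportion — missing, not zero.
#'
#' @param scores An `adherence_scores` object from [score_cohort()] (or its
#'   `results` data frame).
#' @param patients The patient table (provides `group` and `discharge_day`).
#' @param outcome Name of the logical outcome column (default `"adherent"`).
#' @param n_months Number of calendar months on the study axis.
#' @param t0 Last pre-intervention month (used to annotate the series with
#'   the post indicator and time-after covariate).
#' @return Data frame of class `monthly_series` with columns `group`, `t`,
#'   `numerator`, `denominator`, `proportion_pct`, `post_indicator`,
#'   `time_after`.
#' @export
aggregate_monthly <- function(scores, patients, outcome = "adherent",
                              n_months, t0) {
  results <- if (inherits(scores, "adherence_scores")) scores$results else
    scores
  if (!outcome %in% names(results) || !is.logical(results[[outcome]]))
    stop("unknown or non-logical outcome flag: ", outcome, call. = FALSE)
  stopifnot(t0 < n_months)

  df <- merge(results[, c("patient_id", outcome)],
              patients[, c("patient_id", "group", "discharge_day")],
              by = "patient_id")
  df$t <- day_to_month(df$discharge_day, n_months)
  if (anyNA(df$t))
    stop("discharge days outside the ", n_months, "-month study axis",
         call. = FALSE)
  df <- df[!is.na(df[[outcome]]), , drop = FALSE]  # per-class: class at index

  grid <- expand.grid(t = seq_len(n_months),
                      group = unique(patients$group),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  num <- stats::aggregate(df[[outcome]],
                          by = list(group = df$group, t = df$t), FUN = sum)
  den <- stats::aggregate(df[[outcome]],
                          by = list(group = df$group, t = df$t), FUN = length)
  out <- merge(grid, stats::setNames(num, c("group", "t", "numerator")),
               all.x = TRUE)
  out <- merge(out, stats::setNames(den, c("group", "t", "denominator")),
               all.x = TRUE)
  out$numerator[is.na(out$numerator)] <- 0L
  out$denominator[is.na(out$denominator)] <- 0L
  out$proportion_pct <- ifelse(out$denominator > 0,
                               100 * out$numerator / out$denominator, NA_real_)
  out$post_indicator <- as.integer(out$t > t0)
  out$time_after <- pmax(out$t - t0, 0L) * out$post_indicator
  out <- out[order(out$group, out$t),
             c("group", "t", "numerator", "denominator", "proportion_pct",
               "post_indicator", "time_after")]
  rownames(out) <- NULL
  attr(out, "outcome") <- outcome
  attr(out, "t0") <- t0
  class(out) <- c("monthly_series", "data.frame")
  out
}

#' Check a monthly series for stability before modeling
#'
#' A group's series is flagged when any month is missing (zero retained
#' patients) or any monthly denominator falls below a floor; unstable series
#' produce erratic proportions that preclude a meaningful segmented fit and
#' should be excluded from modeling unless forced.
#'
#' @param series A `monthly_series` from [aggregate_monthly()].
#' @param min_denominator Smallest acceptable monthly denominator
#'   (default 10).
#' @return Data frame with one row per group: `group`, `n_months`,
#'   `n_missing`, `min_denominator`, `stable` (logical).
#' @export
stability_check <- function(series, min_denominator = 10L) {
  by_grp <- split(series, series$group)
  out <- do.call(rbind, lapply(by_grp, function(s) {
    data.frame(group = s$group[1],
               n_months = nrow(s),
               n_missing = sum(s$denominator == 0L),
               min_denominator = min(s$denominator),
               stringsAsFactors = FALSE)
  }))
  out$stable <- out$n_missing == 0L & out$min_denominator >= min_denominator
  rownames(out) <- NULL
  out
}
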