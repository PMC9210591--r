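# Patient-level adherence scoring from raw dispensation claims.
#
# All day arithmetic uses half-open intervals at day granularity: a fill on
# day d with s days supplied covers [d, d + s).  Day 0 of a patient's
# follow-up is the discharge day.

#' Scoring thresholds
#'
#' The measurement conventions for claims-based adherence scoring:
#' index fills within 7 days of discharge, adherence at average PDC >= 0.80,
#' persistence broken by an uncovered run of >= 30 days, prolonged
#' dispensation at >= 90 days supplied, follow-up capped at 365 days.  All
#' thresholds are inclusive.
#'
#' @param index_window_days Maximum delay (days) from discharge to index fill.
#' @param pdc_threshold Average-PDC adherence threshold (fraction).
#' @param gap_days Uncovered-run length (days) that breaks persistence.
#' @param prolonged_days Days supplied at index that counts as prolonged.
#' @param followup_days Follow-up window length (days).
#' @return A named list of class `adherence_thresholds`.
#' @export
adherence_thresholds <- function(index_window_days = 7L,
                                 pdc_threshold = 0.80,
                                 gap_days = 30L,
                                 prolonged_days = 90L,
                                 followup_days = 365L) {
  th <- list(index_window_days = as.integer(index_window_days),
             pdc_threshold = pdc_threshold,
             gap_days = as.integer(gap_days),
             prolonged_days = as.integer(prolonged_days),
             followup_days = as.integer(followup_days))
  if (any(unlist(th) <= 0)) stop("all thresholds must be positive",
                                 call. = FALSE)
  class(th) <- "adherence_thresholds"
  th
}

#' Identify a patient's index fill
#'
#' The index fill is the patient's earliest dispensation on or after the
#' discharge day and within the index window (7 days by default).  Its class
#' set is every medication class dispensed on exactly that day; same-class
#' same-day fills are merged by summing days supplied.  Classes first
#' dispensed on a later day do not join the set.
#'
#' @param patient One-row data frame (or list) with `patient_id` and
#'   `discharge_day`.
#' @param fills Data frame of that patient's dispensations
#'   (`med_class`, `fill_day`, `days_supplied`).
#' @param thresholds An [adherence_thresholds()].
#' @return `NULL` if the patient has no fill inside the window (excluded),
#'   else a list with `patient_id`, `index_day` (offset from discharge,
#'   0..7), and named integer vector `days_supplied` keyed by class.
#' @export
find_index_fill <- function(patient, fills,
                            thresholds = adherence_thresholds()) {
  if (nrow(fills) && any(fills$days_supplied < 1))
    stop("days_supplied < 1 for patient ", patient$patient_id,
         call. = FALSE)
  lo <- patient$discharge_day
  hi <- patient$discharge_day + thresholds$index_window_days
  in_win <- fills$fill_day >= lo & fills$fill_day <= hi
  if (!any(in_win)) return(NULL)
  d <- min(fills$fill_day[in_win])
  on_d <- fills[fills$fill_day == d, , drop = FALSE]
  supplied <- tapply(on_d$days_supplied, on_d$med_class, sum)
  supplied <- stats::setNames(as.integer(supplied), names(supplied))
  list(patient_id = patient$patient_id,
       index_day = as.integer(d - lo),
       days_supplied = supplied)
}

#' Covered-day intervals for one medication class
#'
#' Applies sequential supply stacking: fills are consumed in order, and a
#' refill dispensed before the previous supply runs out starts covering when
#' that supply ends.  Same-day fills are merged by summing supply.  The
#' resulting coverage is intersected with the half-open window
#' `[window_start, window_end)`.
#'
#' @param fills Data frame with `fill_day` and `days_supplied` for a single
#'   patient and class.
#' @param window_start,window_end Window bounds (global day offsets),
#'   `window_start < window_end`.
#' @return Two-column integer matrix of disjoint, ordered half-open
#'   intervals `[start, end)`; zero rows if nothing is covered.
#' @export
class_coverage <- function(fills, window_start, window_end) {
  stopifnot(window_start < window_end)
  empty <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (!nrow(fills)) return(empty)
  supplied <- tapply(fills$days_supplied, fills$fill_day, sum)
  days <- as.integer(names(supplied))
  o <- order(days)
  days <- days[o]; supplied <- as.integer(supplied[o])

  starts <- integer(length(days)); ends <- integer(length(days))
  e <- -.Machine$integer.max  # supply-exhaustion pointer
  for (i in seq_along(days)) {
    s <- max(days[i], e)
    e <- s + supplied[i]
    starts[i] <- s; ends[i] <- e
  }
  # stacking makes consecutive segments contiguous whenever a fill arrives
  # early; merge touching segments into maximal runs
  brk <- c(TRUE, starts[-1] > ends[-length(ends)])
  run <- cumsum(brk)
  iv <- cbind(start = tapply(starts, run, min), end = tapply(ends, run, max))
  iv[, "start"] <- pmax(iv[, "start"], window_start)
  iv[, "end"] <- pmin(iv[, "end"], window_end)
  iv <- iv[iv[, "start"] < iv[, "end"], , drop = FALSE]
  rownames(iv) <- NULL
  storage.mode(iv) <- "integer"
  iv
}

covered_days <- function(intervals) sum(intervals[, 2] - intervals[, 1])

# longest uncovered run inside [window_start, window_end), given disjoint
# ordered coverage intervals already clipped to the window; leading and
# trailing runs count
max_uncovered_run <- function(intervals, window_start, window_end) {
  gap_starts <- c(window_start, intervals[, 2])
  gap_ends <- c(intervals[, 1], window_end)
  max(0L, gap_ends - gap_starts)
}

#' Prolonged-dispensation flags at index fill
#'
#' @param index An index fill from [find_index_fill()].
#' @param thresholds An [adherence_thresholds()].
#' @return List with `per_class` (named logical: days supplied at index >=
#'   90) and `average` (mean days supplied across index classes >= 90).
#' @export
prolonged_flags <- function(index, thresholds = adherence_thresholds()) {
  stopifnot(!is.null(index))
  list(per_class = index$days_supplied >= thresholds$prolonged_days,
       average = mean(index$days_supplied) >= thresholds$prolonged_days)
}

#' Score one patient's adherence from claims
#'
#' Computes, for each medication class in the patient's index fill, the
#' proportion of days covered (PDC) over the follow-up window
#' `[discharge, discharge + W)` with `W = min(365, death - discharge)`,
#' using all of that class's fills (not only the index fill); averages the
#' class PDCs; and derives the adherence (average PDC >= 0.80), per-class
#' adherence, per-class persistence (no uncovered run >= 30 days, including
#' a trailing run), and prolonged-dispensation flags.
#'
#' @param patient One-row data frame or list with `patient_id`,
#'   `discharge_day`, and `death_day` (`NA` if alive through follow-up).
#' @param index Index fill from [find_index_fill()]; must not be `NULL`.
#' @param fills Data frame of all the patient's dispensations.
#' @param thresholds An [adherence_thresholds()].
#' @return List of class `adherence_result`: `patient_id`, `window_days`,
#'   `classes`, per-class named numerics/logicals `pdc`, `adherent_class`,
#'   `persistent_class`, `prolonged_class`, and scalars `average_pdc`,
#'   `adherent`, `prolonged_average`.
#' @export
compute_pdc <- function(patient, index, fills,
                        thresholds = adherence_thresholds()) {
  stopifnot(!is.null(index))
  W <- if (!is.null(patient$death_day) && !is.na(patient$death_day)) {
    min(thresholds$followup_days, patient$death_day - patient$discharge_day)
  } else thresholds$followup_days
  if (W <= 0)
    stop("follow-up window is empty (death on or before discharge) for ",
         "patient ", patient$patient_id, call. = FALSE)

  w0 <- patient$discharge_day
  w1 <- patient$discharge_day + W
  classes <- names(index$days_supplied)

  pdc <- persistent <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    f <- fills[fills$med_class == cl & fills$fill_day >= w0 &
                 fills$fill_day < w1, , drop = FALSE]
    iv <- class_coverage(f, w0, w1)
    pdc[cl] <- covered_days(iv) / W
    persistent[cl] <- max_uncovered_run(iv, w0, w1) < thresholds$gap_days
  }
  avg <- sum(pdc) / length(classes)
  pro <- prolonged_flags(index, thresholds)

  structure(list(
    patient_id = patient$patient_id,
    window_days = as.integer(W),
    classes = classes,
    pdc = pdc,
    average_pdc = avg,
    adherent = avg >= thresholds$pdc_threshold,
    adherent_class = pdc >= thresholds$pdc_threshold,
    persistent_class = as.logical(persistent) |>
      stats::setNames(classes),
    prolonged_class = pro$per_class,
    prolonged_average = pro$average,
    index_day = index$index_day,
    index_days_supplied = index$days_supplied),
    class = "adherence_result")
}

#' Score a whole cohort
#'
#' Applies [find_index_fill()] and [compute_pdc()] to every patient.
#' Patients without a fill inside the index window are excluded and logged;
#' dispensations whose `patient_id` matches no patient are counted as
#' orphans and ignored.
#'
#' @param patients,dispensations The two claims tables
#'   (see [read_claims()]).
#' @param thresholds An [adherence_thresholds()].
#' @return List of class `adherence_scores` with elements
#'   `results` (wide data frame, one row per retained patient, per-class
#'   columns suffixed by class name), `class_results` (long data frame, one
#'   row per retained patient x index class), `exclusions` (data frame
#'   `patient_id`, `reason`), and `n_orphan_dispensations`.
#' @export
score_cohort <- function(patients, dispensations,
                         thresholds = adherence_thresholds()) {
  validate_claims(patients, dispensations)
  orphan <- !dispensations$patient_id %in% patients$patient_id
  n_orphan <- sum(orphan)
  if (n_orphan)
    message(n_orphan, " orphan dispensation(s) without a matching patient ",
            "were ignored")
  dispensations <- dispensations[!orphan, , drop = FALSE]
  by_pat <- split(dispensations, dispensations$patient_id)

  res <- vector("list", nrow(patients))
  excl <- list()
  no_fills <- data.frame(patient_id = character(0), med_class = character(0),
                         fill_day = integer(0), days_supplied = integer(0))
  for (i in seq_len(nrow(patients))) {
    p <- patients[i, ]
    f <- by_pat[[p$patient_id]]
    if (is.null(f)) f <- no_fills
    idx <- find_index_fill(p, f, thresholds)
    if (is.null(idx)) {
      excl[[length(excl) + 1L]] <-
        data.frame(patient_id = p$patient_id, reason = "no index fill",
                   stringsAsFactors = FALSE)
      next
    }
    res[[i]] <- compute_pdc(p, idx, f, thresholds)
  }
  res <- res[!vapply(res, is.null, TRUE)]

  structure(list(
    results = adherence_results_wide(res),
    class_results = adherence_results_long(res),
    exclusions = if (length(excl)) do.call(rbind, excl) else
      data.frame(patient_id = character(0), reason = character(0)),
    n_orphan_dispensations = n_orphan,
    thresholds = thresholds),
    class = "adherence_scores")
}

adherence_results_wide <- function(res) {
  base_cols <- function(r) {
    data.frame(patient_id = r$patient_id, window_days = r$window_days,
               n_classes = length(r$classes), average_pdc = r$average_pdc,
               adherent = r$adherent, prolonged_average = r$prolonged_average,
               index_day = r$index_day, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(res, base_cols))
  if (is.null(out)) {
    out <- data.frame(patient_id = character(0), window_days = integer(0),
                      n_classes = integer(0), average_pdc = numeric(0),
                      adherent = logical(0), prolonged_average = logical(0),
                      index_day = integer(0))
  }
  for (cl in MED_CLASSES) {
    out[[paste0("pdc_", cl)]] <-
      vapply(res, function(r) unname(r$pdc[cl]), numeric(1))
    out[[paste0("adherent_", cl)]] <-
      vapply(res, function(r) unname(r$adherent_class[cl]), logical(1))
    out[[paste0("persistent_", cl)]] <-
      vapply(res, function(r) unname(r$persistent_class[cl]), logical(1))
    out[[paste0("prolonged_", cl)]] <-
      vapply(res, function(r) unname(r$prolonged_class[cl]), logical(1))
    out[[paste0("index_days_", cl)]] <-
      vapply(res, function(r) {
        v <- r$index_days_supplied[cl]
        if (is.na(v)) NA_integer_ else as.integer(v)
      }, integer(1))
  }
  rownames(out) <- NULL
  out
}

adherence_results_long <- function(res) {
  rows <- lapply(res, function(r) {
    data.frame(patient_id = r$patient_id, med_class = r$classes,
               pdc = unname(r$pdc),
               adherent = unname(r$adherent_class),
               persistent = unname(r$persistent_class),
               prolonged_at_index = unname(r$prolonged_class),
               index_days_supplied = unname(r$index_days_supplied),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(patient_id = character(0), med_class = character(0),
                      pdc = numeric(0), adherent = logical(0),
                      persistent = logical(0),
                      prolonged_at_index = logical(0),
                      index_days_supplied = integer(0))
  rownames(out) <- NULL
  out
}
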