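# End-to-end orchestration: simulate (or read) claims, score adherence,
# aggregate to group-month series, fit the segmented AR(1) model per group,
# and write publication-style tables and plot data.

#' Pipeline run configuration
#'
#' @param sim A [sim_config()] to generate synthetic claims, or `NULL` to
#'   read claims from `input_dir`.
#' @param input_dir Directory with `patients.csv` / `dispensations.csv`
#'   (ignored when `sim` is given).
#' @param outcome Outcome flag to model: `"adherent"` (primary),
#'   `"prolonged_average"`, or any per-class flag column.
#' @param n_months,t0 Study axis length and last pre-intervention month;
#'   defaulted from `sim` when given.
#' @param horizon Horizon (months) for the overall effect (default 12).
#' @param thresholds An [adherence_thresholds()].
#' @param df_method Degrees-of-freedom method for contrasts.
#' @param min_denominator Stability floor for monthly denominators.
#' @param force_fit Fit flagged-unstable series anyway (default `FALSE`).
#' @param outdir Output directory (`NULL`: no files written).
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), input_dir = NULL,
                       outcome = "adherent", n_months = NULL, t0 = NULL,
                       horizon = 12, thresholds = adherence_thresholds(),
                       df_method = "satterthwaite", min_denominator = 10L,
                       force_fit = FALSE, outdir = NULL) {
  if (is.null(sim) && is.null(input_dir))
    stop("either sim or input_dir must be given", call. = FALSE)
  if (!is.null(sim)) {
    if (is.null(n_months)) n_months <- sim$n_months
    if (is.null(t0)) t0 <- sim$t0
  }
  if (is.null(n_months) || is.null(t0))
    stop("n_months and t0 are required when reading claims from files",
         call. = FALSE)
  stopifnot(horizon >= 0, t0 < n_months)
  structure(list(sim = sim, input_dir = input_dir, outcome = outcome,
                 n_months = as.integer(n_months), t0 = as.integer(t0),
                 horizon = horizon, thresholds = thresholds,
                 df_method = df_method,
                 min_denominator = as.integer(min_denominator),
                 force_fit = force_fit, outdir = outdir),
            class = "run_config")
}

#' Run the full pipeline
#'
#' simulate/read -> score -> aggregate -> stability check -> per-group
#' segmented AR(1) fit -> effect tables and trajectories.  With `outdir`
#' set, writes `adherence_results.csv`, `exclusions.csv`,
#' `monthly_series.csv`, `trajectories.csv`, `effects_report.csv`,
#' `process_eval.csv`, and `fit_results.json`.  Identical configurations
#' (including the simulation seed) produce identical bundles.
#'
#' @param config A [run_config()].
#' @return List of class `adherits_run`: `scores`, `series`, `stability`,
#'   `fits` (per stable group), `effects` (combined effect table),
#'   `trajectories`, `process_eval`, `truth` (when simulated), `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log <<- c(log, msg)
  }

  if (!is.null(config$sim)) {
    sim <- simulate_cohort(config$sim)
    patients <- sim$patients; dispensations <- sim$dispensations
    truth <- sim$truth
    note("simulated %d patients, %d dispensations (seed %d)",
         nrow(patients), nrow(dispensations), config$sim$seed)
  } else {
    inp <- read_claims(config$input_dir)
    patients <- inp$patients; dispensations <- inp$dispensations
    truth <- NULL
    note("read %d patients, %d dispensations from %s",
         nrow(patients), nrow(dispensations), config$input_dir)
  }

  scores <- score_cohort(patients, dispensations, config$thresholds)
  note("scored %d patients; %d excluded (no index fill); %d orphan claims",
       nrow(scores$results), nrow(scores$exclusions),
       scores$n_orphan_dispensations)

  series <- aggregate_monthly(scores, patients, config$outcome,
                              config$n_months, config$t0)
  stab <- stability_check(series, config$min_denominator)
  for (i in seq_len(nrow(stab))) {
    if (!stab$stable[i])
      note(paste0("series for group %s flagged unstable (%d missing ",
                  "months, min denominator %d)%s"),
           stab$group[i], stab$n_missing[i], stab$min_denominator[i],
           if (config$force_fit) " - fitting anyway (force_fit)"
           else " - excluded from modeling")
  }

  groups <- stab$group[stab$stable | config$force_fit]
  fits <- list(); eff <- list(); traj <- list()
  for (g in groups) {
    s <- series[series$group == g, , drop = FALSE]
    fit <- tryCatch(reml_fit_ar1(build_design(s, config$t0)),
                    error = function(e) {
                      note("fit failed for group %s: %s", g,
                           conditionMessage(e))
                      NULL
                    })
    if (is.null(fit)) next
    if (fit$boundary) note("group %s: REML converged at the rho boundary", g)
    fits[[g]] <- fit
    tab <- effect_table(fit, h = config$horizon,
                        df_method = config$df_method)
    tab <- cbind(group = g, tab)
    eff[[g]] <- tab
    tr <- trajectories(fit)
    traj[[g]] <- cbind(group = g, tr)
  }

  pe <- process_eval_report(scores, patients,
                            split_day = month_boundaries(config$n_months)[
                              config$t0 + 1],
                            thresholds = config$thresholds)

  out <- structure(list(
    config = config, patients = patients, scores = scores, series = series,
    stability = stab, fits = fits,
    effects = if (length(eff)) do.call(rbind, eff) else NULL,
    trajectories = if (length(traj)) do.call(rbind, traj) else NULL,
    process_eval = pe, truth = truth, log = log),
    class = "adherits_run")

  if (!is.null(config$outdir)) write_run_bundle(out, config$outdir)
  out
}

write_run_bundle <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    if (!is.null(df))
      utils::write.csv(df, file.path(outdir, name), row.names = FALSE,
                       na = "")
  }
  wcsv(run$scores$results, "adherence_results.csv")
  wcsv(run$scores$exclusions, "exclusions.csv")
  wcsv(as.data.frame(run$series), "monthly_series.csv")
  wcsv(run$trajectories, "trajectories.csv")
  wcsv(run$effects, "effects_report.csv")
  wcsv(run$process_eval$table, "process_eval.csv")

  fits_json <- lapply(run$fits, function(f) {
    list(beta = as.list(f$beta), se = as.list(sqrt(diag(f$cov_beta))),
         rho = f$rho, sigma2 = f$sigma2, mse = f$mse,
         reml_loglik = f$reml_loglik, n = f$n,
         boundary = f$boundary)
  })
  jsonlite::write_json(
    list(outcome = run$config$outcome, t0 = run$config$t0,
         horizon = run$config$horizon, fits = fits_json,
         stability = run$stability, log = run$log),
    file.path(outdir, "fit_results.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(run$log, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}

#' Prolonged-dispensation proportions by group and period
#'
#' For each hospital group and period (pre/post the split day, by discharge
#' day), tabulates the proportion of retained patients with a prolonged
#' (>= 90 days supplied) dispensation at index fill: one row per medication
#' class (denominator: patients with that class at index) plus an
#' average-across-classes row (denominator: all retained patients).
#'
#' @param scores An `adherence_scores` from [score_cohort()].
#' @param patients The patient table.
#' @param split_day First post-intervention day (global day offset).
#' @param thresholds An [adherence_thresholds()] (carried for labeling).
#' @return List with `table` (tidy: `group`, `period`, `measure`,
#'   `numerator`, `denominator`, `pct`, `formatted` as `"n/N (pct%)"`).
#' @export
process_eval_report <- function(scores, patients, split_day,
                                thresholds = adherence_thresholds()) {
  res <- merge(scores$results,
               patients[, c("patient_id", "group", "discharge_day")],
               by = "patient_id")
  res$period <- ifelse(res$discharge_day >= split_day, "post", "pre")

  fmt <- function(n, N) {
    pct <- ifelse(N > 0, 100 * n / N, NA_real_)
    sprintf("%d/%d (%s%%)", n, N,
            ifelse(N > 0, formatC(pct, format = "fg", digits = 2), "-"))
  }
  rows <- list()
  for (g in unique(res$group)) for (per in c("pre", "post")) {
    sub <- res[res$group == g & res$period == per, , drop = FALSE]
    n <- sum(sub$prolonged_average); N <- nrow(sub)
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, period = per, measure = "average_across_classes",
      numerator = n, denominator = N,
      pct = if (N > 0) 100 * n / N else NA_real_, stringsAsFactors = FALSE)
    for (cl in MED_CLASSES) {
      flag <- sub[[paste0("prolonged_", cl)]]
      has <- !is.na(flag)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, period = per, measure = cl,
        numerator = sum(flag[has]), denominator = sum(has),
        pct = if (sum(has) > 0) 100 * sum(flag[has]) / sum(has) else
          NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$formatted <- fmt(tab$numerator, tab$denominator)
  rownames(tab) <- NULL
  list(table = tab, split_day = split_day)
}

#' @export
print.adherits_run <- function(x, ...) {
  cat("adherits pipeline run\n")
  cat(sprintf("  outcome: %s | months: %d (t0 = %d) | horizon: %g\n",
              x$config$outcome, x$config$n_months, x$config$t0,
              x$config$horizon))
  cat(sprintf("  retained patients: %d (excluded: %d)\n",
              nrow(x$scores$results), nrow(x$scores$exclusions)))
  cat(sprintf("  groups fitted: %s\n",
              if (length(x$fits)) paste(names(x$fits), collapse = ", ")
              else "none"))
  if (!is.null(x$effects)) {
    cat("  effect estimates:\n")
    print(within(x$effects, {
      estimate <- round(estimate, 3); se <- round(se, 3)
      ci_low <- round(ci_low, 3); ci_high <- round(ci_high, 3)
      p_value <- round(p_value, 4); df <- round(df, 1)
    })[, c("group", "name", "estimate", "ci_low", "ci_high", "p_value",
           "df")])
  }
  invisible(x)
}
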