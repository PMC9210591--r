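# Synthetic dispensation-claims generator.
#
# The generator is constructive: each patient's month-level latent adherence
# probability is drawn first (segmented trend + AR(1) noise), the patient's
# adherent/non-adherent label is drawn from it, and a refill trajectory is
# then built so that the scored average PDC lands on the intended side of the
# 80% threshold.  This makes the latent group-month proportion the estimand,
# so segmented-regression parameter recovery is a clean end-to-end test.

#' Configuration for the synthetic claims generator
#'
#' Defaults emulate a three-group hospital structure (two intervention
#' groups and one large external control) observed monthly over 36 calendar
#' months with the intervention starting after month 24, and an adherence
#' process with a baseline percentage, secular pre-trend, and immediate
#' (level) plus gradual (trend) intervention effects on the percent scale.
#'
#' @param n_months Number of calendar months of discharges (default 36).
#' @param t0 Last pre-intervention month index; discharges in months
#'   `t0 + 1, ..., n_months` are post-implementation (default 24).
#' @param groups Data frame with columns `group`, `n_sites`, `mean_monthly`
#'   (Poisson mean of monthly discharges) and logical `intervention`.
#'   Intervention effects apply only to rows with `intervention = TRUE`.
#' @param baseline_adherence_pct Baseline latent adherence percent at t = 0;
#'   must lie strictly inside (0, 100).
#' @param pre_slope_pct_per_month Secular pre-intervention slope
#'   (percent/month).
#' @param level_change_pct Immediate intervention effect: level change in the
#'   first post-implementation month (percent).
#' @param trend_change_pct_per_month Gradual intervention effect: slope
#'   change post-implementation (percent/month).
#' @param ar_rho AR(1) coefficient of the month-level latent noise,
#'   in (-1, 1).
#' @param innovation_sd_pct Innovation standard deviation of the AR(1)
#'   month-level noise (percentage points).
#' @param site_sd_pct Between-site SD of a site-constant shift of the latent
#'   percent within a group (default 0: no site heterogeneity).
#' @param class_mix Probabilities that an index fill involves 1, 2, 3 or 4
#'   medication classes (length-4 numeric summing to 1).
#' @param class_weights Relative marginal frequencies of the four classes
#'   (statin, beta blocker, angiotensin system inhibitor, secondary
#'   antiplatelet) used when sampling which classes a patient fills.
#' @param duration_mix Named probabilities over days-supplied values for
#'   pre-intervention discharges, e.g. `c("30" = .8, "60" = .13, "90" = .07)`.
#' @param duration_mix_post Same, for post-intervention discharges (defaults
#'   to `duration_mix`).
#' @param refill_gap_probs Named probabilities over inter-fill delays (days
#'   beyond supply exhaustion) for adherent patients.
#' @param nonadherent_gap_probs Same, for non-adherent patients (larger gaps).
#' @param index_delay_probs Probabilities over the index-fill delay 0..7 days
#'   after discharge.
#' @param nonadherent_coverage_range Range of the target coverage fraction
#'   for non-adherent patients; drawn uniformly, must stay below 0.8.
#' @param death_rate Per-year hazard of death during the 1-year follow-up.
#' @param seed Integer seed; identical configurations (including seed)
#'   produce byte-identical output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_months = 36,
                       t0 = 24,
                       groups = default_sim_groups(),
                       baseline_adherence_pct = 75.3,
                       pre_slope_pct_per_month = 0,
                       level_change_pct = -1.1,
                       trend_change_pct_per_month = 0.54,
                       ar_rho = 0.3,
                       innovation_sd_pct = 5,
                       site_sd_pct = 0,
                       class_mix = c(0.10, 0.25, 0.45, 0.20),
                       class_weights = c(0.30, 0.27, 0.19, 0.24),
                       duration_mix = c("30" = 0.80, "60" = 0.13, "90" = 0.07),
                       duration_mix_post = NULL,
                       refill_gap_probs = c("0" = 0.70, "1" = 0.15,
                                            "2" = 0.10, "3" = 0.05),
                       nonadherent_gap_probs = c("0" = 0.30, "5" = 0.30,
                                                 "15" = 0.20, "35" = 0.20),
                       index_delay_probs = c(0.55, 0.20, 0.10, 0.05, 0.04,
                                             0.03, 0.02, 0.01),
                       nonadherent_coverage_range = c(0.15, 0.70),
                       death_rate = 0.08,
                       seed = 1L) {
  if (is.null(duration_mix_post)) duration_mix_post <- duration_mix
  cfg <- list(
    n_months = as.integer(n_months), t0 = as.integer(t0), groups = groups,
    baseline_adherence_pct = baseline_adherence_pct,
    pre_slope_pct_per_month = pre_slope_pct_per_month,
    level_change_pct = level_change_pct,
    trend_change_pct_per_month = trend_change_pct_per_month,
    ar_rho = ar_rho, innovation_sd_pct = innovation_sd_pct,
    site_sd_pct = site_sd_pct,
    class_mix = class_mix, class_weights = class_weights,
    duration_mix = duration_mix, duration_mix_post = duration_mix_post,
    refill_gap_probs = refill_gap_probs,
    nonadherent_gap_probs = nonadherent_gap_probs,
    index_delay_probs = index_delay_probs,
    nonadherent_coverage_range = nonadherent_coverage_range,
    death_rate = death_rate, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @export
default_sim_groups <- function() {
  data.frame(
    group = c("intervention_1", "intervention_2", "control"),
    n_sites = c(2L, 4L, 143L),
    mean_monthly = c(39, 26, 515),
    intervention = c(TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_months >= 1L, cfg$t0 >= 1L)
  if (cfg$t0 >= cfg$n_months)
    stop("t0 must be strictly less than n_months", call. = FALSE)
  if (!(cfg$baseline_adherence_pct > 0 && cfg$baseline_adherence_pct < 100))
    stop("baseline_adherence_pct must lie strictly inside (0, 100): ",
         "clipping at baseline would bias parameter recovery", call. = FALSE)
  if (abs(cfg$ar_rho) >= 1)
    stop("ar_rho must lie in (-1, 1)", call. = FALSE)
  if (cfg$innovation_sd_pct < 0) stop("innovation_sd_pct must be >= 0",
                                      call. = FALSE)
  for (nm in c("class_mix", "class_weights", "duration_mix",
               "duration_mix_post", "refill_gap_probs",
               "nonadherent_gap_probs", "index_delay_probs")) {
    p <- cfg[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop(nm, " must be non-negative and sum to 1", call. = FALSE)
  }
  req <- c("group", "n_sites", "mean_monthly", "intervention")
  if (!all(req %in% names(cfg$groups)))
    stop("groups must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  r <- cfg$nonadherent_coverage_range
  if (length(r) != 2 || r[1] < 0 || r[2] >= 0.8 || r[1] > r[2])
    stop("nonadherent_coverage_range must lie within [0, 0.8)", call. = FALSE)
  invisible(cfg)
}

#' Latent segmented-trend mean (percent) at given months
#'
#' The deterministic part of the latent adherence process:
#' `baseline + pre_slope * t + [t > t0] * (level + trend * (t - t0))`.
#'
#' @param t Integer month indices.
#' @param cfg A `sim_config`.
#' @param intervention Whether the intervention effect terms apply.
#' @return Numeric vector of latent mean percents (not clipped).
#' @export
latent_mean_pct <- function(t, cfg, intervention = TRUE) {
  post <- as.numeric(t > cfg$t0)
  eff <- if (intervention) {
    post * (cfg$level_change_pct +
              cfg$trend_change_pct_per_month * (t - cfg$t0))
  } else 0
  cfg$baseline_adherence_pct + cfg$pre_slope_pct_per_month * t + eff
}

# Stationary AR(1) noise path of length n: e_t = rho e_{t-1} + u_t,
# u_t ~ N(0, sd^2), e_1 drawn from the stationary distribution.
ar1_noise <- function(n, rho, sd) {
  if (sd == 0) return(numeric(n))
  u <- stats::rnorm(n, 0, sd)
  e <- numeric(n)
  e[1] <- u[1] / sqrt(1 - rho^2)
  for (i in seq_len(n)[-1]) e[i] <- rho * e[i - 1] + u[i]
  e
}

#' Simulate a group-month proportion series directly from the segmented model
#'
#' Draws `y_t = beta0 + beta1 t + I(t > t0) (beta2 + beta3 (t - t0)) + e_t`
#' with stationary AR(1) errors.  This is the model-level simulator used for
#' estimator calibration (bias, confidence-interval coverage, type-I error);
#' unlike the claims generator it applies no clipping and no binomial
#' sampling layer.
#'
#' @param n_months,t0 Series length and last pre-intervention month.
#' @param beta Length-4 coefficient vector (intercept, pre-slope, level
#'   change, trend change), percent scale.
#' @param rho AR(1) coefficient.
#' @param sd Innovation standard deviation (percentage points).
#' @return Data frame with columns `t` and `y`.
#' @export
simulate_series <- function(n_months = 36, t0 = 24,
                            beta = c(75, 0, -1, 0.5), rho = 0.3, sd = 5) {
  stopifnot(length(beta) == 4, abs(rho) < 1, t0 < n_months)
  t <- seq_len(n_months)
  mu <- beta[1] + beta[2] * t +
    (t > t0) * (beta[3] + beta[4] * (t - t0))
  data.frame(t = t, y = mu + ar1_noise(n_months, rho, sd))
}

# Build one patient-class refill sequence by sequential stacking semantics.
# Returns a data.frame(fill_day, days_supplied).  `covered_target` is the
# total days of supply to dispense; `truncate` caps the final fill so total
# supply equals the target exactly (used for non-adherent patients).
gen_class_fills <- function(first_day, window_end, covered_target,
                            dur_values, dur_probs, gap_values, gap_probs,
                            index_duration, truncate) {
  if (first_day >= window_end || covered_target < 1)
    return(data.frame(fill_day = integer(0), days_supplied = integer(0)))
  n_max <- ceiling(covered_target / min(dur_values)) + 1L
  durs <- c(index_duration,
            sample_from(dur_values, n_max, dur_probs))
  cum <- cumsum(durs)
  k <- which(cum >= covered_target)[1]
  durs <- durs[seq_len(k)]
  if (truncate && k >= 1) {
    excess <- cum[k] - covered_target
    durs[k] <- durs[k] - excess
    if (durs[k] < 1) {
      durs <- durs[-k]
      k <- k - 1L
    }
  }
  if (k < 1) return(data.frame(fill_day = integer(0),
                               days_supplied = integer(0)))
  gaps <- sample_from(gap_values, k, gap_probs)
  gaps[1] <- 0
  # under sequential stacking fill i starts when supply i-1 runs out + gap
  starts <- first_day + cumsum(c(0, durs[-k])) + cumsum(gaps)
  keep <- starts < window_end
  data.frame(fill_day = as.integer(starts[keep]),
             days_supplied = as.integer(durs[keep]))
}

#' Simulate a synthetic cohort and its dispensation claims
#'
#' Generates a patient table, a dispensation-claims table, and a truth
#' record.  For each group and calendar month the latent adherence percent
#' follows the segmented trend plus stationary AR(1) noise, clipped to
#' \[0, 100\]; each discharged patient draws an adherent/non-adherent label
#' with that probability and receives a refill trajectory built to score on
#' the corresponding side of the 80% average-PDC threshold.  Every patient
#' who survives their sampled index delay has an index fill within 7 days of
#' discharge; patients who die earlier have no fills (and are excluded
#' downstream, as in real claims cohorts).
#'
#' @param cfg A [sim_config()].
#' @return A list of class `adherits_sim` with elements `patients`,
#'   `dispensations` (data frames in the package CSV dialect) and `truth`
#'   (generating parameters, per-group-month latent percents, per-patient
#'   latent labels, and counts of patients generated without an index fill).
#' @export
simulate_cohort <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  nm <- cfg$n_months
  bounds <- month_boundaries(nm)

  dur_values <- as.integer(names(cfg$duration_mix))
  dur_values_post <- as.integer(names(cfg$duration_mix_post))
  gap_values <- as.integer(names(cfg$refill_gap_probs))
  na_gap_values <- as.integer(names(cfg$nonadherent_gap_probs))

  latent <- list(); pat <- list(); disp <- list(); labels <- list()
  pid_counter <- 0L
  n_no_index <- 0L
  n_clipped <- 0L

  for (g in seq_len(nrow(cfg$groups))) {
    grp <- cfg$groups$group[g]
    n_sites <- cfg$groups$n_sites[g]
    site_ids <- sprintf("%s_s%02d", grp, seq_len(n_sites))
    site_eff <- stats::rnorm(n_sites, 0, cfg$site_sd_pct)
    mu <- latent_mean_pct(seq_len(nm), cfg,
                          intervention = cfg$groups$intervention[g])
    p_lat <- mu + ar1_noise(nm, cfg$ar_rho, cfg$innovation_sd_pct)
    clipped <- p_lat < 0 | p_lat > 100
    n_clipped <- n_clipped + sum(clipped)
    p_lat <- pmin(pmax(p_lat, 0), 100)
    latent[[g]] <- data.frame(group = grp, t = seq_len(nm),
                              latent_pct = p_lat,
                              stringsAsFactors = FALSE)

    n_month <- stats::rpois(nm, cfg$groups$mean_monthly[g])
    for (m in seq_len(nm)) {
      n_pat <- n_month[m]
      if (n_pat == 0L) next
      post <- m > cfg$t0
      dvals <- if (post) dur_values_post else dur_values
      dprobs <- if (post) cfg$duration_mix_post else cfg$duration_mix
      for (i in seq_len(n_pat)) {
        pid_counter <- pid_counter + 1L
        pid <- sprintf("P%06d", pid_counter)
        discharge <- bounds[m] +
          sample.int(bounds[m + 1] - bounds[m], 1L) - 1L
        site_idx <- sample.int(n_sites, 1L)
        p_i <- min(max(p_lat[m] + site_eff[site_idx], 0), 100)
        adherent <- stats::runif(1) < p_i / 100

        dd <- NA_integer_
        death_raw <- stats::rexp(1, rate = cfg$death_rate / 365.25)
        if (death_raw <= 365) dd <- discharge + max(1L, ceiling(death_raw))
        window_end <- if (is.na(dd)) discharge + 365L else min(discharge +
                                                                 365L, dd)

        delay <- sample(0:7, 1L, prob = cfg$index_delay_probs)
        d0 <- discharge + delay
        has_index <- d0 < window_end
        if (!has_index) n_no_index <- n_no_index + 1L

        n_cls <- sample(1:4, 1L, prob = cfg$class_mix)
        classes <- sample(MED_CLASSES, n_cls, prob = cfg$class_weights)

        if (has_index) {
          wlen <- window_end - d0
          fills <- lapply(classes, function(cl) {
            idx_dur <- sample_from(dvals, 1L, dprobs)
            if (adherent) {
              f <- gen_class_fills(d0, window_end, covered_target = wlen,
                                   dur_values = dvals, dur_probs = dprobs,
                                   gap_values = gap_values,
                                   gap_probs = cfg$refill_gap_probs,
                                   index_duration = idx_dur,
                                   truncate = FALSE)
            } else {
              f_cov <- stats::runif(1, cfg$nonadherent_coverage_range[1],
                                    cfg$nonadherent_coverage_range[2])
              # never trim the index fill itself: the prolonged-at-index
              # outcome must follow the configured duration mix exactly
              tgt <- max(idx_dur, floor(f_cov * (window_end - discharge)))
              f <- gen_class_fills(d0, window_end, covered_target = tgt,
                                   dur_values = dvals, dur_probs = dprobs,
                                   gap_values = na_gap_values,
                                   gap_probs = cfg$nonadherent_gap_probs,
                                   index_duration = idx_dur,
                                   truncate = TRUE)
            }
            if (nrow(f)) f$med_class <- cl
            f
          })
          fills <- do.call(rbind, fills[vapply(fills, nrow, 1L) > 0])
          if (!is.null(fills) && nrow(fills)) {
            fills$patient_id <- pid
            disp[[length(disp) + 1L]] <-
              fills[, c("patient_id", "med_class", "fill_day",
                        "days_supplied")]
          }
        }

        pat[[length(pat) + 1L]] <- data.frame(
          patient_id = pid, discharge_day = discharge, death_day = dd,
          group = grp, site_id = site_ids[site_idx],
          age = min(104L, 65L + stats::rpois(1, 11)),
          sex = sample(0:1, 1L),
          stemi = stats::runif(1) < 0.45,
          prior_mi = stats::runif(1) < 0.15,
          prior_med_use = stats::runif(1) < 0.60,
          stringsAsFactors = FALSE)
        labels[[length(labels) + 1L]] <- data.frame(
          patient_id = pid, group = grp, month = m,
          adherent_latent = adherent, has_index_fill = has_index,
          stringsAsFactors = FALSE)
      }
    }
  }

  latent <- do.call(rbind, latent)
  if (n_clipped > 0.01 * nrow(latent))
    warning(sprintf(paste0("latent adherence hit the [0, 100] bounds in ",
                           "%d of %d group-months; clipping biases ",
                           "parameter recovery"), n_clipped, nrow(latent)),
            call. = FALSE)

  out <- list(
    patients = do.call(rbind, pat),
    dispensations = if (length(disp)) do.call(rbind, disp) else
      data.frame(patient_id = character(0), med_class = character(0),
                 fill_day = integer(0), days_supplied = integer(0)),
    truth = list(config = cfg, latent = latent,
                 labels = do.call(rbind, labels),
                 n_no_index_fill = n_no_index,
                 n_clipped_months = n_clipped))
  rownames(out$patients) <- NULL
  rownames(out$dispensations) <- NULL
  class(out) <- "adherits_sim"
  out
}

#' @export
print.adherits_sim <- function(x, ...) {
  cat("Synthetic claims cohort\n")
  cat(sprintf("  patients:      %d\n", nrow(x$patients)))
  cat(sprintf("  dispensations: %d\n", nrow(x$dispensations)))
  cat(sprintf("  months: %d (last pre-intervention month: %d)\n",
              x$truth$config$n_months, x$truth$config$t0))
  cat(sprintf("  patients without index fill: %d\n",
              x$truth$n_no_index_fill))
  invisible(x)
}
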