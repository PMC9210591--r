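# Independent oracles used across the suite.  These deliberately use
# different algorithms from the package internals: coverage is recomputed
# day by day from a supply bank, and the AR(1) REML criterion is recomputed
# with dense-matrix linear algebra instead of the O(n) whitening recursion.

# Day-by-day supply-bank oracle for sequential stacking: each fill adds its
# days supplied to a bank on its fill day; every day with a positive bank is
# covered and consumes one day of supply.  Returns covered days inside
# [w0, w1) as a logical vector of length w1 - w0.
grid_coverage_oracle <- function(fills, w0, w1) {
  out_days <- w0:(w1 - 1)
  if (!nrow(fills)) return(rep(FALSE, length(out_days)))
  start <- min(min(fills$fill_day), w0)
  add <- tapply(fills$days_supplied, fills$fill_day, sum)
  bank <- 0
  covered <- logical(w1 - start)
  days <- start:(w1 - 1)
  for (i in seq_along(days)) {
    a <- add[as.character(days[i])]
    if (!is.na(a)) bank <- bank + a
    if (bank > 0) {
      covered[i] <- TRUE
      bank <- bank - 1
    }
  }
  covered[days >= w0]
}

intervals_to_grid <- function(iv, w0, w1) {
  g <- rep(FALSE, w1 - w0)
  for (r in seq_len(nrow(iv)))
    g[(iv[r, 1] - w0 + 1):(iv[r, 2] - w0)] <- TRUE
  g
}

rand_fill_set <- function(max_fills = 8, day_range = 0:400,
                          supply_range = 1:120) {
  n <- sample(0:max_fills, 1)
  data.frame(fill_day = sample(day_range, n, replace = TRUE),
             days_supplied = sample(supply_range, n, replace = TRUE))
}

fills_df <- function(days, supplies, class = "statin",
                     patient_id = "P1") {
  data.frame(patient_id = patient_id, med_class = class,
             fill_day = as.integer(days),
             days_supplied = as.integer(supplies),
             stringsAsFactors = FALSE)
}

patient_row <- function(patient_id = "P1", discharge_day = 0L,
                        death_day = NA_integer_, group = "intervention_1",
                        site_id = "s1") {
  data.frame(patient_id = patient_id, discharge_day = discharge_day,
             death_day = death_day, group = group, site_id = site_id,
             age = 70L, sex = 1L, stemi = FALSE, prior_mi = FALSE,
             prior_med_use = TRUE, stringsAsFactors = FALSE)
}

# Dense-matrix GLS/REML at fixed rho: covariance rho^|ti-tj|/(1-rho^2),
# explicit inverse, log-determinants via determinant(); independent of the
# whitening implementation under test.
brute_reml <- function(design, rho) {
  y <- design$y; X <- design$X; t <- design$t
  n <- length(y); p <- ncol(X)
  R <- outer(t, t, function(a, b) rho^abs(a - b)) / (1 - rho^2)
  Ri <- solve(R)
  XtRiX <- t(X) %*% Ri %*% X
  beta <- solve(XtRiX, t(X) %*% Ri %*% y)
  r <- y - X %*% beta
  rss <- drop(t(r) %*% Ri %*% r)
  s2 <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(2 * pi * s2) +
                  as.numeric(determinant(R)$modulus) +
                  as.numeric(determinant(XtRiX)$modulus) + rss / s2)
  list(loglik = ll, beta = drop(beta), sigma2 = s2)
}

small_sim_config <- function(seed = 1L, ...) {
  sim_config(
    n_months = 18, t0 = 12,
    groups = data.frame(group = c("intervention_1", "control"),
                        n_sites = c(2L, 5L), mean_monthly = c(30, 60),
                        intervention = c(TRUE, FALSE)),
    seed = seed, ...)
}
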