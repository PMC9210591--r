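test_that("identical configurations produce byte-identical cohorts", {
  a <- simulate_cohort(small_sim_config(seed = 7))
  b <- simulate_cohort(small_sim_config(seed = 7))
  expect_identical(a$patients, b$patients)
  expect_identical(a$dispensations, b$dispensations)
  expect_identical(a$truth$latent, b$truth$latent)
  c <- simulate_cohort(small_sim_config(seed = 8))
  expect_false(identical(a$patients, c$patients))
})

test_that("degenerate no-effect configuration has flat latent series", {
  cfg <- small_sim_config(seed = 3, baseline_adherence_pct = 75,
                          pre_slope_pct_per_month = 0,
                          level_change_pct = 0,
                          trend_change_pct_per_month = 0,
                          innovation_sd_pct = 0)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$truth$latent$latent_pct == 75))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(baseline_adherence_pct = 0), "strictly inside")
  expect_error(sim_config(baseline_adherence_pct = 100), "strictly inside")
  expect_error(sim_config(n_months = 24, t0 = 24), "strictly less")
  expect_error(sim_config(ar_rho = 1), "ar_rho")
  expect_error(sim_config(class_mix = c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
  expect_error(sim_config(nonadherent_coverage_range = c(0.2, 0.85)),
               "0.8")
})

test_that("generated patients satisfy the cohort invariants", {
  sim <- simulate_cohort(small_sim_config(seed = 12))
  p <- sim$patients
  dd <- p$death_day[!is.na(p$death_day)]
  expect_true(all(dd > p$discharge_day[!is.na(p$death_day)]))
  expect_true(all(!is.na(day_to_month(p$discharge_day, 18))))
  expect_true(all(sim$dispensations$days_supplied >= 1))
  expect_true(all(sim$dispensations$med_class %in%
                    c("statin", "beta_blocker",
                      "angiotensin_system_inhibitor",
                      "secondary_antiplatelet")))
  # every generated patient with an index fill has one within 7 days
  disp <- sim$dispensations
  first_fill <- tapply(disp$fill_day, disp$patient_id, min)
  delay <- first_fill - p$discharge_day[match(names(first_fill),
                                              p$patient_id)]
  expect_true(all(delay >= 0 & delay <= 7))
})

test_that("scored adherence flags reproduce the latent labels", {
  sim <- simulate_cohort(small_sim_config(seed = 21))
  sc <- score_cohort(sim$patients, sim$dispensations)
  lab <- merge(sc$results[, c("patient_id", "adherent")],
               sim$truth$labels, by = "patient_id")
  expect_gte(mean(lab$adherent == lab$adherent_latent), 0.99)
  # exclusions match the generator's count of patients without an index fill
  expect_equal(nrow(sc$exclusions), sim$truth$n_no_index_fill)
})

test_that("early deaths can preclude the index fill and are logged", {
  cfg <- small_sim_config(seed = 5, death_rate = 3)  # high hazard
  sim <- simulate_cohort(cfg)
  expect_gt(sim$truth$n_no_index_fill, 0)
  sc <- score_cohort(sim$patients, sim$dispensations)
  expect_equal(nrow(sc$exclusions), sim$truth$n_no_index_fill)
})

test_that("scored monthly proportions track the latent adherence percent", {
  # sd = 0 isolates the binomial sampling layer: the scored proportion per
  # month should sit within binomial Monte-Carlo error of the latent mean
  cfg <- sim_config(n_months = 12, t0 = 8,
                    groups = data.frame(group = "g", n_sites = 1L,
                                        mean_monthly = 400,
                                        intervention = TRUE),
                    baseline_adherence_pct = 75,
                    pre_slope_pct_per_month = 0,
                    level_change_pct = 0,
                    trend_change_pct_per_month = 0.5,
                    innovation_sd_pct = 0, seed = 31)
  sim <- simulate_cohort(cfg)
  sc <- score_cohort(sim$patients, sim$dispensations)
  ser <- aggregate_monthly(sc, sim$patients, "adherent", 12, 8)
  cmp <- merge(as.data.frame(ser), sim$truth$latent,
               by.x = c("group", "t"), by.y = c("group", "t"))
  se <- sqrt(cmp$latent_pct * (100 - cmp$latent_pct) / cmp$denominator)
  expect_true(all(abs(cmp$proportion_pct - cmp$latent_pct) < 4 * se))
  # pooled deviation within 3 pooled standard errors
  pooled_se <- sqrt(sum(se^2)) / nrow(cmp)
  expect_lt(abs(mean(cmp$proportion_pct - cmp$latent_pct)), 3 * pooled_se)
})

test_that("claims tables round-trip losslessly through CSV", {
  sim <- simulate_cohort(small_sim_config(seed = 1))
  dir <- withr::local_tempdir()
  write_claims(sim$patients, sim$dispensations, dir)
  back <- read_claims(dir)
  expect_equal(back$patients, sim$patients)
  expect_equal(back$dispensations, sim$dispensations)
  # re-writing the read tables gives identical bytes
  dir2 <- withr::local_tempdir()
  write_claims(back$patients, back$dispensations, dir2)
  expect_identical(readLines(file.path(dir, "patients.csv")),
                   readLines(file.path(dir2, "patients.csv")))
  expect_identical(readLines(file.path(dir, "dispensations.csv")),
                   readLines(file.path(dir2, "dispensations.csv")))
})

test_that("empty cohorts write header-only files", {
  sim <- simulate_cohort(small_sim_config(seed = 1))
  dir <- withr::local_tempdir()
  write_claims(sim$patients[0, ], sim$dispensations[0, ], dir)
  expect_length(readLines(file.path(dir, "patients.csv")), 1L)
  expect_length(readLines(file.path(dir, "dispensations.csv")), 1L)
})
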