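test_that("index fill is the earliest dispensation within 7 days of discharge", {
  p <- patient_row()
  # fill 8 days post-discharge: outside the window, patient excluded
  expect_null(find_index_fill(p, fills_df(8, 30)))

  # two classes filled on the same day join the index class set
  f <- rbind(fills_df(3, 30, "statin"), fills_df(3, 60, "beta_blocker"))
  idx <- find_index_fill(p, f)
  expect_equal(idx$index_day, 3L)
  expect_setequal(names(idx$days_supplied), c("statin", "beta_blocker"))
  expect_equal(idx$days_supplied[["beta_blocker"]], 60L)

  # a class first dispensed later than the index day is not an index class
  f <- rbind(fills_df(2, 30, "statin"), fills_df(5, 30, "beta_blocker"))
  idx <- find_index_fill(p, f)
  expect_equal(idx$index_day, 2L)
  expect_equal(names(idx$days_supplied), "statin")

  # same-class same-day fills merge by summing supply
  f <- rbind(fills_df(0, 30, "statin"), fills_df(0, 60, "statin"))
  expect_equal(find_index_fill(p, f)$days_supplied[["statin"]], 90L)

  # discharge offset respected and pre-discharge fills ignored
  p2 <- patient_row(discharge_day = 100L)
  expect_null(find_index_fill(p2, fills_df(95, 30)))
  expect_equal(find_index_fill(p2, fills_df(107, 30))$index_day, 7L)

  expect_error(find_index_fill(p, fills_df(0, -5)), "days_supplied")
})

test_that("sequential stacking pushes overlapping supply forward", {
  # overlapping refill: 30 + 30 days dispensed on days 0 and 20 cover [0,60)
  iv <- class_coverage(fills_df(c(0, 20), c(30, 30)), 0, 365)
  expect_equal(unname(iv), matrix(c(0L, 60L), 1))

  # a single year-long fill covers the whole window
  iv <- class_coverage(fills_df(0, 365), 0, 365)
  expect_equal(covered_days(iv), 365L)

  # disjoint fills leave the gap uncovered
  iv <- class_coverage(fills_df(c(0, 40), c(10, 10)), 0, 365)
  expect_equal(unname(iv), matrix(c(0L, 40L, 10L, 50L), 2))
  expect_equal(covered_days(iv), 20L)

  # coverage extending past the window is truncated
  iv <- class_coverage(fills_df(300, 100), 0, 365)
  expect_equal(unname(iv), matrix(c(300L, 365L), 1))

  expect_equal(nrow(class_coverage(data.frame(fill_day = integer(0),
                                              days_supplied = integer(0)),
                                   0, 365)), 0L)
})

test_that("PDC, adherence, and persistence follow the definitions", {
  th <- adherence_thresholds()
  p <- patient_row()

  # full coverage
  idx <- find_index_fill(p, fills_df(0, 365))
  r <- compute_pdc(p, idx, fills_df(0, 365))
  expect_equal(unname(r$pdc["statin"]), 1.0)
  expect_true(r$adherent)
  expect_true(unname(r$persistent_class["statin"]))

  # death censoring: covered [0,80), death day 100 -> PDC exactly 0.80,
  # adherent at the inclusive threshold
  pd <- patient_row(death_day = 100L)
  f <- fills_df(0, 80)
  r <- compute_pdc(pd, find_index_fill(pd, f), f)
  expect_equal(r$window_days, 100L)
  expect_equal(r$average_pdc, 0.80)
  expect_true(r$adherent)

  # average across classes: 1.0 and 0.50 -> 0.75, not adherent overall
  f <- rbind(fills_df(0, 365, "statin"),
             fills_df(0, 182, "beta_blocker"))
  r <- compute_pdc(p, find_index_fill(p, f), f)
  expect_equal(r$average_pdc, (1 + 182 / 365) / 2)
  expect_false(r$adherent)
  expect_true(unname(r$adherent_class["statin"]))
  expect_false(unname(r$adherent_class["beta_blocker"]))
  # exact averaging invariant
  expect_equal(r$average_pdc, sum(r$pdc) / length(r$classes))

  # sparse fills: 20/365 covered, 30-day gap breaks persistence
  f <- fills_df(c(0, 40), c(10, 10))
  r <- compute_pdc(p, find_index_fill(p, f), f)
  expect_equal(r$average_pdc, 20 / 365)
  expect_false(unname(r$persistent_class["statin"]))

  # death on the discharge day leaves no follow-up
  pbad <- patient_row(death_day = 0L)
  pbad$death_day <- 0L
  expect_error(compute_pdc(pbad, find_index_fill(pbad, fills_df(0, 30)),
                           fills_df(0, 30)), "follow-up window")
})

test_that("a trailing uncovered run of 30 days breaks persistence", {
  p <- patient_row()
  # exactly 30-day interior gap, covered to window end: non-persistent
  f <- fills_df(c(0, 40), c(10, 325))
  r <- compute_pdc(p, find_index_fill(p, f), f)
  expect_false(unname(r$persistent_class["statin"]))
  # 29-day gap: persistent
  f <- fills_df(c(0, 39), c(10, 326))
  r <- compute_pdc(p, find_index_fill(p, f), f)
  expect_true(unname(r$persistent_class["statin"]))
  # trailing gap only: stop 40 days before window end
  f <- fills_df(0, 325)
  r <- compute_pdc(p, find_index_fill(p, f), f)
  expect_false(unname(r$persistent_class["statin"]))
})

test_that("prolonged-dispensation flags use the inclusive 90-day threshold", {
  p <- patient_row()
  f <- rbind(fills_df(0, 90, "statin"), fills_df(0, 30, "beta_blocker"))
  pro <- prolonged_flags(find_index_fill(p, f))
  expect_true(pro$per_class[["statin"]])
  expect_false(pro$per_class[["beta_blocker"]])
  expect_false(pro$average)  # mean 60 < 90

  pro <- prolonged_flags(find_index_fill(p, fills_df(0, 90)))
  expect_true(pro$per_class[["statin"]])
  expect_true(pro$average)

  f <- rbind(fills_df(0, 100, "statin"), fills_df(0, 100, "beta_blocker"),
             fills_df(0, 80, "secondary_antiplatelet"))
  pro <- prolonged_flags(find_index_fill(p, f))
  expect_equal(sum(pro$per_class), 2L)
  expect_true(pro$average)  # (100 + 100 + 80) / 3 = 93.33 >= 90
})

test_that("cohort scoring excludes and logs patients without an index fill", {
  patients <- rbind(patient_row("A", 0L), patient_row("B", 0L),
                    patient_row("C", 0L))
  disp <- rbind(fills_df(0, 365, patient_id = "A"),
                fills_df(20, 365, patient_id = "B"),   # first fill day 20
                fills_df(3, 365, patient_id = "ORPHAN"))
  sc <- suppressMessages(score_cohort(patients, disp))
  expect_equal(sort(sc$results$patient_id), c("A"))
  expect_setequal(sc$exclusions$patient_id, c("B", "C"))
  expect_true(all(sc$exclusions$reason == "no index fill"))
  expect_equal(sc$n_orphan_dispensations, 1L)

  # every patient filling on day 0: zero exclusions
  disp_all <- rbind(fills_df(0, 30, patient_id = "A"),
                    fills_df(0, 30, patient_id = "B"),
                    fills_df(0, 30, patient_id = "C"))
  sc <- score_cohort(patients, disp_all)
  expect_equal(nrow(sc$exclusions), 0L)
  expect_equal(nrow(sc$results), 3L)
})
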