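test_that("category boundaries are assigned exactly", {
  expect_identical(
    categorize_bg(c(3.89, 3.9, 10, 10.01, 13.9, 13.91, 16.7, 16.71)),
    c(1L, 0L, 0L, 2L, 2L, 3L, 3L, 4L))
  expect_error(categorize_bg(0), "positive")
  expect_error(categorize_bg(c(5, NA)), "positive")
})

test_that("first-event detection keeps first crossings and flags day-zero events", {
  # single hypoglycemia crossing: first of two low values wins
  labs <- mk_labs("C1", "glucose", c(5.0, 3.5, 3.1), c(2, 10, 20))
  ev <- detect_first_events(labs)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$category, 1L)
  expect_identical(ev$bg_value, 3.5)
  expect_false(ev$at_first_measurement)

  # severe hyperglycemia at the very first measurement is voided
  labs <- mk_labs("C1", "glucose", c(18.0, 6.0), c(0, 5))
  ev <- detect_first_events(labs)
  expect_true(ev$at_first_measurement[ev$category == 4])

  # staircase: the first-measurement flag depends on earlier non-BG data
  labs <- mk_labs("C1", "glucose", c(11, 15, 17), c(1, 2, 3))
  ev <- detect_first_events(labs)
  expect_identical(ev$category, c(2L, 3L, 4L))
  expect_identical(ev$at_first_measurement, c(TRUE, FALSE, FALSE))
  with_prior <- rbind(mk_labs("C1", "sodium", 140, 0.5), labs)
  ev2 <- detect_first_events(with_prior)
  expect_false(any(ev2$at_first_measurement))
  # under the BG-only reading the flag returns
  ev3 <- detect_first_events(with_prior, first_measurement = "bg")
  expect_true(ev3$at_first_measurement[ev3$category == 2])

  expect_identical(nrow(detect_first_events(mk_labs("C1", "sodium", 140, 1))), 0L)
})

test_that("look-back windows precede the event strictly and yield the horizon", {
  labs <- mk_labs("C1", "glucose", c(5, 6, 12, 7), c(2, 5, 10, 12))
  coh <- mk_cohort(labs, stay_h = 48)
  ev_time <- labs$time[3]
  w <- build_lookback(coh, "C1", 2, ev_time)
  expect_identical(nrow(w$rows), 2L)            # h2 and h5 rows only
  expect_true(all(w$rows$time < ev_time))
  expect_equal(compute_horizon(w), 5)           # 10 - 5
  # control window spans the whole stay
  wc <- build_lookback(coh, "C1", 0)
  expect_identical(nrow(wc$rows), 4L)
  # single prior datum: window of one row, horizon 8 h
  labs1 <- mk_labs("C1", "glucose", c(5, 3.2), c(2, 10))
  coh1 <- mk_cohort(labs1, stay_h = 48)
  w1 <- build_lookback(coh1, "C1", 1, labs1$time[2])
  expect_identical(nrow(w1$rows), 1L)
  expect_equal(w1$horizon_hours, 8)
  # no data before the event: the category is dropped
  expect_error(build_lookback(coh1, "C1", 1, labs1$time[1]),
               "first measurements")
})

test_that("labeling a synthetic cohort recovers every injected event exactly", {
  coh <- small_cohort()
  lab <- small_labels()
  gt <- coh$ground_truth
  got <- lab$events[!lab$events$at_first_measurement, ]
  expect_identical(nrow(got), nrow(gt))
  m <- merge(gt, got, by = c("case_id", "category"))
  expect_identical(nrow(m), nrow(gt))
  expect_true(all(m$event_time.x == m$event_time.y))
  expect_true(all(m$bg_value.x == m$bg_value.y))
  # manifest horizons are positive and windows end at the events
  ev_rows <- lab$manifest[lab$manifest$category > 0, ]
  expect_true(all(ev_rows$horizon_hours > 0))
  expect_true(all(ev_rows$n_rows >= 1))
})

test_that("horizons are invariant under data recorded after the event", {
  labs <- mk_labs("C1", "glucose", c(5, 6, 3.0, 6, 7), c(2, 6, 9, 15, 20))
  coh <- mk_cohort(labs, stay_h = 48)
  lab1 <- label_cohort(coh)
  coh2 <- coh
  coh2$labs <- rbind(coh2$labs, mk_labs("C1", "sodium", 180, c(9.5, 18)))
  lab2 <- label_cohort(coh2)
  h1 <- lab1$manifest$horizon_hours[lab1$manifest$category == 1]
  h2 <- lab2$manifest$horizon_hours[lab2$manifest$category == 1]
  expect_identical(h1, h2)
  expect_equal(h1, 3)                            # 9 - 6
})

test_that("inclusion rules fire on diagnosis, drug and glycemia evidence", {
  base <- mk_labs("C1", "glucose", c(5, 9, 6.2), c(1, 5, 9))
  # no rule fires
  expect_false(meets_inclusion_criteria(mk_cohort(base))$included)
  # single extreme BG measurement
  inc <- meets_inclusion_criteria(
    mk_cohort(rbind(base, mk_labs("C1", "glucose", 11.1, 12))))
  expect_true(inc$included)
  expect_identical(inc$rule, "glucose")
  # HbA1c at the diagnostic threshold (mmol/mol and %)
  expect_true(meets_inclusion_criteria(
    mk_cohort(rbind(base, mk_labs("C1", "hba1c", 48, 2))))$included)
  expect_true(meets_inclusion_criteria(
    mk_cohort(rbind(base, mk_labs("C1", "hba1c_pct", 6.5, 2))))$included)
  # fasting and OGTT thresholds
  expect_true(meets_inclusion_criteria(
    mk_cohort(rbind(base, mk_labs("C1", "glucose_fasting", 7.0, 2))))$included)
  expect_false(meets_inclusion_criteria(
    mk_cohort(rbind(base, mk_labs("C1", "glucose_fasting", 6.9, 2))))$included)
  # diagnosis and drug routes
  t0 <- as.POSIXct("2016-04-01", tz = "UTC")
  inc_dx <- meets_inclusion_criteria(mk_cohort(base, diagnoses = data.frame(
    patient_id = "P1", icd10 = "E11.9", time = t0)))
  expect_identical(inc_dx$rule, "diagnosis")
  inc_drug <- meets_inclusion_criteria(mk_cohort(base, drugs = data.frame(
    case_id = "C1", atc = "A10BA02", time = t0, pre_admission = TRUE)))
  expect_identical(inc_drug$rule, "drug")
  # non-diabetes codes and drugs do not qualify
  expect_false(meets_inclusion_criteria(mk_cohort(base, diagnoses = data.frame(
    patient_id = "P1", icd10 = "I10", time = t0)))$included)
})
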