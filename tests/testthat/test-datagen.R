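test_that("the noise-free trajectory follows its closed form", {
  p <- trajectory_params(baseline_start = 160, stable_level = 125,
                         decline_halflife_days = 10, noise_cv = 0)
  x <- simulate_trajectory(p, 365, seed = 1)
  expect_equal(x[1], 160)
  expect_equal(x[11], 125 + 35 / 2)  # one half-life
  expect_equal(x[365], 125, tolerance = 1e-6)  # long-run level
  expect_true(all(diff(x) <= 0))
  # a rejection episode lifts the curve multiplicatively
  pr <- trajectory_params(baseline_start = 160, stable_level = 125,
                          decline_halflife_days = 10, noise_cv = 0,
                          rejection_events = list(c(100, 0.25, 7)))
  y <- simulate_trajectory(pr, 365, seed = 1)
  expect_equal(y[103], 1.25 * x[103])   # day 102, inside the event
  expect_equal(y[108], x[108])          # day 107, after the event
})

test_that("lognormal noise has roughly the configured coefficient of variation", {
  p <- trajectory_params(decline_halflife_days = 1e-6, noise_cv = 0.09)
  x <- simulate_trajectory(p, 5000, seed = 2)
  expect_equal(mean(x), p$stable_level, tolerance = 0.01)
  expect_equal(stats::sd(x) / mean(x), 0.09, tolerance = 0.1)
})

test_that("cohort simulation is reproducible and patients draw from substreams", {
  a <- simulate_cohort(n_patients = 4, seed = 5)
  b <- simulate_cohort(n_patients = 4, seed = 5)
  expect_identical(a$device, b$device)
  expect_identical(a$smss, b$smss)
  expect_identical(a$contacts, b$contacts)
  # the first patients are unchanged when the cohort grows
  c6 <- simulate_cohort(n_patients = 6, seed = 5)
  keep <- c6$device$patient_id %in% a$device$patient_id
  expect_identical(c6$device[keep, ], a$device)
  # a different seed changes the data
  d <- simulate_cohort(n_patients = 4, seed = 6)
  expect_false(identical(a$smss, d$smss))
})

test_that("simulated logs satisfy the interchange invariants", {
  sim <- simulate_cohort(n_patients = 6, seed = 9)
  expect_true(all(sim$device$value > 0))
  expect_true(all(sim$smss$value > 0))
  expect_true(all(sim$smss$slot %in% 1:2))
  expect_false(any(duplicated(
    paste(sim$smss$patient_id, sim$smss$measurement_date, sim$smss$slot))))
  expect_true(all(sim$smss$registration_date >= sim$smss$measurement_date))
  expect_true(all(as.numeric(sim$smss$registration_date -
                               sim$smss$measurement_date) <= 81))
  # truth labels one row per registration, mutually consistent
  expect_equal(nrow(sim$truth), nrow(sim$smss))
  expect_true(all(is.na(sim$truth$true_value[sim$truth$is_phantom])))
  expect_false(any(sim$truth$is_typo & sim$truth$is_rounded))
})

test_that("strict phantom days recover the injected phantom labels exactly", {
  sim <- simulate_cohort(n_patients = 20, seed = 21)
  tst <- filter_test_values(sim$device, sim$smss)
  days <- classify_days(build_buckets(tst$device, sim$smss))
  ph_days <- days[days$category == "phantom", c("patient_id", "date")]
  flagged <- paste(ph_days$patient_id, ph_days$date)
  truth_key <- paste(sim$truth$patient_id, sim$truth$measurement_date)
  # precision 1: every strict-phantom registration is a labelled phantom
  is_ph <- sim$truth$is_phantom[truth_key %in% flagged]
  expect_true(all(is_ph))
  # recall: labelled phantoms can hide on days with other device activity,
  # but the strict days must recover a substantial share
  recall <- sum(truth_key %in% flagged) / sum(sim$truth$is_phantom)
  expect_gt(recall, 0.8)
})

test_that("the default profile reproduces the study's headline structure", {
  sim <- simulate_cohort(n_patients = 43, seed = 12)
  tst <- filter_test_values(sim$device, sim$smss)
  s <- summarize_reliability(tst$device, sim$smss)
  # phantom share near 2% of registrations, unregistered share near 22%
  expect_gt(s$phantom$frac_of_registered, 0.005)
  expect_lt(s$phantom$frac_of_registered, 0.05)
  expect_gt(s$unregistered$frac_of_measured, 0.10)
  expect_lt(s$unregistered$frac_of_measured, 0.35)
  # noncorrespondence broadly at the published level
  expect_gt(s$noncorresponding$frac, 0.05)
  expect_lt(s$noncorresponding$frac, 0.25)
})
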