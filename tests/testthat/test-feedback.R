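test_that("the rolling baseline averages the last five registered values", {
  expect_equal(fb_baseline(rep(100, 5)), 100)
  expect_equal(fb_baseline(c(90, 95, 100, 105, 110, 200)), 122)  # last five
  expect_equal(fb_baseline(120), 120)
  expect_equal(fb_baseline(c(100, 110), feedback_policy(baseline_window = 5)),
               105)
  expect_error(fb_baseline(numeric(0)), "empty")
})

test_that("first-registration feedback follows the strict >15%/>20% bands", {
  h <- rep(100, 5)
  expect_equal(classify_first(110, h),
               list(light = "green", kind = "day_conclusion",
                    advice = "continue"))
  expect_equal(classify_first(115, h)$light, "green")   # boundary: strict >
  o <- classify_first(116, h)
  expect_equal(o$light, "orange")
  expect_equal(o$kind, "action_feedback")
  expect_equal(o$advice, "repeat_measurement_now")
  expect_equal(classify_first(120, h)$light, "orange")  # boundary: strict >
  r <- classify_first(121, h)
  expect_equal(r$light, "red")
  expect_equal(r$advice, "repeat_measurement_now")
  expect_error(classify_first(100, h, registrations_today = 2), "cap")
})

test_that("second-registration feedback maps bands onto day-conclusion advices", {
  h <- rep(100, 5)
  expect_equal(classify_second(100, h),
               list(light = "green", kind = "day_conclusion",
                    advice = "continue"))
  expect_equal(classify_second(118, h)$advice, "measure_again_tomorrow")
  r <- classify_second(125, h)
  expect_equal(r$light, "red")
  expect_equal(r$advice, "contact_hospital")
  expect_error(classify_second(100, h, registrations_today = 0),
               "prior first")
})

test_that("with no history the system starts green and baselines grow from available values", {
  expect_equal(classify_first(500, numeric(0))$light, "green")
  # two prior values: baseline is their mean
  expect_equal(classify_first(round(105 * 1.16), c(100, 110))$light, "orange")
})

test_that("feedback severity is monotone in the registered value", {
  h <- c(98, 103, 100, 102, 97)
  sev <- c(green = 1, orange = 2, red = 3)
  lights <- vapply(80:140, function(v) classify_first(v, h)$light,
                   character(1))
  expect_true(all(diff(sev[lights]) >= 0))
})

test_that("replay emits the feedback of the historical system in registration order", {
  # stable log: everything green
  stable <- smss_row("P1", DAY0 + 0:9, 100)
  out <- replay_feedback(stable)
  expect_equal(nrow(out), 10L)
  expect_true(all(out$light == "green"))

  # one value 21% above a constant baseline: exactly one red action feedback
  one_red <- smss_row("P1", DAY0 + 0:9, c(rep(100, 6), 121, rep(100, 3)))
  out <- replay_feedback(one_red)
  expect_equal(sum(out$light == "red"), 1L)
  expect_equal(out$kind[out$light == "red"], "action_feedback")

  # empty log
  expect_equal(nrow(replay_feedback(stable[0, ])), 0L)
})

test_that("replay computes baselines at registration time, not measurement time", {
  # five seeds, then a high value measured early but registered AFTER five
  # later stable values: at registration time the baseline is still ~100,
  # so the stale high value alerts.
  seeds <- smss_row("P1", DAY0 + 0:4, 100)
  late_high <- smss_row("P1", DAY0 + 5, 125, delay = 6L)
  fresh <- smss_row("P1", DAY0 + 6:10, 100)
  out <- replay_feedback(dplyr::bind_rows(seeds, late_high, fresh))
  high <- out[out$value == 125, ]
  expect_equal(high$light, "red")
  # and the later stable values were processed before it
  expect_true(all(out$registration_date == sort(out$registration_date)))
})

test_that("the second value of a day is judged against the pre-day baseline", {
  seeds <- smss_row("P1", DAY0 + 0:4, 100)
  d <- DAY0 + 5
  first <- smss_row("P1", d, 200, slot = 1)   # +100%: red action feedback
  second <- smss_row("P1", d, 118, slot = 2)  # vs 100, not vs (100..200)
  out <- replay_feedback(dplyr::bind_rows(seeds, first, second))
  expect_equal(out$light[out$slot == 2 & out$measurement_date == d], "orange")
  # with the first value included instead, 118 would read as green
  pol <- feedback_policy(include_first_in_second_baseline = TRUE)
  out2 <- replay_feedback(dplyr::bind_rows(seeds, first, second), pol)
  expect_equal(out2$light[out2$slot == 2 & out2$measurement_date == d],
               "green")
})

test_that("registrations beyond the per-day cap are flagged and skipped", {
  seeds <- smss_row("P1", DAY0 + 0:4, 100)
  d <- DAY0 + 5
  three <- dplyr::bind_rows(
    smss_row("P1", d, 100, slot = 1),
    smss_row("P1", d, 100, slot = 2),
    # malformed third entry for the same day
    tibble::tibble(patient_id = "P1", measurement_date = d,
                   registration_date = d, value = 100, slot = 3L)
  )
  expect_warning(out <- replay_feedback(dplyr::bind_rows(seeds, three)),
                 "cap")
  expect_equal(sum(out$skipped), 1L)
  expect_true(is.na(out$light[out$skipped]))
})
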