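test_that("buckets join device and SMSS values on the claimed measurement day", {
  dev <- dplyr::bind_rows(
    device_row("P1", DAY0, 130, hour = 8),
    device_row("P1", DAY0, 140, hour = 20),
    device_row("P1", DAY0 + 1, 150)
  )
  reg <- dplyr::bind_rows(
    smss_row("P1", DAY0, 130),
    smss_row("P1", DAY0 + 2, 118)  # claims a day with no measurement
  )
  b <- build_buckets(dev, reg)
  expect_equal(nrow(b), 3L)
  expect_equal(b$measured[[1]], c(130, 140))  # ascending by time
  expect_equal(b$registered[[1]], 130)
  expect_equal(b$measured[[3]], numeric(0))
  expect_equal(b$registered[[3]], 118)
  # test-flagged values never enter the measured side
  dev$is_test[2] <- TRUE
  b2 <- build_buckets(dev, reg)
  expect_equal(b2$measured[[1]], 130)
})

test_that("day classification implements the five-way taxonomy plus mixed days", {
  expect_equal(classify_day(130, 130)$category, "reliable")
  expect_equal(classify_day(130, 120)$category, "noncorresponding")
  expect_equal(classify_day(numeric(0), 118)$category, "phantom")
  expect_equal(classify_day(130, numeric(0))$category, "omission")
  sel <- classify_day(c(130, 145, 150), 130)
  expect_equal(sel$category, "selection")
  expect_setequal(sel$unregistered, c(145, 150))
  expect_equal(sel$pairs$measured, 130)  # the registered value pairs exactly
  mix <- classify_day(130, c(130, 140))
  expect_equal(mix$category, "mixed")
  expect_equal(mix$surplus_registered, 140)
  expect_error(classify_day(numeric(0), numeric(0)), "empty")
})

test_that("day classification agrees with exhaustive case enumeration on small buckets", {
  # independent oracle: decide the category from counts and elementwise
  # equality alone, for every bucket shape with <= 3 values per side
  oracle <- function(m, r) {
    if (length(m) == length(r)) {
      if (all(m == r)) "reliable" else "noncorresponding"
    } else if (length(m) == 0) "phantom"
    else if (length(r) == 0) "omission"
    else if (length(m) > length(r)) "selection"
    else "mixed"
  }
  vals <- c(100, 110)
  for (nm in 0:3) {
    for (nr in 0:3) {
      if (nm == 0 && nr == 0) next
      grid_m <- if (nm == 0) list(numeric(0)) else
        asplit(as.matrix(expand.grid(rep(list(vals), nm))), 1)
      grid_r <- if (nr == 0) list(numeric(0)) else
        asplit(as.matrix(expand.grid(rep(list(vals), nr))), 1)
      for (m in grid_m) {
        for (r in grid_r) {
          m <- as.numeric(m); r <- as.numeric(r)
          expect_equal(classify_day(m, r)$category, oracle(m, r),
                       info = paste("m:", paste(m, collapse = ","),
                                    "r:", paste(r, collapse = ",")))
        }
      }
    }
  }
})

test_that("cause attribution distinguishes date shifts, rounding, typos and incorrect entries", {
  expect_equal(attribute_cause(137, 135, numeric(0)), "rounding")
  expect_equal(attribute_cause(137, 173, numeric(0)), "typo")
  expect_equal(attribute_cause(137, 101, neighbor_values = 101), "date_shift")
  expect_equal(attribute_cause(130, 147, numeric(0)), "unexplained")
  # precedence: an exact nearby-date match beats everything
  expect_equal(attribute_cause(137, 135, neighbor_values = 135), "date_shift")
  # dropped digit and adjacent transposition both count as typos
  expect_equal(attribute_cause(137, 13, numeric(0)), "typo")
  expect_equal(attribute_cause(137, 1375, numeric(0)), "typo")
  expect_error(attribute_cause(130, 130, numeric(0)), "differing")
})

test_that("date-shift attribution uses unmatched device values on nearby days", {
  # day 3 measured 137 but registered 101; 101 was measured (and never
  # registered) two days earlier
  dev <- dplyr::bind_rows(
    device_row("P1", DAY0, 101),
    device_row("P1", DAY0 + 2, 137)
  )
  reg <- smss_row("P1", DAY0 + 2, 101)
  days <- classify_days(build_buckets(dev, reg))
  causes <- attribute_causes(days, dev, reg)
  expect_equal(causes$cause, "date_shift")
  # but if the nearby value had its own registration, no shift is inferred
  reg2 <- dplyr::bind_rows(reg, smss_row("P1", DAY0, 101))
  days2 <- classify_days(build_buckets(dev, reg2))
  causes2 <- attribute_causes(days2, dev, reg2)
  expect_equal(causes2$cause, "unexplained")
})

test_that("unflagged test-strip values are identified by the four criteria", {
  d <- DAY0
  dev <- dplyr::bind_rows(
    device_row("P1", d, 120, hour = 8),
    # unregistered 180, in test range, differing from both neighbours,
    # minutes before a registered value
    tibble::tibble(patient_id = "P1",
                   timestamp = as.POSIXct(as.character(d), tz = "UTC") +
                     8 * 3600 + 600,
                   value = 180, is_test = FALSE),
    device_row("P1", d + 1, 120)
  )
  reg <- dplyr::bind_rows(smss_row("P1", d, 120), smss_row("P1", d + 1, 120))
  out <- filter_test_values(dev, reg)
  expect_equal(out$candidates$value, 180)

  # outside the manufacturer's range: not a candidate
  dev2 <- dev
  dev2$value[2] <- 300
  expect_equal(nrow(filter_test_values(dev2, reg)$candidates), 0L)

  # flagged on the device: excluded regardless of criteria
  dev3 <- dev
  dev3$is_test[2] <- TRUE
  out3 <- filter_test_values(dev3, reg)
  expect_equal(nrow(out3$test_flagged), 1L)
  expect_false(any(out3$device$value == 180))

  # measured too long before the registered value: criterion 4 fails
  dev4 <- dev
  dev4$timestamp[2] <- dev4$timestamp[1] + 4 * 3600
  expect_equal(nrow(filter_test_values(dev4, reg)$candidates), 0L)
})

test_that("the reliability summary reproduces constructed fractions and closes its partitions", {
  # perfect log
  logs <- daily_logs("P1", rep(130, 20), rep(130, 20))
  s <- summarize_reliability(logs$device, logs$smss)
  expect_equal(s$reliable$frac, 1.0)
  expect_equal(s$phantom$n, 0L)
  expect_equal(s$omission$n_values, 0)

  # 87 matching of 100 equal-count registrations
  fx <- equal_count_fixture(87, 0, 13, n_patients = 10)
  s <- summarize_reliability(fx$device, fx$smss)
  expect_equal(s$reliable$frac, 0.87)
  expect_equal(s$noncorresponding$n, 13)
  expect_equal(s$noncorresponding$incorrect_n, 13L)
})

test_that("every registration and measurement is counted exactly once", {
  sim <- simulate_cohort(n_patients = 12, seed = 42)
  tst <- filter_test_values(sim$device, sim$smss)
  s <- summarize_reliability(tst$device, sim$smss)
  days <- s$days
  # registrations partition
  reg_counted <- s$equal_days$n_registrations + s$phantom$n +
    sum(days$n_registered[days$category == "selection"]) +
    sum(days$n_measured[days$category == "mixed"]) + s$mixed$surplus_n
  expect_equal(reg_counted, s$totals$n_registered)
  # measurements partition
  matched <- sum(vapply(days$pairs, nrow, integer(1)))
  meas_counted <- matched + s$omission$n_values + s$selection$n_unregistered
  expect_equal(meas_counted, s$totals$n_measured)
  # reliable + noncorresponding = equal-count registrations
  expect_equal(s$reliable$n + s$noncorresponding$n,
               s$equal_days$n_registrations)
  # explained + incorrect = noncorresponding
  expect_equal(s$noncorresponding$explained_n + s$noncorresponding$incorrect_n,
               s$noncorresponding$n)
})

test_that("selection-day pairing is deterministic and prefers exact value matches", {
  r1 <- classify_day(c(150, 130, 145), 130)
  expect_equal(r1$pairs$measured, 130)
  # closest match when no exact one exists
  r2 <- classify_day(c(150, 128, 145), 130)
  expect_equal(r2$pairs$measured, 128)
  # repeated calls give identical results
  expect_identical(r1, classify_day(c(150, 130, 145), 130))
})

test_that("forced lowest-value selection registers the day minimum", {
  prof <- behavior_profile(p_select_lowest = 1, p_extra_measurement = 1,
                           p_same_day = 1, p_typo = 0, p_round = 0,
                           p_underreport = 0, p_omit_high_extra = 0,
                           p_phantom_per_missed_day = 0, tests_per_month = 0,
                           p_repeat_on_alert = 0,
                           p_register_given_measured = 1)
  sim <- simulate_cohort(n_patients = 4, profile = prof, seed = 7)
  days <- classify_days(build_buckets(sim$device, sim$smss))
  sel <- days[days$category == "selection", ]
  expect_gt(nrow(sel), 0)
  for (i in seq_len(nrow(sel))) {
    expect_equal(sel$registered[[i]], min(sel$measured[[i]]))
  }
})
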