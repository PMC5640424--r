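test_that("adherence categories partition the ratio axis with the printed boundaries", {
  r <- c(0, 0.2499, 0.25, 0.5, 0.7499, 0.75, 0.9, 1.0, 1.0001, 2)
  expect_equal(as.character(adherence_category(r)),
               c("extremely_nonadherent", "extremely_nonadherent",
                 "nonadherent", "nonadherent", "nonadherent",
                 "adherent", "adherent", "adherent",
                 "overadherent", "overadherent"))
  # boundary cases from the protocol definitions
  expect_equal(as.character(adherence_category(21 / 28)), "adherent")
  expect_equal(as.character(adherence_category(6 / 28)),
               "extremely_nonadherent")
  expect_equal(as.character(adherence_category(16 / 15)), "overadherent")
  expect_error(adherence_category(-0.1), "non-negative")
})

test_that("adherence scoring counts distinct event days per phase", {
  starts <- tibble::tibble(patient_id = "P1", start_date = DAY0,
                           end_date = DAY0 + 363)
  # 21 distinct days in phase 1, one of them measured twice
  events <- tibble::tibble(patient_id = "P1",
                           date = DAY0 + c(0:20, 5))
  sc <- score_adherence(events, starts)
  p1 <- sc[sc$phase == 1, ]
  expect_equal(p1$performed_days, 21)
  expect_equal(p1$ratio, 0.75)
  expect_equal(as.character(p1$category), "adherent")
  expect_equal(sc$performed_days[sc$phase == 2], 0)
  expect_error(
    score_adherence(tibble::tibble(patient_id = "P9", date = DAY0), starts),
    "start date"
  )
})

test_that("cohort adherence reports printed-style percentages over complete phases only", {
  fx <- adherence_fixture()
  sc <- score_adherence(fx$events, fx$starts)
  coh <- cohort_adherence(sc)
  expect_equal(coh$per_phase$n_eligible, c(48L, 47L, 46L, 46L))
  expect_equal(coh$per_phase$n_adherent_or_over, c(36L, 46L, 43L, 39L))
  expect_equal(coh$per_phase$pct, c(75, 98, 93, 85))
  # every patient perfect: 100% everywhere
  cal <- requested_day_calendar()
  perfect_events <- tidyr::crossing(patient_id = c("A", "B"),
                                    day = cal$day_index) |>
    dplyr::transmute(patient_id, date = DAY0 + day)
  st <- tibble::tibble(patient_id = c("A", "B"), start_date = DAY0,
                       end_date = DAY0 + 363)
  coh2 <- cohort_adherence(score_adherence(perfect_events, st))
  expect_equal(coh2$per_phase$pct, c(100, 100, 100, 100))
  # empty cohort
  empty <- cohort_adherence(score_adherence(perfect_events[0, ], st[0, ]))
  expect_equal(nrow(empty$per_phase), 0L)
})

test_that("repeatedly nonadherent patients are flagged", {
  st <- tibble::tibble(patient_id = "P1", start_date = DAY0,
                       end_date = DAY0 + 363)
  # nonadherent in phases 1 and 2, adherent later
  cal <- requested_day_calendar()
  ev <- tibble::tibble(
    patient_id = "P1",
    date = DAY0 + c(0:9, cal$day_index[cal$phase %in% 3:4])
  )
  coh <- cohort_adherence(score_adherence(ev, st))
  expect_equal(coh$repeat_nonadherent, "P1")
})

test_that("delay statistics band patients and clamp negative delays", {
  reg <- dplyr::bind_rows(
    smss_row("P1", DAY0 + 0:2, 100),                 # always same day
    smss_row("P2", DAY0 + 0:2, 100, delay = c(0, 0, 12)),
    smss_row("P3", DAY0, 100, delay = 81)
  )
  ds <- delay_stats(reg, device = NULL)
  pp <- ds$per_patient
  expect_true(pp$always_same_day[pp$patient_id == "P1"])
  expect_equal(pp$mean_delay[pp$patient_id == "P2"], 4)
  expect_true(pp$mean_delay_gt_3[pp$patient_id == "P2"])
  expect_equal(pp$mean_delay[pp$patient_id == "P3"], 81)
  expect_equal(ds$max_delay, 81)

  neg <- smss_row("P4", DAY0 + 5, 100)
  neg$registration_date <- DAY0 + 2
  ds2 <- delay_stats(dplyr::bind_rows(reg, neg), device = NULL)
  expect_equal(ds2$n_negative_clamped, 1L)
  expect_equal(min(ds2$delays$delay), 0)
})

test_that("delay uses the device date when the claimed date mislabels the measurement", {
  # value 137 measured on day 0, registered under day 2 with day-2 entry date
  dev <- device_row("P1", DAY0, 137)
  reg <- smss_row("P1", DAY0 + 2, 137)
  ds <- delay_stats(reg, dev)
  expect_equal(ds$delays$delay, 2)  # device day 0 -> registered day 2
  # without a device match the claimed date stands
  ds2 <- delay_stats(reg, device = NULL)
  expect_equal(ds2$delays$delay, 0)
})

test_that("the feedback audit attributes outcomes and closes its counts", {
  fx <- audit_fixture()
  fb <- replay_feedback(fx$smss)
  audit <- audit_feedback_adherence(fb, fx$device, fx$smss, fx$contacts)
  expect_equal(audit$action$total, 258L)
  expect_equal(audit$action$followed, 137L)
  expect_equal(audit$action$delayed_registration, 85L)
  expect_equal(audit$action$premeasured, 14L)
  with(audit$action,
       expect_equal(followed + delayed_registration + premeasured + other,
                    total))
  expect_equal(audit$tomorrow$total, 39L)
  expect_equal(audit$tomorrow$followed, 33L)
  expect_equal(audit$hospital$total, 24L)
  expect_equal(audit$hospital$contacted, 14L)
  expect_equal(audit$hospital$sameday_frac, 1.0)
})

test_that("single audit cases behave as designed", {
  # red day conclusion + telephone contact next day -> contacted
  one <- audit_case("X1", "red_contacted")
  fb <- replay_feedback(one$smss)
  a <- audit_feedback_adherence(fb, one$device, one$smss, one$contacts)
  expect_equal(a$hospital$contacted, 1L)
  # action feedback registered five days late -> delayed registration
  two <- audit_case("X2", "delayed")
  fb2 <- replay_feedback(two$smss)
  a2 <- audit_feedback_adherence(fb2, two$device, two$smss, NULL)
  expect_equal(a2$action$delayed_registration, 1L)
  # no contact log: hospital adherence not evaluable, never zero
  expect_false(a2$hospital$evaluable)
  expect_true(is.na(a2$hospital$frac_contacted))
})

test_that("registration-basis adherence never exceeds measurement-basis adherence without phantoms", {
  prof <- behavior_profile(p_phantom_per_missed_day = 0)
  sim <- simulate_cohort(n_patients = 10, profile = prof, seed = 11)
  m <- score_adherence(
    tibble::tibble(patient_id = sim$device$patient_id[!sim$device$is_test],
                   date = as.Date(sim$device$timestamp[!sim$device$is_test])),
    sim$starts, basis = "measured")
  r <- score_adherence(
    tibble::tibble(patient_id = sim$smss$patient_id,
                   date = sim$smss$measurement_date),
    sim$starts, basis = "registered")
  j <- dplyr::inner_join(m, r, by = c("patient_id", "phase"),
                         suffix = c("_m", "_r"))
  expect_true(all(j$ratio_r <= j$ratio_m))
})
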