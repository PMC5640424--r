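# Fixture builders used across tests. All fixtures are constructed in code;
# dates are arbitrary calendar dates, values are integers in µmol/l.

DAY0 <- as.Date("2015-01-01")

device_row <- function(pid, date, value, hour = 8, is_test = FALSE) {
  tibble::tibble(
    patient_id = pid,
    timestamp = as.POSIXct(as.character(date), tz = "UTC") + hour * 3600,
    value = value, is_test = is_test
  )
}

smss_row <- function(pid, mdate, value, slot = 1L, delay = 0L) {
  tibble::tibble(
    patient_id = pid, measurement_date = as.Date(mdate),
    registration_date = as.Date(mdate) + delay, value = value,
    slot = as.integer(slot)
  )
}

# One measurement and one registration per day over consecutive dates.
# `registered` NA means omission day; `measured` NA means phantom day.
daily_logs <- function(pid, measured, registered, start = DAY0) {
  n <- max(length(measured), length(registered))
  dates <- start + seq_len(n) - 1
  dev <- tibble::tibble(
    patient_id = pid,
    timestamp = as.POSIXct(as.character(dates), tz = "UTC") + 8 * 3600,
    value = as.numeric(measured), is_test = FALSE
  )[!is.na(measured), ]
  reg <- tibble::tibble(
    patient_id = pid, measurement_date = dates,
    registration_date = dates, value = as.numeric(registered), slot = 1L
  )[!is.na(registered), ]
  list(device = dev, smss = reg)
}

# Equal-count fixture: `n_rel` matching days (130/130), `n_expl` explained
# mismatches (130/135: rounding), `n_incorrect` unexplained (130/147),
# spread round-robin over `n_patients`.
equal_count_fixture <- function(n_rel, n_expl, n_incorrect, n_patients = 43) {
  n <- n_rel + n_expl + n_incorrect
  registered <- c(rep(130, n_rel), rep(135, n_expl), rep(147, n_incorrect))
  pid <- sprintf("R%02d", rep_len(seq_len(n_patients), n))
  date <- DAY0 + (seq_len(n) - 1) %/% n_patients
  dev <- tibble::tibble(
    patient_id = pid,
    timestamp = as.POSIXct(as.character(date), tz = "UTC") + 8 * 3600,
    value = 130, is_test = FALSE
  )
  reg <- tibble::tibble(
    patient_id = pid, measurement_date = date, registration_date = date,
    value = registered, slot = 1L
  )
  list(device = dplyr::arrange(dev, patient_id, timestamp),
       smss = dplyr::arrange(reg, patient_id, measurement_date))
}

# Registration-count fixture: `n_matched` matched registrations plus
# `n_phantom` registrations on measurement-free days.
phantom_fixture <- function(n_matched, n_phantom, n_patients = 43) {
  n <- n_matched + n_phantom
  pid <- sprintf("R%02d", rep_len(seq_len(n_patients), n))
  date <- DAY0 + (seq_len(n) - 1) %/% n_patients
  measured <- c(rep(TRUE, n_matched), rep(FALSE, n_phantom))
  dev <- tibble::tibble(
    patient_id = pid[measured],
    timestamp = as.POSIXct(as.character(date[measured]), tz = "UTC") + 8 * 3600,
    value = 130, is_test = FALSE
  )
  reg <- tibble::tibble(
    patient_id = pid, measurement_date = date, registration_date = date,
    value = c(rep(130, n_matched), rep(118, n_phantom)), slot = 1L
  )
  list(device = dev, smss = reg)
}

# Measurement-count fixture: n_eq equal-count days (1/1), n_omit omission
# days (1/0), n_sel selection days (3 measured / 1 registered).
representativeness_fixture <- function(n_eq, n_omit, n_sel, n_patients = 43) {
  n_days <- n_eq + n_omit + n_sel
  pid <- sprintf("R%02d", rep_len(seq_len(n_patients), n_days))
  date <- DAY0 + (seq_len(n_days) - 1) %/% n_patients
  kind <- c(rep("eq", n_eq), rep("omit", n_omit), rep("sel", n_sel))
  dev <- list(); reg <- list()
  for (i in seq_len(n_days)) {
    if (kind[i] == "sel") {
      dev[[i]] <- tibble::tibble(
        patient_id = pid[i],
        timestamp = as.POSIXct(as.character(date[i]), tz = "UTC") +
          c(8, 12, 16) * 3600,
        value = c(130, 145, 150), is_test = FALSE
      )
    } else {
      dev[[i]] <- tibble::tibble(
        patient_id = pid[i],
        timestamp = as.POSIXct(as.character(date[i]), tz = "UTC") + 8 * 3600,
        value = 130, is_test = FALSE
      )
    }
    if (kind[i] != "omit") {
      reg[[i]] <- tibble::tibble(
        patient_id = pid[i], measurement_date = date[i],
        registration_date = date[i], value = 130, slot = 1L
      )
    }
  }
  list(device = dplyr::bind_rows(dev), smss = dplyr::bind_rows(reg))
}

# Adherence fixture realizing given per-phase adherent/eligible counts.
# Patients adherent in a phase get the full requested-day calendar for it,
# nonadherent patients get half; ineligible patients have end_date before
# the phase end.
adherence_fixture <- function(adherent = c(36, 46, 43, 39),
                              eligible = c(48, 47, 46, 46)) {
  sched <- default_schedule()
  cal <- requested_day_calendar(sched)
  ranges <- phase_day_range(sched)
  n <- max(eligible)
  starts <- tibble::tibble(
    patient_id = sprintf("A%02d", seq_len(n)),
    start_date = DAY0,
    end_date = DAY0 + max(ranges$day_end)
  )
  # patients become ineligible from the top index down
  for (ph in seq_len(4)) {
    drop <- n - eligible[ph]
    if (drop > 0) {
      cut_day <- ranges$day_end[ph] - 1
      idx <- seq(n - drop + 1, n)
      starts$end_date[idx] <- pmin(starts$end_date[idx], DAY0 + cut_day)
    }
  }
  events <- list()
  for (i in seq_len(n)) {
    for (ph in seq_len(4)) {
      if (as.numeric(starts$end_date[i] - DAY0) < ranges$day_end[ph]) next
      days <- cal$day_index[cal$phase == ph]
      if (i > adherent[ph]) days <- days[seq_len(floor(length(days) / 2))]
      events[[length(events) + 1L]] <- tibble::tibble(
        patient_id = starts$patient_id[i], date = DAY0 + days
      )
    }
  }
  list(events = dplyr::bind_rows(events), starts = starts)
}

# Feedback-audit fixture. Each case is its own pseudo-patient with five
# same-day seed registrations of 100 (stable baseline), then an event day
# with a first value of 120 (orange action feedback). The outcome argument
# drives what happens next. Returns device/smss/contacts plus the event
# date per case.
audit_case <- function(pid, outcome) {
  seed_dates <- DAY0 + 0:4
  d <- DAY0 + 5
  dev <- dplyr::bind_rows(
    device_row(pid, seed_dates, 100),
    device_row(pid, d, 120, hour = 8)
  )
  reg <- dplyr::bind_rows(
    smss_row(pid, seed_dates, 100),
    smss_row(pid, d, 120, slot = 1L,
             delay = if (outcome %in% c("delayed", "orange_delayed",
                                        "red_delayed")) 4L else 0L)
  )
  contacts <- NULL
  second <- function(value, delay = 0L) {
    dev <<- dplyr::bind_rows(dev, device_row(pid, d, value, hour = 9))
    reg <<- dplyr::bind_rows(reg, smss_row(pid, d, value, slot = 2L,
                                           delay = delay))
  }
  switch(outcome,
    followed_green = second(110),
    orange_followed = {
      second(118)
      dev <- dplyr::bind_rows(dev, device_row(pid, d + 1, 100))
      reg <- dplyr::bind_rows(reg, smss_row(pid, d + 1, 100))
    },
    orange_delayed = second(118, delay = 4L),
    orange_measured_only = {
      second(118)
      dev <- dplyr::bind_rows(dev, device_row(pid, d + 1, 100))
    },
    orange_other = second(118),
    red_contacted = {
      second(125)
      contacts <- tibble::tibble(patient_id = pid, date = d + 1,
                                 channel = "telephone")
    },
    red_delayed = second(125, delay = 4L),
    delayed = NULL,
    premeasured = {
      dev <- dplyr::bind_rows(dev, device_row(pid, d, 119, hour = 7))
    },
    other = NULL,
    stop("unknown outcome ", outcome)
  )
  list(device = dev, smss = reg, contacts = contacts)
}

audit_fixture <- function(counts = c(followed_green = 87,
                                     orange_followed = 33,
                                     orange_delayed = 3,
                                     orange_measured_only = 1,
                                     orange_other = 2,
                                     red_contacted = 14,
                                     red_delayed = 10,
                                     delayed = 72,
                                     premeasured = 14,
                                     other = 22)) {
  outcomes <- rep(names(counts), counts)
  parts <- lapply(seq_along(outcomes), function(i) {
    audit_case(sprintf("F%03d", i), outcomes[i])
  })
  list(
    device = dplyr::bind_rows(lapply(parts, `[[`, "device")),
    smss = dplyr::bind_rows(lapply(parts, `[[`, "smss")),
    contacts = dplyr::bind_rows(lapply(parts, `[[`, "contacts"))
  )
}
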