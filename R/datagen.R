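#' Parameters of the post-transplant creatinine trajectory
#'
#' A recovering graft is modelled as an exponential decline from
#' `baseline_start` towards `stable_level` with half-life
#' `decline_halflife_days`, multiplied by day-to-day lognormal noise (the
#' compound of biological variation and meter imprecision) and by optional
#' multiplicative rejection bumps. The noise coefficient of variation default
#' (0.09) is calibrated so that a stable simulated patient triggers
#' repeat-measurement feedback on roughly 7% of registrations under the
#' default 15%/20% thresholds — the rate observed with this class of
#' point-of-care meter.
#'
#' @param baseline_start Creatinine at day 0, µmol/l (default 160).
#' @param stable_level Long-run level, µmol/l (default 125).
#' @param decline_halflife_days Half-life of the decline (default 10).
#' @param noise_cv Lognormal coefficient of variation (default 0.09).
#' @param rejection_events List of `c(start_day, relative_rise,
#'   duration_days)` vectors (default none).
#' @return A list of class `trajectory_params`.
#' @export
trajectory_params <- function(baseline_start = 160,
                              stable_level = 125,
                              decline_halflife_days = 10,
                              noise_cv = 0.09,
                              rejection_events = list()) {
  stopifnot(baseline_start > 0, stable_level > 0,
            stable_level <= baseline_start,
            decline_halflife_days > 0, noise_cv >= 0)
  for (ev in rejection_events) {
    stopifnot(length(ev) == 3, ev[1] >= 0, ev[2] > 0, ev[3] > 0)
  }
  structure(list(
    baseline_start = baseline_start, stable_level = stable_level,
    decline_halflife_days = decline_halflife_days, noise_cv = noise_cv,
    rejection_events = rejection_events
  ), class = "trajectory_params")
}

#' Behavioral profile of a simulated patient
#'
#' Encodes, as probabilities and simple distributions, every behaviour the
#' audit pipeline is designed to detect: imperfect measurement adherence per
#' phase, skipped registrations (with an extra tendency to skip when the
#' value looks high), batching of registrations (delay), selective
#' registration of the lowest of multiple same-day values, deliberate
#' under-reporting, typos, rounding, phantom entries drawn below the
#' patient's recent level, occasional extra same-day repeats and unflagged
#' test-strip values, and responsiveness to red feedback.
#'
#' @param p_measure Probability of measuring on a requested day, one value
#'   per phase (default `c(0.80, 0.95, 0.95, 0.85)`).
#' @param p_register_given_measured Probability a measured day is registered
#'   at all (default 0.9).
#' @param p_same_day Probability a registration happens on the measurement
#'   day (default 0.5); otherwise the delay is `1 + Geometric` with mean
#'   `delay_mean` days, truncated at `delay_max`.
#' @param delay_mean Mean delay in days given not same-day (default 6).
#' @param delay_max Delay truncation, days (default 81).
#' @param p_select_lowest Probability of registering only the lowest of
#'   multiple same-day measurements (default 0.7).
#' @param p_typo Probability of a digit typo in the registered value
#'   (default 0.02).
#' @param p_round Probability of registering the value rounded to the
#'   nearest 10 (default 0.03).
#' @param p_underreport Probability of deliberately entering a value 10-40
#'   µmol/l lower (default 0.06); `underreport_steps` are the multiples of
#'   10 sampled.
#' @param p_omit_high_extra Extra omission probability when the day's value
#'   exceeds the recent mean by more than `omit_high_threshold` (defaults
#'   0.15 and 0.05).
#' @param p_phantom_per_missed_day Probability of registering a phantom
#'   value on a requested day with no measurement (default 0.12, which puts
#'   the phantom share of registrations near the ~2% seen in home-monitoring
#'   diaries); phantom values are Normal(recent mean + `phantom_shift`,
#'   `phantom_sd`) (defaults -15 and 10).
#' @param p_repeat_on_alert Probability that a patient whose value exceeds
#'   the recent mean by more than the orange threshold performs a
#'   confirmatory repeat and registers both values (default 0.6). Whether
#'   that response reaches the system in time still depends on the delay
#'   model — delayed registrants see stale advice.
#' @param p_extra_measurement Probability of an extra same-day repeat
#'   (default 0.08) with within-day CV `repeat_cv` (default 0.04).
#' @param tests_per_month Expected unprompted test-strip measurements per
#'   month (default 0.5), uniform in 133-239 µmol/l, flagged on the device
#'   with probability `p_test_flagged` (default 0.5).
#' @param p_contact_given_red_sameday,p_contact_given_red_delayed
#'   Probability of contacting the hospital after a red day conclusion when
#'   the triggering registration was same-day (default 1) or delayed
#'   (default 0).
#' @param underreport_steps,omit_high_threshold,phantom_shift,phantom_sd,repeat_cv,p_test_flagged
#'   See above.
#' @return A list of class `behavior_profile`.
#' @export
behavior_profile <- function(p_measure = c(0.80, 0.95, 0.95, 0.85),
                             p_register_given_measured = 0.9,
                             p_same_day = 0.5,
                             delay_mean = 6,
                             delay_max = 81,
                             p_select_lowest = 0.7,
                             p_typo = 0.02,
                             p_round = 0.03,
                             p_underreport = 0.06,
                             underreport_steps = 1:4,
                             p_omit_high_extra = 0.15,
                             omit_high_threshold = 0.05,
                             p_phantom_per_missed_day = 0.12,
                             phantom_shift = -15,
                             phantom_sd = 10,
                             p_extra_measurement = 0.08,
                             p_repeat_on_alert = 0.6,
                             repeat_cv = 0.04,
                             tests_per_month = 0.5,
                             p_test_flagged = 0.5,
                             p_contact_given_red_sameday = 1.0,
                             p_contact_given_red_delayed = 0.0) {
  fields <- as.list(environment())
  probs <- c(p_measure, p_register_given_measured, p_same_day,
             p_select_lowest, p_typo, p_round, p_underreport,
             p_omit_high_extra, p_phantom_per_missed_day,
             p_extra_measurement, p_repeat_on_alert, p_test_flagged,
             p_contact_given_red_sameday, p_contact_given_red_delayed)
  stopifnot(all(probs >= 0), all(probs <= 1),
            p_typo + p_round + p_underreport <= 1,
            delay_mean >= 1, delay_max >= 1, phantom_sd >= 0, repeat_cv >= 0,
            tests_per_month >= 0)
  structure(fields, class = "behavior_profile")
}

#' Error-free, fully adherent behavioral profile
#'
#' Every requested day measured once, every measurement registered the same
#' day without distortion, no phantoms, repeats or test strips; hospital is
#' always contacted after red feedback.
#'
#' @return A `behavior_profile`.
#' @export
perfect_profile <- function() {
  behavior_profile(
    p_measure = c(1, 1, 1, 1), p_register_given_measured = 1,
    p_same_day = 1, p_select_lowest = 0, p_typo = 0, p_round = 0,
    p_underreport = 0, p_omit_high_extra = 0,
    p_phantom_per_missed_day = 0, p_extra_measurement = 0,
    p_repeat_on_alert = 1, tests_per_month = 0,
    p_contact_given_red_sameday = 1, p_contact_given_red_delayed = 1
  )
}

#' Simulate a daily true-creatinine series
#'
#' `value(d) = stable + (start - stable) * 2^(-d / halflife)`, multiplied by
#' lognormal noise with the configured coefficient of variation (mean 1) and
#' by `(1 + relative_rise)` during any rejection event.
#'
#' @param params A [trajectory_params()].
#' @param n_days Number of days (day indices `0 .. n_days - 1`).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (as inside [simulate_cohort()]).
#' @return Numeric vector of length `n_days`, µmol/l.
#' @export
simulate_trajectory <- function(params = trajectory_params(), n_days,
                                seed = NULL) {
  stopifnot(inherits(params, "trajectory_params"), n_days >= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- seq_len(n_days) - 1
  base <- params$stable_level +
    (params$baseline_start - params$stable_level) *
    2^(-d / params$decline_halflife_days)
  bump <- rep(1, n_days)
  for (ev in params$rejection_events) {
    sel <- d >= ev[1] & d < ev[1] + ev[3]
    bump[sel] <- bump[sel] * (1 + ev[2])
  }
  if (params$noise_cv > 0) {
    sdlog <- sqrt(log(1 + params$noise_cv^2))
    noise <- exp(stats::rnorm(n_days, -sdlog^2 / 2, sdlog))
  } else {
    noise <- rep(1, n_days)
  }
  base * bump * noise
}

# single-digit typo: substitution of one digit or adjacent transposition
typo_value <- function(v) {
  s <- strsplit(as.character(v), "")[[1]]
  for (. in 1:10) {
    t <- s
    if (length(s) >= 2 && stats::runif(1) < 0.5) {
      i <- sample.int(length(s) - 1L, 1L)
      t[c(i, i + 1L)] <- t[c(i + 1L, i)]
    } else {
      i <- sample.int(length(s), 1L)
      t[i] <- as.character(sample(setdiff(0:9, as.integer(t[i])), 1))
    }
    out <- as.numeric(paste(t, collapse = ""))
    if (!is.na(out) && out != v && out >= 20) return(out)
  }
  v + 1  # degenerate fallback (all candidates invalid)
}

draw_delay <- function(profile) {
  if (stats::runif(1) < profile$p_same_day) return(0L)
  min(1L + stats::rgeom(1, 1 / profile$delay_mean), profile$delay_max)
}

#' Simulate a monitored cohort with labelled ground truth
#'
#' Generates, per patient, a true creatinine trajectory, a device log of
#' performed measurements (plus repeats and test strips), an SMSS log of
#' registered values subject to selection, distortion, omission, delay and
#' phantoms, a hospital-contact log responding to red day conclusions, and a
#' truth table labelling every registered value. Fully reproducible per
#' seed; every patient draws from its own substream so single patients can
#' be regenerated in isolation.
#'
#' @param n_patients Cohort size (default 43).
#' @param params A [trajectory_params()].
#' @param profile A [behavior_profile()].
#' @param schedule A schedule tibble.
#' @param seed Integer seed.
#' @param origin First possible monitoring start date.
#' @param policy [feedback_policy()] used for the in-stream feedback replay
#'   that drives hospital contacts.
#' @return A list with tibbles `device`, `smss`, `contacts`, `truth`,
#'   `starts`, and the replayed `feedback`.
#' @export
simulate_cohort <- function(n_patients = 43,
                            params = trajectory_params(),
                            profile = behavior_profile(),
                            schedule = default_schedule(),
                            seed = 1L,
                            origin = as.Date("2015-03-01"),
                            policy = feedback_policy()) {
  cal <- requested_day_calendar(schedule)
  horizon <- max(phase_day_range(schedule)$day_end)
  n_days <- horizon + 1L
  dev_rows <- smss_rows <- truth_rows <- vector("list", n_patients)
  starts <- tibble::tibble(patient_id = sprintf("P%03d", seq_len(n_patients)),
                           start_date = origin, end_date = origin)
  for (i in seq_len(n_patients)) {
    set.seed((seed * 131071L + i) %% 2147483647L)
    pid <- starts$patient_id[i]
    start <- origin + sample.int(30L, 1L) - 1L
    starts$start_date[i] <- start
    starts$end_date[i] <- start + horizon
    traj <- simulate_trajectory(params, n_days)

    measured <- stats::runif(nrow(cal)) < profile$p_measure[cal$phase]
    day0 <- as.POSIXct(as.character(start), tz = "UTC")
    dev_time <- as.POSIXct(character(), tz = "UTC")
    dev_val <- numeric(0); dev_test <- logical(0)
    reg_mdate <- reg_rdate <- as.Date(character())
    reg_val <- numeric(0); reg_slot <- integer(0)
    tru_true <- tru_emit <- tru_delay <- numeric(0)
    tru_typo <- tru_round <- tru_under <- tru_phantom <- tru_sel <- logical(0)
    recent <- numeric(0)  # measured main values, day order
    sdlog_rep <- sqrt(log(1 + profile$repeat_cv^2))

    for (j in seq_len(nrow(cal))) {
      d <- cal$day_index[j]
      date <- start + d
      if (measured[j]) {
        main_val <- max(20, round(traj[d + 1]))
        main_time <- day0 + d * 86400 + 8 * 3600 +
          round(stats::runif(1, 0, 7200))
        day_vals <- main_val
        day_times <- main_time
        trail <- if (length(recent) > 0) {
          mean(utils::tail(recent, 5))
        } else main_val
        # a value clearly above the recent level alarms the patient: with
        # some probability they repeat the measurement to confirm, and will
        # register both values (the protocol's intended response)
        responds <- main_val > trail * (1 + policy$orange_threshold) &&
          stats::runif(1) < profile$p_repeat_on_alert
        if (responds || stats::runif(1) < profile$p_extra_measurement) {
          rep_val <- max(20, round(traj[d + 1] *
                                     exp(stats::rnorm(1, -sdlog_rep^2 / 2,
                                                      sdlog_rep))))
          day_vals <- c(day_vals, rep_val)
          day_times <- c(day_times, main_time + if (responds) 1800 else 4 * 3600)
        }
        dev_time <- c(dev_time, day_times)
        dev_val <- c(dev_val, day_vals)
        dev_test <- c(dev_test, rep(FALSE, length(day_vals)))

        p_reg <- profile$p_register_given_measured
        if (!responds &&
            main_val > trail * (1 + profile$omit_high_threshold)) {
          p_reg <- max(0, p_reg - profile$p_omit_high_extra)
        }
        if (responds || stats::runif(1) < p_reg) {
          if (!responds && length(day_vals) > 1 &&
              stats::runif(1) < profile$p_select_lowest) {
            to_reg <- min(day_vals)
            selected_low <- TRUE
          } else {
            to_reg <- day_vals[seq_len(min(2L, length(day_vals)))]
            selected_low <- FALSE
          }
          delay <- draw_delay(profile)
          for (s in seq_along(to_reg)) {
            v <- to_reg[s]
            emitted <- v
            is_typo <- is_round <- is_under <- FALSE
            u <- stats::runif(1)
            if (u < profile$p_underreport) {
              emitted <- max(20, v - 10 * sample(profile$underreport_steps, 1))
              is_under <- TRUE
            } else if (u < profile$p_underreport + profile$p_typo) {
              emitted <- typo_value(v)
              is_typo <- emitted != v
            } else if (u < profile$p_underreport + profile$p_typo +
                         profile$p_round) {
              emitted <- max(20, round(v, -1))
              is_round <- emitted != v
            }
            reg_mdate <- c(reg_mdate, date)
            reg_rdate <- c(reg_rdate, date + delay)
            reg_val <- c(reg_val, emitted)
            reg_slot <- c(reg_slot, s)
            tru_true <- c(tru_true, v); tru_emit <- c(tru_emit, emitted)
            tru_typo <- c(tru_typo, is_typo)
            tru_round <- c(tru_round, is_round)
            tru_under <- c(tru_under, is_under)
            tru_phantom <- c(tru_phantom, FALSE)
            tru_sel <- c(tru_sel, selected_low)
            tru_delay <- c(tru_delay, delay)
          }
        }
        recent <- c(recent, main_val)
      } else if (stats::runif(1) < profile$p_phantom_per_missed_day) {
        trail <- if (length(recent) > 0) {
          mean(utils::tail(recent, 5))
        } else params$stable_level
        v <- max(20, round(stats::rnorm(1, trail + profile$phantom_shift,
                                        profile$phantom_sd)))
        delay <- draw_delay(profile)
        reg_mdate <- c(reg_mdate, date)
        reg_rdate <- c(reg_rdate, date + delay)
        reg_val <- c(reg_val, v)
        reg_slot <- c(reg_slot, 1L)
        tru_true <- c(tru_true, NA_real_); tru_emit <- c(tru_emit, v)
        tru_typo <- c(tru_typo, FALSE); tru_round <- c(tru_round, FALSE)
        tru_under <- c(tru_under, FALSE); tru_phantom <- c(tru_phantom, TRUE)
        tru_sel <- c(tru_sel, FALSE); tru_delay <- c(tru_delay, delay)
      }
    }

    # unprompted test-strip measurements next to an existing measured value
    n_tests <- stats::rpois(1, profile$tests_per_month * n_days / 30)
    if (n_tests > 0 && length(dev_val) > 0) {
      pick <- sample.int(length(dev_val), min(n_tests, length(dev_val)))
      dev_time <- c(dev_time, dev_time[pick] - 900)
      dev_val <- c(dev_val, round(stats::runif(length(pick), 133, 239)))
      dev_test <- c(dev_test,
                    stats::runif(length(pick)) < profile$p_test_flagged)
    }

    dev_rows[[i]] <- tibble::tibble(patient_id = pid, timestamp = dev_time,
                                    value = dev_val, is_test = dev_test)
    smss_rows[[i]] <- tibble::tibble(
      patient_id = pid, measurement_date = reg_mdate,
      registration_date = reg_rdate, value = reg_val,
      slot = reg_slot)
    truth_rows[[i]] <- tibble::tibble(
      patient_id = pid, measurement_date = reg_mdate, slot = reg_slot,
      true_value = tru_true, emitted_value = tru_emit, is_typo = tru_typo,
      is_rounded = tru_round, is_underreport = tru_under,
      is_phantom = tru_phantom, was_selected_low = tru_sel,
      delay_days = tru_delay)
  }

  device <- dplyr::arrange(dplyr::bind_rows(dev_rows),
                           .data$patient_id, .data$timestamp)
  smss <- dplyr::arrange(dplyr::bind_rows(smss_rows), .data$patient_id,
                         .data$registration_date, .data$measurement_date,
                         .data$slot)
  truth <- dplyr::bind_rows(truth_rows)

  feedback <- replay_feedback(smss, policy)
  red <- feedback[!feedback$skipped & feedback$kind == "day_conclusion" &
                    feedback$light == "red", , drop = FALSE]
  set.seed((seed * 524287L + 7L) %% 2147483647L)
  contacts <- tibble::tibble(patient_id = character(),
                             date = as.Date(character()),
                             channel = character())
  if (nrow(red) > 0) {
    sameday <- red$registration_date == red$measurement_date
    p <- ifelse(sameday, profile$p_contact_given_red_sameday,
                profile$p_contact_given_red_delayed)
    hit <- stats::runif(nrow(red)) < p
    if (any(hit)) {
      contacts <- tibble::tibble(
        patient_id = red$patient_id[hit],
        date = red$registration_date[hit],
        channel = sample(c("telephone", "outpatient"), sum(hit),
                         replace = TRUE, prob = c(0.8, 0.2)))
    }
  }
  list(device = device, smss = smss, contacts = contacts, truth = truth,
       starts = starts, feedback = feedback)
}
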