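#' Adherence category for a performed/requested ratio
#'
#' The four categories partition `[0, Inf)`: extremely nonadherent below 25%
#' of requested days, nonadherent from 25% up to (but excluding) 75%,
#' adherent from 75% through 100% inclusive, overadherent strictly above
#' 100%.
#'
#' @param ratio Numeric vector of performed/requested ratios.
#' @return An ordered factor with levels `extremely_nonadherent <
#'   nonadherent < adherent < overadherent`.
#' @export
#' @examples
#' adherence_category(c(0.2, 0.5, 0.75, 1, 1.1))
adherence_category <- function(ratio) {
  if (any(ratio < 0)) stop("ratio must be non-negative", call. = FALSE)
  cut(ratio,
      breaks = c(-Inf, 0.25, 0.75, 1, Inf),
      labels = c("extremely_nonadherent", "nonadherent", "adherent",
                 "overadherent"),
      right = FALSE, ordered_result = TRUE) |>
    (\(f) {
      # [0.75, 1] is closed on both ends: ratio exactly 1 is adherent
      f[ratio == 1] <- "adherent"
      f
    })()
}

#' Score adherence to the measurement (or registration) schedule
#'
#' Counts, per patient and phase, the distinct days with at least one event
#' and compares them with the phase's requested number of measurement days.
#' Multiple events on one day count once.
#'
#' @param events Tibble with `patient_id` and `date` (one row per event; a
#'   device log collapsed to dates or an SMSS log keyed by claimed
#'   measurement date).
#' @param starts Tibble with `patient_id`, `start_date` (day 0 of
#'   monitoring) and optionally `end_date` (last day observed; defaults to
#'   the full schedule horizon). A patient-phase is marked `complete` when
#'   the observation window covers the whole phase.
#' @param schedule A schedule tibble ([default_schedule()]).
#' @param basis Label recorded in the output: `"measured"` or
#'   `"registered"`.
#' @return A tibble with one row per (patient, phase): `performed_days`,
#'   `requested_days`, `ratio`, `category`, `complete`.
#' @export
score_adherence <- function(events, starts, schedule = default_schedule(),
                            basis = c("measured", "registered")) {
  basis <- match.arg(basis)
  if (!all(c("patient_id", "start_date") %in% names(starts))) {
    stop("starts must have patient_id and start_date", call. = FALSE)
  }
  ranges <- phase_day_range(schedule)
  horizon <- max(ranges$day_end)
  if (!"end_date" %in% names(starts)) {
    starts$end_date <- starts$start_date + horizon
  }
  missing_start <- setdiff(unique(events$patient_id), starts$patient_id)
  if (length(missing_start) > 0) {
    stop("no start date for patient(s): ",
         paste(missing_start, collapse = ", "), call. = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(starts))) {
    pid <- starts$patient_id[i]
    start <- starts$start_date[i]
    end <- starts$end_date[i]
    di <- as.numeric(unique(events$date[events$patient_id == pid]) - start)
    di <- di[di >= 0 & di <= horizon]
    for (j in seq_len(nrow(ranges))) {
      performed <- sum(di >= ranges$day_start[j] & di <= ranges$day_end[j])
      requested <- ranges$requested_days[j]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient_id = pid, phase = ranges$phase[j], basis = basis,
        performed_days = performed, requested_days = requested,
        ratio = performed / requested,
        complete = as.numeric(end - start) >= ranges$day_end[j]
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      patient_id = character(), phase = integer(), basis = character(),
      performed_days = integer(), requested_days = integer(),
      ratio = numeric(), complete = logical(),
      category = adherence_category(numeric(0))
    ))
  }
  scores <- dplyr::bind_rows(rows)
  scores$category <- adherence_category(scores$ratio)
  scores
}

#' Cohort-level adherence per phase
#'
#' The fraction of patients scoring adherent or overadherent per phase,
#' counting only patients whose observation window covers the complete phase.
#' Also flags patients who were (extremely) nonadherent during two or more
#' phases.
#'
#' @param scores Output of [score_adherence()].
#' @return A list with `per_phase` (tibble: `phase`, `n_eligible`,
#'   `n_adherent_or_over`, `frac`, `pct` rounded to whole percent) and
#'   `repeat_nonadherent` (patient ids nonadherent in >= 2 phases).
#' @export
cohort_adherence <- function(scores) {
  if (nrow(scores) == 0) {
    return(list(per_phase = tibble::tibble(
      phase = integer(), n_eligible = integer(),
      n_adherent_or_over = integer(), frac = numeric(), pct = numeric()),
      repeat_nonadherent = character()))
  }
  eligible <- scores[scores$complete, , drop = FALSE]
  per_phase <- eligible |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(
      n_eligible = dplyr::n(),
      n_adherent_or_over = sum(.data$category %in%
                                 c("adherent", "overadherent")),
      .groups = "drop"
    ) |>
    dplyr::mutate(frac = .data$n_adherent_or_over / .data$n_eligible,
                  pct = round(100 * .data$frac))
  nonadh <- eligible[eligible$category %in%
                       c("nonadherent", "extremely_nonadherent"), ]
  counts <- table(nonadh$patient_id)
  list(per_phase = per_phase,
       repeat_nonadherent = names(counts)[counts >= 2])
}

#' Registration delay statistics
#'
#' Delay of a registration is the number of whole days between measurement
#' and registration. The measurement date is the patient-claimed date; when
#' the claimed date carries no device value equal to the registered one but a
#' nearby date (within `match_window` days) does, the device date is used
#' instead. Negative computed delays are clamped to zero and counted as a
#' data-quality warning.
#'
#' @param smss SMSS log tibble.
#' @param device Device log tibble (may be `NULL`: claimed dates are then
#'   used as-is).
#' @param match_window Days searched around the claimed date for an
#'   exact-value device match (default 3).
#' @return A list with `per_patient` (tibble: `n`, `mean_delay`,
#'   `always_same_day`, `mean_delay_lt_1`, `mean_delay_gt_3`), `delays`
#'   (per-record tibble), `mean_delay`, `sd_delay`, `max_delay` and
#'   `n_negative_clamped`.
#' @export
delay_stats <- function(smss, device = NULL, match_window = 3L) {
  base_date <- smss$measurement_date
  if (!is.null(device) && nrow(device) > 0) {
    dev <- device[!device$is_test, , drop = FALSE]
    dev_day <- tibble::tibble(patient_id = dev$patient_id,
                              date = as.Date(dev$timestamp),
                              value = dev$value)
    key <- paste(dev_day$patient_id, dev_day$date, dev_day$value)
    for (k in seq_len(nrow(smss))) {
      if (paste(smss$patient_id[k], base_date[k], smss$value[k]) %in% key) next
      cand <- dev_day[dev_day$patient_id == smss$patient_id[k] &
                        dev_day$value == smss$value[k] &
                        abs(as.numeric(dev_day$date - base_date[k])) <=
                          match_window, , drop = FALSE]
      if (nrow(cand) > 0) {
        # nearest matching device date
        base_date[k] <- cand$date[which.min(abs(as.numeric(cand$date -
                                                             base_date[k])))]
      }
    }
  }
  raw <- as.numeric(smss$registration_date - base_date)
  n_negative <- sum(raw < 0)
  delay <- pmax(raw, 0)
  delays <- tibble::tibble(patient_id = smss$patient_id,
                           measurement_date = smss$measurement_date,
                           registration_date = smss$registration_date,
                           delay = delay)
  per_patient <- delays |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_delay = mean(.data$delay),
      always_same_day = all(.data$delay == 0),
      mean_delay_lt_1 = mean(.data$delay) < 1,
      mean_delay_gt_3 = mean(.data$delay) > 3,
      .groups = "drop"
    )
  list(per_patient = per_patient, delays = delays,
       mean_delay = mean(delay),
       sd_delay = if (length(delay) > 1) stats::sd(delay) else NA_real_,
       max_delay = if (length(delay) > 0) max(delay) else NA_real_,
       n_negative_clamped = n_negative)
}

#' Audit adherence to system feedback
#'
#' For every *action feedback* (orange/red after a first registration:
#' repeat the measurement now) the audit checks whether a second value was
#' measured and registered on the same day; failures are attributed to
#' delayed registration (the advice was stale when shown) or to the patient
#' having pre-measured several values already. For orange *day conclusions*
#' (measure again tomorrow) it checks for a registration the next day. For
#' red day conclusions (contact the hospital) it searches the contact log
#' within `contact_window` days of the registration, and additionally reports
#' follow-up restricted to same-day registrations.
#'
#' @param feedback Replayed feedback from [replay_feedback()].
#' @param device Device log tibble.
#' @param smss SMSS log tibble.
#' @param contacts Contact log tibble (`patient_id`, `date`, `channel`) or
#'   `NULL`; without it hospital-contact adherence is reported as not
#'   evaluable, not as zero.
#' @param contact_window Calendar days (starting at the registration date)
#'   within which a contact counts as following the advice (default 2: same
#'   day or next day).
#' @return A list of class `feedback_audit` with components `action`,
#'   `tomorrow` and `hospital`.
#' @export
audit_feedback_adherence <- function(feedback, device, smss, contacts = NULL,
                                     contact_window = 2L) {
  fb <- feedback[!feedback$skipped, , drop = FALSE]
  dev <- device[!device$is_test, , drop = FALSE]
  dev_day <- tibble::tibble(patient_id = dev$patient_id,
                            date = as.Date(dev$timestamp),
                            timestamp = dev$timestamp)
  reg_day_key <- paste(smss$patient_id, smss$measurement_date)

  # --- action feedback: repeat the measurement now -------------------------
  act <- fb[fb$kind == "action_feedback", , drop = FALSE]
  n_act <- nrow(act)
  followed <- delayed <- premeasured <- logical(n_act)
  for (k in seq_len(n_act)) {
    pid <- act$patient_id[k]; d <- act$measurement_date[k]
    second <- smss[smss$patient_id == pid & smss$measurement_date == d &
                     smss$slot > act$slot[k], , drop = FALSE]
    n_meas_day <- sum(dev_day$patient_id == pid & dev_day$date == d)
    followed[k] <- nrow(second) > 0 &&
      any(second$registration_date == d) && n_meas_day >= 2
    if (!followed[k]) {
      if (act$registration_date[k] != d) {
        delayed[k] <- TRUE
      } else if (n_meas_day >= 2) {
        premeasured[k] <- TRUE
      }
    }
  }
  action <- list(total = n_act, followed = sum(followed),
                 delayed_registration = sum(delayed),
                 premeasured = sum(premeasured),
                 other = n_act - sum(followed) - sum(delayed) -
                   sum(premeasured),
                 frac_followed = if (n_act > 0) mean(followed) else NA_real_)

  # --- orange day conclusion: measure again tomorrow -----------------------
  tom <- fb[fb$kind == "day_conclusion" & fb$light == "orange", , drop = FALSE]
  n_tom <- nrow(tom)
  t_followed <- t_delayed <- t_measured_only <- logical(n_tom)
  for (k in seq_len(n_tom)) {
    pid <- tom$patient_id[k]; d <- tom$measurement_date[k]
    t_followed[k] <- paste(pid, d + 1) %in% reg_day_key
    if (!t_followed[k]) {
      if (tom$registration_date[k] != d) {
        t_delayed[k] <- TRUE
      } else if (any(dev_day$patient_id == pid & dev_day$date == d + 1)) {
        t_measured_only[k] <- TRUE
      }
    }
  }
  tomorrow <- list(total = n_tom, followed = sum(t_followed),
                   delayed_registration = sum(t_delayed),
                   measured_not_registered = sum(t_measured_only),
                   other = n_tom - sum(t_followed) - sum(t_delayed) -
                     sum(t_measured_only),
                   frac_followed = if (n_tom > 0) mean(t_followed) else NA_real_)

  # --- red day conclusion: contact the hospital ----------------------------
  red <- fb[fb$kind == "day_conclusion" & fb$light == "red", , drop = FALSE]
  n_red <- nrow(red)
  if (is.null(contacts)) {
    hospital <- list(total = n_red, evaluable = FALSE, contacted = NA_integer_,
                     delayed_no_contact = NA_integer_, other = NA_integer_,
                     frac_contacted = NA_real_,
                     sameday_total = NA_integer_,
                     sameday_contacted = NA_integer_,
                     sameday_frac = NA_real_)
  } else {
    contacted <- h_delayed <- logical(n_red)
    sameday <- red$registration_date == red$measurement_date
    for (k in seq_len(n_red)) {
      pid <- red$patient_id[k]; rd <- red$registration_date[k]
      contacted[k] <- any(contacts$patient_id == pid &
                            contacts$date >= rd &
                            contacts$date <= rd + contact_window - 1L)
      if (!contacted[k] && !sameday[k]) h_delayed[k] <- TRUE
    }
    hospital <- list(
      total = n_red, evaluable = TRUE, contacted = sum(contacted),
      delayed_no_contact = sum(h_delayed),
      other = n_red - sum(contacted) - sum(h_delayed),
      frac_contacted = if (n_red > 0) mean(contacted) else NA_real_,
      sameday_total = sum(sameday),
      sameday_contacted = sum(contacted & sameday),
      sameday_frac = if (sum(sameday) > 0) {
        sum(contacted & sameday) / sum(sameday)
      } else NA_real_
    )
  }
  structure(list(action = action, tomorrow = tomorrow, hospital = hospital),
            class = "feedback_audit")
}

#' @export
print.feedback_audit <- function(x, ...) {
  cat("Adherence to system feedback\n")
  cat(sprintf("  action feedback: %d cases, %d followed (%.0f%%), %d delayed registration, %d premeasured\n",
              x$action$total, x$action$followed,
              100 * x$action$frac_followed, x$action$delayed_registration,
              x$action$premeasured))
  cat(sprintf("  measure again tomorrow: %d cases, %d followed (%.0f%%)\n",
              x$tomorrow$total, x$tomorrow$followed,
              100 * x$tomorrow$frac_followed))
  if (isTRUE(x$hospital$evaluable)) {
    cat(sprintf("  contact hospital: %d cases, %d contacted (%.0f%%); same-day subset %d/%d\n",
                x$hospital$total, x$hospital$contacted,
                100 * x$hospital$frac_contacted,
                x$hospital$sameday_contacted, x$hospital$sameday_total))
  } else {
    cat(sprintf("  contact hospital: %d cases, not evaluable (no contact log)\n",
                x$hospital$total))
  }
  invisible(x)
}
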