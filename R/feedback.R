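#' Rolling baseline for feedback classification
#'
#' The mean of the last `baseline_window` previously registered values; when
#' fewer are available, the mean of all available values (the system starts up
#' gently while history accumulates).
#'
#' @param history Numeric vector of previously registered creatinine values,
#'   oldest first (µmol/l).
#' @param policy A [feedback_policy()].
#' @return The baseline mean in µmol/l.
#' @export
#' @examples
#' fb_baseline(c(90, 95, 100, 105, 110, 200))  # mean of last five = 122
fb_baseline <- function(history, policy = feedback_policy()) {
  if (length(history) == 0) {
    stop("no baseline: history is empty", call. = FALSE)
  }
  window <- min(length(history), policy$baseline_window)
  mean(utils::tail(history, window))
}

severity_of <- function(value, baseline, policy) {
  r <- value / baseline - 1
  if (r > policy$red_threshold) "red"
  else if (r > policy$orange_threshold) "orange"
  else "green"
}

feedback_result <- function(light, kind, advice) {
  list(light = light, kind = kind, advice = advice)
}

#' Classify the first registered value of a day
#'
#' Compares the value against the rolling baseline. Up to +15% the light is
#' green and the day is concluded (advice: continue the regular schedule).
#' Strictly above 15% (orange) or 20% (red) the system emits *action
#' feedback*: perform and register a second measurement right away. With no
#' prior history the result is green/continue.
#'
#' @param value Newly registered creatinine value, µmol/l.
#' @param history Previously registered values, oldest first.
#' @param policy A [feedback_policy()].
#' @param registrations_today Number of values already registered for this
#'   day; must be 0 for a first classification.
#' @return A list with elements `light` (`green`/`orange`/`red`), `kind`
#'   (`day_conclusion`/`action_feedback`) and `advice`.
#' @export
#' @examples
#' classify_first(116, rep(100, 5))  # orange action feedback
classify_first <- function(value, history, policy = feedback_policy(),
                           registrations_today = 0L) {
  if (registrations_today >= policy$max_registrations_per_day) {
    stop("registration cap reached for this day", call. = FALSE)
  }
  if (registrations_today != 0L) {
    stop("classify_first requires registrations_today = 0", call. = FALSE)
  }
  if (length(history) == 0) {
    return(feedback_result("green", "day_conclusion", "continue"))
  }
  light <- severity_of(value, fb_baseline(history, policy), policy)
  if (light == "green") {
    feedback_result("green", "day_conclusion", "continue")
  } else {
    feedback_result(light, "action_feedback", "repeat_measurement_now")
  }
}

#' Classify the second registered value of a day (the day conclusion)
#'
#' Applies the same threshold bands against the baseline — by default the
#' pre-day baseline, i.e. excluding the day's first value — and maps them to
#' the terminal advice for the day: green/continue, orange/measure again
#' tomorrow, red/contact the hospital.
#'
#' @inheritParams classify_first
#' @param history Previously registered values, oldest first, *excluding*
#'   today's first value (callers using
#'   `include_first_in_second_baseline = TRUE` pass it included).
#' @export
#' @examples
#' classify_second(125, rep(100, 5), registrations_today = 1)  # red: contact hospital
classify_second <- function(value, history, policy = feedback_policy(),
                            registrations_today = 1L) {
  if (registrations_today >= policy$max_registrations_per_day) {
    stop("registration cap reached for this day", call. = FALSE)
  }
  if (registrations_today != 1L) {
    stop("classify_second requires a prior first registration for the day",
         call. = FALSE)
  }
  if (length(history) == 0) {
    return(feedback_result("green", "day_conclusion", "continue"))
  }
  light <- severity_of(value, fb_baseline(history, policy), policy)
  advice <- switch(light,
    green = "continue",
    orange = "measure_again_tomorrow",
    red = "contact_hospital"
  )
  feedback_result(light, "day_conclusion", advice)
}

#' Replay the SMSS feedback engine over a registration log
#'
#' Reconstructs the feedback each registration would have produced, processing
#' records in registration order (feedback is computed when the patient
#' registers, not when they measure — which is what makes delayed registration
#' render the advice stale). Baselines are means over previously registered
#' values; for the second value of a measurement day the day's first value is
#' excluded from the baseline unless the policy says otherwise. Records beyond
#' the per-day cap are flagged `skipped` and excluded from history.
#'
#' @param smss A tibble of SMSS registrations with columns `patient_id`,
#'   `measurement_date`, `registration_date`, `value`, `slot`.
#' @param policy A [feedback_policy()].
#' @return The input rows (in processing order) with `light`, `kind`,
#'   `advice`, `position` (1 or 2 within the measurement day) and `skipped`
#'   columns.
#' @export
replay_feedback <- function(smss, policy = feedback_policy()) {
  cols <- c("patient_id", "measurement_date", "registration_date", "value", "slot")
  stopifnot(all(cols %in% names(smss)))
  if (nrow(smss) == 0) {
    return(tibble::tibble(
      patient_id = character(), measurement_date = as.Date(character()),
      registration_date = as.Date(character()), value = numeric(),
      slot = integer(), position = integer(), light = character(),
      kind = character(), advice = character(), skipped = logical()
    ))
  }
  smss <- dplyr::arrange(smss, .data$patient_id, .data$registration_date,
                         .data$measurement_date, .data$slot)
  out <- vector("list", length(unique(smss$patient_id)))
  i <- 0L
  for (pid in unique(smss$patient_id)) {
    rec <- smss[smss$patient_id == pid, cols]
    n <- nrow(rec)
    history <- numeric(0)
    # index into history of the first value of each measurement date
    first_pos <- new.env(parent = emptyenv())
    day_count <- new.env(parent = emptyenv())
    light <- kind <- advice <- character(n)
    position <- integer(n)
    skipped <- logical(n)
    for (k in seq_len(n)) {
      key <- as.character(rec$measurement_date[k])
      seen <- if (is.null(day_count[[key]])) 0L else day_count[[key]]
      if (seen >= policy$max_registrations_per_day) {
        skipped[k] <- TRUE
        light[k] <- NA_character_; kind[k] <- NA_character_
        advice[k] <- NA_character_; position[k] <- NA_integer_
        next
      }
      position[k] <- seen + 1L
      if (seen == 0L) {
        res <- classify_first(rec$value[k], history, policy)
        first_pos[[key]] <- length(history) + 1L
      } else {
        hist2 <- history
        if (!policy$include_first_in_second_baseline) {
          hist2 <- history[-first_pos[[key]]]
        }
        res <- classify_second(rec$value[k], hist2, policy)
      }
      light[k] <- res$light; kind[k] <- res$kind; advice[k] <- res$advice
      history <- c(history, rec$value[k])
      day_count[[key]] <- seen + 1L
    }
    i <- i + 1L
    out[[i]] <- tibble::tibble(
      rec, position = position, light = light, kind = kind,
      advice = advice, skipped = skipped
    )
  }
  res <- dplyr::bind_rows(out)
  if (any(res$skipped)) {
    warning(sum(res$skipped), " registration(s) beyond the per-day cap of ",
            policy$max_registrations_per_day, " were skipped", call. = FALSE)
  }
  res
}
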