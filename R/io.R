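device_cols <- c("patient_id", "timestamp", "value", "is_test")
smss_cols <- c("patient_id", "measurement_date", "registration_date",
               "value", "slot")
bp_cols <- c("patient_id", "date", "systolic", "diastolic")
contact_cols <- c("patient_id", "date", "channel")

check_header <- function(path, expected) {
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  if (!identical(hdr, expected)) {
    stop("unexpected header in ", path, ": got [",
         paste(hdr, collapse = ","), "], expected [",
         paste(expected, collapse = ","), "]", call. = FALSE)
  }
}

report_problems <- function(x, path) {
  probs <- readr::problems(x)
  if (nrow(probs) > 0) {
    warning(nrow(probs), " malformed row(s) rejected in ", path,
            " (rows ", paste(utils::head(probs$row, 5), collapse = ", "),
            if (nrow(probs) > 5) ", ..." else "", ")", call. = FALSE)
  }
  probs
}

value_range_warnings <- function(values, what) {
  bad <- which(!is.na(values) & (values < 20 | values > 1500))
  if (length(bad) > 0) {
    warning(length(bad), " ", what,
            " value(s) outside the plausible 20-1500 µmol/l range",
            call. = FALSE)
  }
  bad
}

#' Read a device log
#'
#' CSV with header `patient_id,timestamp,value,is_test` and ISO-8601
#' timestamps. Malformed rows are reported with their line numbers (never
#' silently dropped); creatinine values outside 20-1500 µmol/l raise a
#' warning.
#'
#' @param path File path.
#' @return A tibble sorted by patient and timestamp, with attributes
#'   `problems` (rejected-row diagnostics) and `value_warnings`.
#' @export
read_device_log <- function(path) {
  check_header(path, device_cols)
  x <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    timestamp = readr::col_datetime(),
    value = readr::col_double(),
    is_test = readr::col_logical()
  ))
  probs <- report_problems(x, path)
  bad <- value_range_warnings(x$value, "device")
  x <- dplyr::arrange(x, .data$patient_id, .data$timestamp)
  attr(x, "problems") <- probs
  attr(x, "value_warnings") <- bad
  x
}

#' Read an SMSS registration log
#'
#' CSV with header `patient_id,measurement_date,registration_date,value,slot`.
#' A slot outside {1, 2} or a duplicate (patient, measurement date, slot) is
#' a hard error; malformed rows and implausible values are reported.
#'
#' @param path File path.
#' @return A tibble sorted by patient, registration date, measurement date
#'   and slot.
#' @export
read_smss_log <- function(path) {
  check_header(path, smss_cols)
  x <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    measurement_date = readr::col_date(),
    registration_date = readr::col_date(),
    value = readr::col_double(),
    slot = readr::col_integer()
  ))
  probs <- report_problems(x, path)
  bad_slot <- which(!x$slot %in% c(1L, 2L))
  if (length(bad_slot) > 0) {
    stop("slot outside {1,2} in ", path, " (data row ",
         paste(utils::head(bad_slot, 5), collapse = ", "), ")", call. = FALSE)
  }
  key <- paste(x$patient_id, x$measurement_date, x$slot)
  if (anyDuplicated(key) > 0) {
    stop("duplicate (patient, measurement_date, slot) in ", path,
         " (data row ", which(duplicated(key))[1], ")", call. = FALSE)
  }
  bad <- value_range_warnings(x$value, "registered")
  x <- dplyr::arrange(x, .data$patient_id, .data$registration_date,
                      .data$measurement_date, .data$slot)
  attr(x, "problems") <- probs
  attr(x, "value_warnings") <- bad
  x
}

#' Read a blood-pressure log
#'
#' CSV with header `patient_id,date,systolic,diastolic`; requires
#' `systolic >= diastolic > 0`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_bp_log <- function(path) {
  check_header(path, bp_cols)
  x <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    date = readr::col_date(),
    systolic = readr::col_double(),
    diastolic = readr::col_double()
  ))
  report_problems(x, path)
  if (any(x$diastolic <= 0 | x$systolic < x$diastolic, na.rm = TRUE)) {
    stop("invalid blood pressures (need systolic >= diastolic > 0) in ",
         path, call. = FALSE)
  }
  dplyr::arrange(x, .data$patient_id, .data$date)
}

#' Read a hospital-contact log
#'
#' CSV with header `patient_id,date,channel`; channel is `telephone` or
#' `outpatient`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_contact_log <- function(path) {
  check_header(path, contact_cols)
  x <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    date = readr::col_date(),
    channel = readr::col_character()
  ))
  report_problems(x, path)
  bad <- which(!x$channel %in% c("telephone", "outpatient"))
  if (length(bad) > 0) {
    stop("unknown contact channel in ", path, " (data row ", bad[1], ")",
         call. = FALSE)
  }
  dplyr::arrange(x, .data$patient_id, .data$date)
}

#' Write interchange logs
#'
#' Plain-CSV writers matching the reader schemas, so that writing then
#' reading reproduces the records exactly.
#'
#' @param x Tibble to write.
#' @param path Destination.
#' @name log_writers
NULL

#' @rdname log_writers
#' @export
write_device_log <- function(x, path) {
  readr::write_csv(x[, device_cols], path)
  invisible(path)
}

#' @rdname log_writers
#' @export
write_smss_log <- function(x, path) {
  readr::write_csv(x[, smss_cols], path)
  invisible(path)
}

#' @rdname log_writers
#' @export
write_contact_log <- function(x, path) {
  readr::write_csv(x[, contact_cols], path)
  invisible(path)
}

#' Read policy configuration from YAML
#'
#' Recognised top-level keys: `feedback` (fields of [feedback_policy()]),
#' `test_strip` ([test_strip_policy()]), `reconcile`
#' ([reconcile_params()]). Missing keys fall back to defaults.
#'
#' @param path YAML file.
#' @return A list with elements `feedback`, `test_strip`, `reconcile`.
#' @export
read_policy_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(
    feedback = do.call(feedback_policy, cfg$feedback %||% list()),
    test_strip = do.call(test_strip_policy, cfg$test_strip %||% list()),
    reconcile = do.call(reconcile_params, cfg$reconcile %||% list())
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full audit pipeline
#'
#' Orchestrates the end-to-end analysis: test-value filtering, feedback
#' replay, day reconciliation and reliability summary (with and without the
#' candidate test values), adherence scoring on the measured and the
#' registered basis, registration-delay statistics, and the
#' feedback-adherence audit. Deterministic given inputs and configuration.
#'
#' @param device,smss Parsed logs (tibbles) or file paths.
#' @param contacts Contact log, path, or `NULL` (hospital-contact adherence
#'   then reported as not evaluable).
#' @param starts Tibble of `patient_id`, `start_date`, optional `end_date`.
#'   When `NULL`, each patient's first device day is used as day 0 and the
#'   last activity day as the end of observation.
#' @param schedule,policy,test_policy,params Configuration objects; defaults
#'   as documented in their constructors.
#' @param exclude_patients Character vector of patient ids dropped from all
#'   logs before analysis (cohort filter, e.g. hospitalized patients).
#' @param out_dir If non-`NULL`, writes `report.json`, `days.csv`,
#'   `adherence.csv` and `summary.txt` there.
#' @return A list of class `smss_report`.
#' @export
run_pipeline <- function(device, smss, contacts = NULL, starts = NULL,
                         schedule = default_schedule(),
                         policy = feedback_policy(),
                         test_policy = test_strip_policy(),
                         params = reconcile_params(),
                         exclude_patients = character(),
                         out_dir = NULL) {
  if (is.character(device)) device <- read_device_log(device)
  if (is.character(smss)) smss <- read_smss_log(smss)
  if (is.character(contacts)) contacts <- read_contact_log(contacts)
  if (length(exclude_patients) > 0) {
    device <- device[!device$patient_id %in% exclude_patients, ]
    smss <- smss[!smss$patient_id %in% exclude_patients, ]
    if (!is.null(contacts)) {
      contacts <- contacts[!contacts$patient_id %in% exclude_patients, ]
    }
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  tests <- stage("filter_test_values",
                 filter_test_values(device, smss, test_policy))
  feedback <- stage("replay_feedback", replay_feedback(smss, policy))
  reliability <- stage("summarize_reliability",
                       summarize_reliability(tests$device, smss, params))
  reliability_no_candidates <- stage(
    "summarize_reliability (candidates excluded)",
    summarize_reliability(tests$device, smss, params, drop_candidates = TRUE))

  if (is.null(starts)) {
    starts <- tests$device |>
      dplyr::mutate(date = as.Date(.data$timestamp)) |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::summarise(start_date = min(.data$date),
                       end_date = max(.data$date), .groups = "drop")
  }
  dev_events <- tibble::tibble(patient_id = tests$device$patient_id,
                               date = as.Date(tests$device$timestamp))
  reg_events <- tibble::tibble(patient_id = smss$patient_id,
                               date = smss$measurement_date)
  adh_measured <- stage("score_adherence (measured)",
                        score_adherence(dev_events, starts, schedule,
                                        basis = "measured"))
  adh_registered <- stage("score_adherence (registered)",
                          score_adherence(reg_events, starts, schedule,
                                          basis = "registered"))
  cohort_measured <- cohort_adherence(adh_measured)
  cohort_registered <- cohort_adherence(adh_registered)
  delays <- stage("delay_stats",
                  delay_stats(smss, tests$device, params$date_shift_window))
  audit <- stage("audit_feedback_adherence",
                 audit_feedback_adherence(feedback, tests$device, smss,
                                          contacts))

  report <- structure(list(
    tests = list(n_flagged = nrow(tests$test_flagged),
                 n_candidates = nrow(tests$candidates)),
    feedback = feedback,
    reliability = reliability,
    reliability_no_candidates = reliability_no_candidates,
    adherence = list(measured = adh_measured, registered = adh_registered),
    cohort_adherence = list(measured = cohort_measured,
                            registered = cohort_registered),
    delays = delays,
    audit = audit,
    starts = starts
  ), class = "smss_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# JSON-serializable view of the report (counts, fractions and comparisons;
# no raw per-record tables). Floats kept at 6 significant digits for
# readable diffs.
report_json <- function(report) {
  comp <- lapply(report$reliability$comparisons, function(x) {
    if (is.null(x)) return(NULL)
    x[c("labels", "n", "mean_a", "mean_b", "mean_diff", "t", "df", "p",
        "significant", "zero_variance")]
  })
  rel <- report$reliability
  list(
    tests = report$tests,
    reliability = list(
      totals = rel$totals,
      equal_days = rel$equal_days,
      reliable = rel$reliable,
      noncorresponding = rel$noncorresponding[
        c("n", "frac", "causes", "explained_n", "incorrect_n",
          "incorrect_frac", "median_per_patient", "iqr_per_patient")],
      phantom = rel$phantom,
      omission = rel$omission[c("n_days", "n_values", "median_per_patient",
                                "range_per_patient")],
      selection = rel$selection,
      mixed = rel$mixed,
      unregistered = rel$unregistered
    ),
    comparisons = comp,
    cohort_adherence = list(
      measured = report$cohort_adherence$measured$per_phase,
      registered = report$cohort_adherence$registered$per_phase,
      repeat_nonadherent_measured =
        report$cohort_adherence$measured$repeat_nonadherent,
      repeat_nonadherent_registered =
        report$cohort_adherence$registered$repeat_nonadherent
    ),
    delays = report$delays[c("mean_delay", "sd_delay", "max_delay",
                             "n_negative_clamped")],
    audit = unclass(report$audit)
  )
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_json(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 6, null = "null",
                       pretty = TRUE)
  days <- report$reliability$days
  readr::write_csv(tibble::tibble(
    patient_id = days$patient_id,
    date = days$date,
    category = days$category,
    n_measured = days$n_measured,
    n_registered = days$n_registered,
    measured_values = vapply(days$measured, paste, character(1),
                             collapse = ";"),
    registered_values = vapply(days$registered, paste, character(1),
                               collapse = ";")
  ), file.path(out_dir, "days.csv"))
  readr::write_csv(dplyr::bind_rows(report$adherence$measured,
                                    report$adherence$registered),
                   file.path(out_dir, "adherence.csv"))
  con <- file(file.path(out_dir, "summary.txt"), "w")
  sink(con)
  print(report$reliability)
  print(report$audit)
  sink()
  close(con)
  invisible(out_dir)
}
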