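#' Build per patient-day buckets of measured and registered values
#'
#' Device and SMSS logs are joined on the calendar day: device values by the
#' date of the device timestamp, SMSS values by the measurement date the
#' patient claimed. Test-flagged device values (and, when present, values
#' marked `candidate_test`) never enter the `measured` side.
#'
#' @param device Device log tibble (`patient_id`, `timestamp`, `value`,
#'   `is_test`, optionally `candidate_test`).
#' @param smss SMSS log tibble (`patient_id`, `measurement_date`,
#'   `registration_date`, `value`, `slot`).
#' @param drop_candidates Also exclude `candidate_test` values from the
#'   measured side (sensitivity re-run).
#' @return A tibble with one row per (patient, date) with any activity and
#'   list-columns `measured` (values sorted by time) and `registered` (values
#'   sorted by slot).
#' @export
build_buckets <- function(device, smss, drop_candidates = FALSE) {
  dev <- device[!device$is_test, , drop = FALSE]
  if (drop_candidates && "candidate_test" %in% names(dev)) {
    dev <- dev[!dev$candidate_test, , drop = FALSE]
  }
  dev_days <- dev |>
    dplyr::mutate(date = as.Date(.data$timestamp)) |>
    dplyr::arrange(.data$patient_id, .data$timestamp) |>
    dplyr::group_by(.data$patient_id, .data$date) |>
    dplyr::summarise(measured = list(.data$value), .groups = "drop")
  smss_days <- smss |>
    dplyr::arrange(.data$patient_id, .data$measurement_date, .data$slot) |>
    dplyr::group_by(.data$patient_id, date = .data$measurement_date) |>
    dplyr::summarise(registered = list(.data$value), .groups = "drop")
  buckets <- dplyr::full_join(dev_days, smss_days,
                              by = c("patient_id", "date"))
  buckets$measured <- lapply(buckets$measured, function(x) if (is.null(x)) numeric(0) else x)
  buckets$registered <- lapply(buckets$registered, function(x) if (is.null(x)) numeric(0) else x)
  dplyr::arrange(buckets, .data$patient_id, .data$date)
}

# Pair registered values to measured values by closeness (exact matches take
# priority through the min-|diff| rule; ties resolved to the earlier
# measurement). Used on selection days where in-order pairing is undefined.
pair_by_value <- function(measured, registered) {
  m_idx <- integer(length(registered))
  free <- rep(TRUE, length(measured))
  for (j in seq_along(registered)) {
    d <- abs(measured - registered[j])
    d[!free] <- Inf
    k <- which.min(d)
    m_idx[j] <- k
    free[k] <- FALSE
  }
  m_idx
}

#' Classify one patient-day bucket
#'
#' Implements the reliability/representativeness taxonomy:
#' \describe{
#'   \item{reliable}{equal counts and every value identical in order}
#'   \item{noncorresponding}{equal counts, at least one value differs}
#'   \item{phantom}{values registered on a day with no measurement}
#'   \item{omission}{measurements performed but nothing registered}
#'   \item{selection}{fewer values registered than measured}
#'   \item{mixed}{more registered than measured (both nonzero): the matched
#'     prefix is compared in order and surplus registrations are flagged
#'     separately so headline phantom counts keep the strict no-measurement
#'     definition}
#' }
#'
#' @param measured Numeric vector of the day's device values (time order).
#' @param registered Numeric vector of the day's registered values (slot
#'   order).
#' @param value_tol Equality tolerance, µmol/l (default 0).
#' @return A list with `category`, a `pairs` tibble (`measured`,
#'   `registered`, `match` logical), `unregistered` (measured values with no
#'   registration) and `surplus_registered` (mixed-day registrations beyond
#'   the measured count).
#' @export
classify_day <- function(measured, registered, value_tol = 0) {
  n_m <- length(measured)
  n_r <- length(registered)
  if (n_m == 0 && n_r == 0) {
    stop("empty bucket: no measured and no registered values", call. = FALSE)
  }
  pairs <- tibble::new_tibble(list(measured = numeric(0),
                                   registered = numeric(0),
                                   match = logical(0)), nrow = 0L)
  unregistered <- numeric(0)
  surplus <- numeric(0)
  make_pairs <- function(m, r) {
    tibble::new_tibble(list(measured = m, registered = r,
                            match = values_equal(m, r, value_tol)),
                       nrow = length(m))
  }
  if (n_m == n_r) {
    pairs <- make_pairs(measured, registered)
    category <- if (all(pairs$match)) "reliable" else "noncorresponding"
  } else if (n_m == 0) {
    category <- "phantom"
    surplus <- registered
  } else if (n_r == 0) {
    category <- "omission"
    unregistered <- measured
  } else if (n_m > n_r) {
    category <- "selection"
    idx <- pair_by_value(measured, registered)
    pairs <- make_pairs(measured[idx], registered)
    unregistered <- measured[-idx]
  } else {
    category <- "mixed"
    k <- n_m
    pairs <- make_pairs(measured, registered[seq_len(k)])
    surplus <- registered[-seq_len(k)]
  }
  list(category = category, pairs = pairs, unregistered = unregistered,
       surplus_registered = surplus)
}

#' Classify all buckets
#'
#' @param buckets Output of [build_buckets()].
#' @param params A [reconcile_params()].
#' @return The buckets with `n_measured`, `n_registered`, `category` and
#'   list-columns `pairs`, `unregistered`, `surplus_registered`.
#' @export
classify_days <- function(buckets, params = reconcile_params()) {
  cls <- Map(classify_day, buckets$measured, buckets$registered,
             MoreArgs = list(value_tol = params$value_tol))
  buckets$n_measured <- lengths(buckets$measured)
  buckets$n_registered <- lengths(buckets$registered)
  buckets$category <- vapply(cls, `[[`, character(1), "category")
  buckets$pairs <- lapply(cls, `[[`, "pairs")
  buckets$unregistered <- lapply(cls, `[[`, "unregistered")
  buckets$surplus_registered <- lapply(cls, `[[`, "surplus_registered")
  buckets
}

# Damerau-Levenshtein distance 1 on the decimal strings: one substitution,
# one adjacent transposition, or one dropped/added digit.
is_typo_pair <- function(a, b) {
  sa <- strsplit(format(a, scientific = FALSE, trim = TRUE), "")[[1]]
  sb <- strsplit(format(b, scientific = FALSE, trim = TRUE), "")[[1]]
  la <- length(sa); lb <- length(sb)
  if (identical(sa, sb)) return(FALSE)
  if (la == lb) {
    diff <- which(sa != sb)
    if (length(diff) == 1) return(TRUE)                      # substitution
    if (length(diff) == 2 && diff[2] == diff[1] + 1 &&
        sa[diff[1]] == sb[diff[2]] && sa[diff[2]] == sb[diff[1]]) {
      return(TRUE)                                           # transposition
    }
    return(FALSE)
  }
  if (abs(la - lb) == 1) {                                   # drop/add digit
    long <- if (la > lb) sa else sb
    short <- if (la > lb) sb else sa
    for (i in seq_along(long)) {
      if (identical(long[-i], short)) return(TRUE)
    }
  }
  FALSE
}

#' Attribute a cause to a noncorresponding registration
#'
#' Mirrors the manual review of mismatches: a wrong date/value combination
#' (the registered value exactly matches a device value on a nearby date that
#' itself has no matching registration), a typo (single-character edit or
#' adjacent transposition of the digits), or rounding (difference within
#' `rounding_tol` and the registered value a multiple of 5). Precedence:
#' date_shift > rounding > typo (a small difference landing on a multiple of
#' 5 reads as rounding even though it is also one edit away); anything else
#' is `unexplained` — these are the incorrect entries.
#'
#' @param measured_value,registered_value The differing pair, µmol/l.
#' @param neighbor_values Device values on dates within the date-shift window
#'   that have no matching registration of their own.
#' @param params A [reconcile_params()].
#' @return One of `"date_shift"`, `"typo"`, `"rounding"`, `"unexplained"`.
#' @export
#' @examples
#' attribute_cause(137, 135, numeric(0))  # rounding
#' attribute_cause(137, 173, numeric(0))  # typo (transposed digits)
attribute_cause <- function(measured_value, registered_value,
                            neighbor_values = numeric(0),
                            params = reconcile_params()) {
  if (values_equal(measured_value, registered_value, params$value_tol)) {
    stop("attribute_cause requires differing values", call. = FALSE)
  }
  if (length(neighbor_values) > 0 &&
      any(values_equal(neighbor_values, registered_value, params$value_tol))) {
    return("date_shift")
  }
  if (abs(measured_value - registered_value) <= params$rounding_tol &&
      registered_value %% 5 == 0) {
    return("rounding")
  }
  if (is_typo_pair(measured_value, registered_value)) {
    return("typo")
  }
  "unexplained"
}

# Device values on nearby dates lacking their own matching registration, per
# patient; used as the date-shift candidate pool.
unmatched_device_values <- function(device_day_tbl, smss, params) {
  reg_keys <- paste(smss$patient_id, smss$measurement_date, smss$value)
  has_match <- paste(device_day_tbl$patient_id, device_day_tbl$date,
                     device_day_tbl$value) %in% reg_keys
  device_day_tbl[!has_match, , drop = FALSE]
}

#' Attribute causes for every noncorresponding pair in classified days
#'
#' @param days Output of [classify_days()].
#' @param device Device log (test values included or not — only non-test rows
#'   are used).
#' @param smss SMSS log.
#' @param params A [reconcile_params()].
#' @return A tibble of noncorresponding pairs with columns `patient_id`,
#'   `date`, `measured`, `registered`, `cause`, including mismatching pairs on
#'   selection and mixed days (flagged by `day_category`).
#' @export
attribute_causes <- function(days, device, smss, params = reconcile_params()) {
  dev <- device[!device$is_test, , drop = FALSE]
  dev_day <- tibble::tibble(
    patient_id = dev$patient_id,
    date = as.Date(dev$timestamp),
    value = dev$value
  )
  pool <- unmatched_device_values(dev_day, smss, params)
  rows <- list()
  for (i in seq_len(nrow(days))) {
    pr <- days$pairs[[i]]
    if (nrow(pr) == 0 || all(pr$match)) next
    bad <- pr[!pr$match, , drop = FALSE]
    pid <- days$patient_id[i]
    d <- days$date[i]
    nb <- pool$value[pool$patient_id == pid &
                       pool$date != d &
                       abs(as.numeric(pool$date - d)) <= params$date_shift_window]
    cause <- vapply(seq_len(nrow(bad)), function(j) {
      attribute_cause(bad$measured[j], bad$registered[j], nb, params)
    }, character(1))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      patient_id = pid, date = d, day_category = days$category[i],
      measured = bad$measured, registered = bad$registered, cause = cause
    )
  }
  if (length(rows) == 0) {
    return(tibble::tibble(patient_id = character(), date = as.Date(character()),
                          day_category = character(), measured = numeric(),
                          registered = numeric(), cause = character()))
  }
  dplyr::bind_rows(rows)
}

#' Identify test-strip values in the device log
#'
#' Values flagged as test measurements on the device are always excluded from
#' analysis. Unflagged values are marked *candidate* test values when all four
#' criteria hold: (1) the value was not registered in the SMSS on that date,
#' (2) it differs from both temporal neighbours by more than
#' `policy$neighbor_diff`, (3) it lies within the manufacturer's test range,
#' and (4) another device value measured within `policy$neighbor_window_mins`
#' minutes on the same day was registered in the SMSS that day. Analyses are
#' meant to be run with and without the candidates excluded.
#'
#' @param device Device log tibble.
#' @param smss SMSS log tibble.
#' @param policy A [test_strip_policy()].
#' @return A list: `device` (non-test rows with a `candidate_test` column),
#'   `test_flagged` (rows flagged on the device), `candidates` (the candidate
#'   rows).
#' @export
filter_test_values <- function(device, smss, policy = test_strip_policy()) {
  dev <- dplyr::arrange(device, .data$patient_id, .data$timestamp)
  flagged <- dev[dev$is_test, , drop = FALSE]
  dev <- dev[!dev$is_test, , drop = FALSE]
  if (nrow(dev) == 0) {
    dev$candidate_test <- logical(0)
    return(list(device = dev, test_flagged = flagged, candidates = dev))
  }
  dev$date <- as.Date(dev$timestamp)
  reg_key <- paste(smss$patient_id, smss$measurement_date, smss$value)
  candidate <- logical(nrow(dev))
  for (pid in unique(dev$patient_id)) {
    sel <- which(dev$patient_id == pid)
    v <- dev$value[sel]
    ts <- dev$timestamp[sel]
    dt <- dev$date[sel]
    prev_ok <- c(TRUE, abs(diff(v)) > policy$neighbor_diff)
    next_ok <- c(abs(diff(v)) > policy$neighbor_diff, TRUE)
    for (j in seq_along(sel)) {
      val <- v[j]
      if (val < policy$value_range[1] || val > policy$value_range[2]) next
      if (!prev_ok[j] || !next_ok[j]) next
      if (paste(pid, dt[j], val) %in% reg_key) next
      same_day <- which(dt == dt[j] & seq_along(sel) != j)
      close <- same_day[abs(as.numeric(difftime(ts[same_day], ts[j],
                                                units = "mins"))) <=
                          policy$neighbor_window_mins]
      if (length(close) == 0) next
      if (any(paste(pid, dt[close], v[close]) %in% reg_key)) {
        candidate[sel[j]] <- TRUE
      }
    }
  }
  dev$candidate_test <- candidate
  dev$date <- NULL
  list(device = dev, test_flagged = flagged,
       candidates = dev[candidate, , drop = FALSE])
}

#' Summarise reliability and representativeness of a registration log
#'
#' Runs bucket construction, day classification and cause attribution, and
#' assembles the headline bookkeeping: the equal-count comparison (reliable
#' vs noncorresponding, with the explained/incorrect split), phantom values,
#' omissions, selection of measurements, the unregistered total, per-patient
#' summaries, and the paired-mean comparisons.
#'
#' @param device Device log (run through [filter_test_values()] first if
#'   unflagged test values should be marked).
#' @param smss SMSS log.
#' @param params A [reconcile_params()].
#' @param drop_candidates Exclude `candidate_test` values from the measured
#'   side.
#' @return A list of class `reliability_summary`.
#' @export
summarize_reliability <- function(device, smss, params = reconcile_params(),
                                  drop_candidates = FALSE) {
  buckets <- build_buckets(device, smss, drop_candidates = drop_candidates)
  days <- classify_days(buckets, params)
  causes <- attribute_causes(days, device, smss, params)

  eq <- days[days$category %in% c("reliable", "noncorresponding"), ]
  n_eq <- sum(eq$n_registered)
  reliable_n <- sum(vapply(eq$pairs, function(p) sum(p$match), numeric(1)))
  noncorr_n <- n_eq - reliable_n

  eq_causes <- causes[causes$day_category %in% c("reliable", "noncorresponding"), ]
  cause_counts <- table(factor(eq_causes$cause,
                               levels = c("date_shift", "typo", "rounding",
                                          "unexplained")))
  incorrect_n <- as.integer(cause_counts[["unexplained"]])

  phantom_days <- days[days$category == "phantom", ]
  phantom_n <- sum(phantom_days$n_registered)
  omission_days <- days[days$category == "omission", ]
  omitted_n <- sum(omission_days$n_measured)
  selection_days <- days[days$category == "selection", ]
  selection_unreg_n <- sum(selection_days$n_measured - selection_days$n_registered)
  mixed_days <- days[days$category == "mixed", ]
  mixed_surplus_n <- sum(lengths(mixed_days$surplus_registered))

  n_registered <- nrow(smss)
  dev_used <- device[!device$is_test, , drop = FALSE]
  if (drop_candidates && "candidate_test" %in% names(dev_used)) {
    dev_used <- dev_used[!dev_used$candidate_test, , drop = FALSE]
  }
  n_measured <- nrow(dev_used)
  unregistered_n <- omitted_n + selection_unreg_n

  # per-patient noncorrespondence (equal-count days, strict comparison)
  patients <- sort(unique(c(device$patient_id, smss$patient_id)))
  per_pat_noncorr <- vapply(patients, function(p) {
    sum(vapply(eq$pairs[eq$patient_id == p],
               function(pr) sum(!pr$match), numeric(1)))
  }, numeric(1))
  per_pat_omissions <- vapply(patients, function(p) {
    sum(omission_days$n_measured[omission_days$patient_id == p])
  }, numeric(1))

  comparisons <- reliability_comparisons(days, causes, patients)

  structure(list(
    totals = list(n_registered = n_registered, n_measured = n_measured,
                  n_patients = length(patients)),
    equal_days = list(n_days = nrow(eq), n_registrations = n_eq),
    reliable = list(n = reliable_n,
                    frac = if (n_eq > 0) reliable_n / n_eq else NA_real_),
    noncorresponding = list(
      n = noncorr_n,
      frac = if (n_eq > 0) noncorr_n / n_eq else NA_real_,
      causes = as.list(cause_counts),
      explained_n = noncorr_n - incorrect_n,
      incorrect_n = incorrect_n,
      incorrect_frac = if (n_eq > 0) incorrect_n / n_eq else NA_real_,
      per_patient = tibble::tibble(patient_id = patients, n = per_pat_noncorr),
      median_per_patient = stats::median(per_pat_noncorr),
      iqr_per_patient = stats::IQR(per_pat_noncorr, type = 2)
    ),
    phantom = list(
      n = phantom_n,
      frac_of_registered = if (n_registered > 0) phantom_n / n_registered else NA_real_,
      n_patients_with_any = sum(vapply(patients, function(p) {
        any(phantom_days$patient_id == p)
      }, logical(1)))
    ),
    omission = list(
      n_days = nrow(omission_days), n_values = omitted_n,
      per_patient = tibble::tibble(patient_id = patients, n = per_pat_omissions),
      median_per_patient = stats::median(per_pat_omissions),
      range_per_patient = range(per_pat_omissions)
    ),
    selection = list(n_days = nrow(selection_days),
                     n_unregistered = selection_unreg_n),
    mixed = list(n_days = nrow(mixed_days), surplus_n = mixed_surplus_n),
    unregistered = list(
      n = unregistered_n,
      frac_of_measured = if (n_measured > 0) unregistered_n / n_measured else NA_real_
    ),
    comparisons = comparisons,
    days = days,
    causes = causes
  ), class = "reliability_summary")
}

# Paired-mean comparisons mirroring the published analyses. Returns NULL for
# a comparison whenever fewer than two pairs exist.
reliability_comparisons <- function(days, causes, patients) {
  safe_t <- function(a, b, labels) {
    if (length(a) < 2) return(NULL)
    paired_t(a, b, labels = labels)
  }
  eq_causes <- causes[causes$day_category %in%
                        c("reliable", "noncorresponding"), , drop = FALSE]
  incorrect <- eq_causes[eq_causes$cause == "unexplained", , drop = FALSE]

  # measured values matched to a registration anywhere (for the omission
  # comparison's "measured and registered" side)
  matched_measured <- function(p) {
    unlist(lapply(days$pairs[days$patient_id == p], function(pr) pr$measured))
  }
  phantom_vals <- function(p) {
    unlist(days$surplus_registered[days$patient_id == p &
                                     days$category == "phantom"])
  }
  all_measured <- function(p) {
    unlist(days$measured[days$patient_id == p])
  }
  omission_vals <- function(p) {
    unlist(days$unregistered[days$patient_id == p &
                               days$category == "omission"])
  }
  sel_matched <- function(p) {
    unlist(lapply(days$pairs[days$patient_id == p &
                               days$category == "selection"],
                  function(pr) pr$measured))
  }
  sel_unreg <- function(p) {
    unlist(days$unregistered[days$patient_id == p &
                               days$category == "selection"])
  }

  per_patient_pairs <- function(f_a, f_b) {
    a <- b <- numeric(0)
    for (p in patients) {
      va <- f_a(p); vb <- f_b(p)
      if (length(va) > 0 && length(vb) > 0) {
        a <- c(a, mean(va)); b <- c(b, mean(vb))
      }
    }
    list(a = a, b = b)
  }

  out <- list()
  out$noncorresponding_per_value <- safe_t(
    incorrect$measured, incorrect$registered,
    c("measured", "registered (incorrect entries)"))
  pp <- per_patient_pairs(
    function(p) incorrect$measured[incorrect$patient_id == p],
    function(p) incorrect$registered[incorrect$patient_id == p])
  out$noncorresponding_per_patient <- safe_t(
    pp$a, pp$b, c("measured mean", "registered mean (incorrect entries)"))
  pp <- per_patient_pairs(all_measured, phantom_vals)
  out$phantom_per_patient <- safe_t(
    pp$a, pp$b, c("all measured mean", "phantom mean"))
  pp <- per_patient_pairs(matched_measured, omission_vals)
  out$omission_per_patient <- safe_t(
    pp$a, pp$b, c("measured-and-registered mean", "omission-day mean"))
  pp <- per_patient_pairs(sel_matched, sel_unreg)
  out$selection_per_patient <- safe_t(
    pp$a, pp$b, c("selected (registered) mean", "unselected mean"))
  out
}

#' @export
print.reliability_summary <- function(x, ...) {
  cat("Reliability of registered data\n")
  cat(sprintf("  registrations: %d   measurements (non-test): %d   patients: %d\n",
              x$totals$n_registered, x$totals$n_measured, x$totals$n_patients))
  cat(sprintf("  equal-count days: %d registrations\n",
              x$equal_days$n_registrations))
  cat(sprintf("  reliable:          %5d (%.2f%%)\n",
              x$reliable$n, 100 * x$reliable$frac))
  cat(sprintf("  noncorresponding:  %5d (%.0f%%), of which incorrect entries %d (%.0f%%)\n",
              x$noncorresponding$n, 100 * x$noncorresponding$frac,
              x$noncorresponding$incorrect_n,
              100 * x$noncorresponding$incorrect_frac))
  cat(sprintf("  phantom values:    %5d (%.2f%% of registrations)\n",
              x$phantom$n, 100 * x$phantom$frac_of_registered))
  cat(sprintf("  unregistered:      %5d (%.2f%% of measurements; %d omissions, %d in series)\n",
              x$unregistered$n, 100 * x$unregistered$frac_of_measured,
              x$omission$n_values, x$selection$n_unregistered))
  invisible(x)
}
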