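#' Feedback policy of the self-management support system
#'
#' Encodes the traffic-light rules: a newly registered creatinine value is
#' compared against the mean of the previous `baseline_window` registered
#' values; a relative increase strictly above `orange_threshold` turns the
#' light orange and strictly above `red_threshold` red. At most
#' `max_registrations_per_day` values can be registered per calendar day.
#'
#' @param orange_threshold Relative increase above baseline for an orange
#'   light (default 0.15, i.e. >15%).
#' @param red_threshold Relative increase for a red light (default 0.20).
#' @param baseline_window Number of prior registered values averaged
#'   (default 5).
#' @param max_registrations_per_day Registration cap per day (default 2).
#' @param include_first_in_second_baseline If `TRUE`, the baseline used for
#'   the second value of a day includes that day's first value. The default
#'   (`FALSE`) excludes it, so a first spike cannot mask itself.
#' @return A list of class `feedback_policy`.
#' @export
feedback_policy <- function(orange_threshold = 0.15,
                            red_threshold = 0.20,
                            baseline_window = 5L,
                            max_registrations_per_day = 2L,
                            include_first_in_second_baseline = FALSE) {
  stopifnot(
    orange_threshold > 0, red_threshold > orange_threshold,
    baseline_window >= 1, max_registrations_per_day >= 1
  )
  structure(
    list(
      orange_threshold = orange_threshold,
      red_threshold = red_threshold,
      baseline_window = as.integer(baseline_window),
      max_registrations_per_day = as.integer(max_registrations_per_day),
      include_first_in_second_baseline = isTRUE(include_first_in_second_baseline)
    ),
    class = "feedback_policy"
  )
}

#' Test-strip value policy
#'
#' Patients were asked to perform a test measurement when opening a new bottle
#' of strips; unflagged test values are identified by four criteria: the value
#' was never registered, it differs from both temporal neighbours, it falls in
#' the manufacturer's test range, and it was measured shortly before or after
#' a registered value on the same day.
#'
#' @param value_range Closed test-value interval in µmol/l (default
#'   `c(133, 239)`).
#' @param neighbor_diff Minimum absolute difference from both temporal
#'   neighbours, µmol/l (default 10).
#' @param neighbor_window_mins "Shortly after one another" window in minutes
#'   (default 30).
#' @return A list of class `test_strip_policy`.
#' @export
test_strip_policy <- function(value_range = c(133, 239),
                              neighbor_diff = 10,
                              neighbor_window_mins = 30) {
  stopifnot(length(value_range) == 2, value_range[1] < value_range[2],
            neighbor_diff >= 0, neighbor_window_mins > 0)
  structure(
    list(
      value_range = as.numeric(value_range),
      neighbor_diff = as.numeric(neighbor_diff),
      neighbor_window_mins = as.numeric(neighbor_window_mins)
    ),
    class = "test_strip_policy"
  )
}

#' Reconciliation parameters
#'
#' Operational thresholds for cause attribution of noncorresponding
#' registrations and value matching.
#'
#' @param date_shift_window Days (+/-) searched for an exact-value match on a
#'   neighbouring date (default 3).
#' @param rounding_tol Maximum absolute difference for the rounding cause
#'   (default 5); the registered value must also be a multiple of 5.
#' @param value_tol Equality tolerance in µmol/l (default 0: exact integer
#'   equality, matching a meter that reports integers).
#' @return A list of class `reconcile_params`.
#' @export
reconcile_params <- function(date_shift_window = 3L,
                             rounding_tol = 5,
                             value_tol = 0) {
  stopifnot(date_shift_window >= 0, rounding_tol >= 0, value_tol >= 0)
  structure(
    list(
      date_shift_window = as.integer(date_shift_window),
      rounding_tol = as.numeric(rounding_tol),
      value_tol = as.numeric(value_tol)
    ),
    class = "reconcile_params"
  )
}

values_equal <- function(a, b, tol = 0) {
  abs(a - b) <= tol
}
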