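#' Paired t test from first principles
#'
#' Computes the paired comparison used throughout the reporting: the t
#' statistic is the mean of the differences over its standard error,
#' `t = mean(d) / (sd(d)/sqrt(n))`, with `n - 1` degrees of freedom and a
#' two-sided p value. When the differences have zero variance the statistic
#' is not defined: the result carries a `zero_variance` flag and `t` is 0 for
#' a zero mean difference or signed infinity otherwise.
#'
#' @param a,b Numeric vectors of paired observations in identical units.
#' @param labels Character vector of length 2 naming the two sides.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return A list of class `paired_comparison` with `n`, `mean_a`, `mean_b`,
#'   `mean_diff`, `sd_diff`, `t`, `df`, `p`, `significant`, `zero_variance`
#'   and `labels`.
#' @export
#' @examples
#' paired_t(c(130, 140, 125), c(123, 131, 120))
paired_t <- function(a, b, labels = c("a", "b"), alpha = 0.05) {
  if (length(a) != length(b)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) {
    stop("paired_t does not accept missing values", call. = FALSE)
  }
  n <- length(a)
  if (n < 2) {
    stop("need at least 2 pairs", call. = FALSE)
  }
  d <- a - b
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  df <- n - 1L
  if (sd_diff == 0) {
    t_stat <- if (mean_diff == 0) 0 else sign(mean_diff) * Inf
    p <- if (mean_diff == 0) 1 else 0
    zero_var <- TRUE
  } else {
    t_stat <- mean_diff / (sd_diff / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = df)
    zero_var <- FALSE
  }
  structure(list(
    labels = labels, n = n, mean_a = mean(a), mean_b = mean(b),
    mean_diff = mean_diff, sd_diff = sd_diff, t = t_stat, df = df, p = p,
    significant = is.finite(p) && p < alpha, zero_variance = zero_var
  ), class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Paired comparison: %s vs %s\n", x$labels[1], x$labels[2]))
  cat(sprintf("  n = %d, means %.2f vs %.2f, diff %.2f\n",
              x$n, x$mean_a, x$mean_b, x$mean_diff))
  if (x$zero_variance) {
    cat("  zero variance of differences\n")
  } else {
    cat(sprintf("  t(%d) = %.2f, p = %.3g\n", x$df, x$t, x$p))
  }
  invisible(x)
}

#' Mean arterial pressure
#'
#' `MAP = (2 * diastolic + systolic) / 3`, the standard weighted average that
#' weights the (longer) diastolic part of the cardiac cycle twice.
#'
#' @param systolic,diastolic Pressures in mmHg; `systolic >= diastolic > 0`.
#' @return MAP in mmHg.
#' @export
#' @examples
#' mean_arterial_pressure(120, 80)  # 93.33
mean_arterial_pressure <- function(systolic, diastolic) {
  if (any(diastolic <= 0) || any(systolic < diastolic)) {
    stop("require systolic >= diastolic > 0", call. = FALSE)
  }
  (2 * diastolic + systolic) / 3
}

#' Per-day MAP pairs from measured and registered blood pressures
#'
#' Keeps only days where the device and the SMSS hold an equal number of
#' readings, computes each side's daily MAP as the mean of its per-reading
#' MAPs, and flags days whose two MAPs disagree (the noncorresponding set
#' that feeds the paired comparison).
#'
#' @param bp_device,bp_smss Tibbles with `patient_id`, `date`, `systolic`,
#'   `diastolic`.
#' @param tol MAP equality tolerance in mmHg (default 1e-9).
#' @return A tibble with `patient_id`, `date`, `n_readings`, `map_measured`,
#'   `map_registered`, `noncorresponding`.
#' @export
bp_day_map <- function(bp_device, bp_smss, tol = 1e-9) {
  daily <- function(x, name) {
    x |>
      dplyr::group_by(.data$patient_id, .data$date) |>
      dplyr::summarise(
        n = dplyr::n(),
        map = mean(mean_arterial_pressure(.data$systolic, .data$diastolic)),
        .groups = "drop"
      ) |>
      stats::setNames(c("patient_id", "date", paste0("n_", name),
                        paste0("map_", name)))
  }
  merged <- dplyr::inner_join(daily(bp_device, "measured"),
                              daily(bp_smss, "registered"),
                              by = c("patient_id", "date"))
  merged <- merged[merged$n_measured == merged$n_registered, , drop = FALSE]
  tibble::tibble(
    patient_id = merged$patient_id,
    date = merged$date,
    n_readings = merged$n_measured,
    map_measured = merged$map_measured,
    map_registered = merged$map_registered,
    noncorresponding = abs(merged$map_measured - merged$map_registered) > tol
  )
}
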