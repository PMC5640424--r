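#' Default four-phase creatinine monitoring schedule
#'
#' The first post-transplantation year is monitored in four phases of
#' decreasing frequency: daily during weeks 1-4 (phase 1), every other day
#' during weeks 5-9 (phase 2), twice a week during weeks 10-15 (phase 3), and
#' weekly from week 16 through week 52 (phase 4). The number of requested
#' measurement days per phase is 28, 15, 12 and 37 respectively (92 days over
#' the year).
#'
#' @return A tibble with one row per phase and columns `phase`, `week_start`,
#'   `week_end` (inclusive 1-based week numbers), `frequency` and
#'   `requested_days`.
#' @export
#' @examples
#' default_schedule()
default_schedule <- function() {
  tibble::tibble(
    phase = 1:4,
    week_start = c(1L, 5L, 10L, 16L),
    week_end = c(4L, 9L, 15L, 52L),
    frequency = c("daily", "every-other-day", "twice-weekly", "weekly"),
    requested_days = c(28L, 15L, 12L, 37L)
  )
}

validate_schedule <- function(schedule) {
  required <- c("phase", "week_start", "week_end", "frequency", "requested_days")
  missing <- setdiff(required, names(schedule))
  if (length(missing) > 0) {
    stop("schedule is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(schedule$week_start > schedule$week_end)) {
    stop("schedule has week_start > week_end", call. = FALSE)
  }
  # week ranges must partition the covered weeks consecutively
  if (nrow(schedule) > 1 &&
      any(schedule$week_start[-1] != schedule$week_end[-nrow(schedule)] + 1L)) {
    stop("schedule week ranges must be consecutive", call. = FALSE)
  }
  invisible(schedule)
}

#' Map a day index to its monitoring phase
#'
#' Day 0 is the first monitored day; weeks are consecutive 7-day blocks, so
#' day `d` falls in week `d %/% 7 + 1`.
#'
#' @param day_index Integer vector of days since monitoring start (>= 0).
#' @param schedule A schedule tibble as returned by [default_schedule()].
#' @return Integer vector of phase numbers.
#' @export
#' @examples
#' phase_of(0)    # 1
#' phase_of(28)   # first day of week 5 -> phase 2
#' phase_of(110)  # week 16 -> phase 4
phase_of <- function(day_index, schedule = default_schedule()) {
  validate_schedule(schedule)
  if (any(is.na(day_index)) || any(day_index < 0)) {
    stop("day_index must be non-negative and non-missing", call. = FALSE)
  }
  week <- day_index %/% 7L + 1L
  idx <- findInterval(week, schedule$week_start)
  if (any(idx < 1L) || any(week > schedule$week_end[nrow(schedule)])) {
    stop("day_index beyond schedule horizon (weeks 1-",
         schedule$week_end[nrow(schedule)], ")", call. = FALSE)
  }
  schedule$phase[idx]
}

#' First and last day index of each phase
#'
#' @param schedule A schedule tibble.
#' @return The schedule with `day_start` and `day_end` columns (0-based,
#'   inclusive).
#' @export
phase_day_range <- function(schedule = default_schedule()) {
  validate_schedule(schedule)
  dplyr::mutate(schedule,
    day_start = (.data$week_start - 1L) * 7L,
    day_end = .data$week_end * 7L - 1L
  )
}

#' Requested-day calendar for a schedule
#'
#' Expands each phase into the explicit day indices on which a measurement is
#' requested: daily phases request every day; every-other-day phases request
#' days 0, 2, 4, ... of the phase; twice-weekly phases request the 1st and 4th
#' day of each phase week; weekly phases request the first day of each week.
#' Each phase's calendar is truncated to its `requested_days` count so that
#' calendars and adherence denominators always agree.
#'
#' @param schedule A schedule tibble.
#' @return A tibble with columns `day_index` and `phase`, one row per
#'   requested day, sorted by `day_index`.
#' @export
requested_day_calendar <- function(schedule = default_schedule()) {
  ranges <- phase_day_range(schedule)
  rows <- lapply(seq_len(nrow(ranges)), function(i) {
    r <- ranges[i, ]
    offsets <- switch(r$frequency,
      "daily" = seq(0L, r$day_end - r$day_start),
      "every-other-day" = seq(0L, r$day_end - r$day_start, by = 2L),
      "twice-weekly" = as.integer(outer(c(0L, 3L), 7L * (0:(r$week_end - r$week_start)), `+`)),
      "weekly" = 7L * (0:(r$week_end - r$week_start)),
      stop("unknown frequency: ", r$frequency, call. = FALSE)
    )
    offsets <- sort(offsets)
    offsets <- offsets[seq_len(min(length(offsets), r$requested_days))]
    tibble::tibble(day_index = r$day_start + offsets, phase = r$phase)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$day_index)
}
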