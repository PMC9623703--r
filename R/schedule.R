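#' Build the 21-day urea acclimation schedule for one treatment
#'
#' Cows were ramped onto their final urea dose over 21 days to avoid ammonia
#' toxicity. The high-N ramp steps through 88, 176, 351, 450, 600 and
#' 690 g/d (4, 3, 4, 3, 4 and 3 days respectively); the medium-N group runs
#' the first three steps only, starting on day 11 so that both groups are at
#' their final dose over the same final days. Doses of at least 351 g/d are
#' split into 3 daily doses, smaller doses into 2. Any other positive
#' `final_dose` reuses the same step pattern scaled proportionally.
#'
#' @param treatment One of `"LOW_N"`, `"MEDIUM_N"`, `"HIGH_N"`.
#' @param final_dose Final daily urea dose in g/d. Defaults to the study dose
#'   for the treatment (0, 351 or 690 g/d).
#' @param n_days Total days covered by the schedule (default 21).
#'
#' @return A tibble with one row per schedule step: `start_day`, `n_days`,
#'   `grams_per_dose`, `doses_per_day`, `total_g_per_day`.
#' @examples
#' urea_schedule("HIGH_N")
#' urea_schedule("MEDIUM_N")
#' @export
urea_schedule <- function(treatment = c("LOW_N", "MEDIUM_N", "HIGH_N"),
                          final_dose = NULL, n_days = 21L) {
  treatment <- match.arg(treatment)
  if (is.null(final_dose)) {
    final_dose <- c(LOW_N = 0, MEDIUM_N = 351, HIGH_N = 690)[[treatment]]
  }
  if (final_dose < 0) stop("`final_dose` must be non-negative.", call. = FALSE)

  if (final_dose == 0) {
    return(schedule_tbl(start_day = 1L, n_days = as.integer(n_days),
                        total = 0))
  }

  # ramp step pattern: fractions of the full 690 g/d high-N ramp and durations
  ramp_frac <- c(88, 176, 351, 450, 600, 690) / 690
  ramp_days <- c(4L, 3L, 4L, 3L, 4L, 3L)

  if (treatment == "MEDIUM_N") {
    # first three steps of the ramp, rescaled so the third step is final_dose,
    # preceded by an unsupplemented lead-in so final doses align across groups
    frac <- ramp_frac[1:3] / ramp_frac[3]
    days <- ramp_days[1:3]
    lead <- as.integer(n_days) - sum(days)
    if (lead < 0) stop("`n_days` too short for the medium-N ramp.", call. = FALSE)
    steps <- schedule_tbl(
      start_day = lead + cumsum(c(1L, days[-length(days)])),
      n_days = days,
      total = frac * final_dose
    )
    if (lead > 0) {
      steps <- dplyr::bind_rows(
        schedule_tbl(start_day = 1L, n_days = lead, total = 0),
        steps
      )
    }
    return(steps)
  }

  # LOW_N with a positive dose is treated like a full ramp (generalized use)
  total <- ramp_frac * final_dose
  schedule_tbl(
    start_day = cumsum(c(1L, ramp_days[-length(ramp_days)])),
    n_days = ramp_days,
    total = total
  )
}

# internal: assemble schedule rows, deriving doses/day and grams/dose
schedule_tbl <- function(start_day, n_days, total) {
  total <- round(total, 9) # drop scaling dust so dose thresholds are exact
  doses <- ifelse(total >= 351, 3L, 2L)
  tibble::tibble(
    start_day = as.integer(start_day),
    n_days = as.integer(n_days),
    grams_per_dose = total / doses,
    doses_per_day = doses,
    total_g_per_day = total
  )
}

#' Expand an acclimation schedule to one dose per day
#'
#' @param schedule A schedule tibble from [urea_schedule()].
#' @return A tibble with columns `day` and `urea_g`, one row per day.
#' @export
schedule_daily_doses <- function(schedule) {
  tidyr::uncount(schedule, weights = .data$n_days, .id = "offset") |>
    dplyr::transmute(
      day = .data$start_day + .data$offset - 1L,
      urea_g = .data$total_g_per_day
    ) |>
    dplyr::arrange(.data$day)
}
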