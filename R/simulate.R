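#' Predict milk yield from the true piecewise dose-response
#'
#' Evaluates the continuous broken-stick model
#' `y = intercept + slope_below * min(x, bp) + slope_above * max(x - bp, 0)`.
#' With the default parameters of [sim_config()] this is the dose-response the
#' generator uses as ground truth: a mild rise up to 350 g urea/d and a decline
#' of 2.35 kg milk per 100 g urea beyond it.
#'
#' @param urea_g Urea dose(s), g/d.
#' @param params Length-4 numeric `(intercept, slope_below, slope_above,
#'   breakpoint)`.
#' @return Milk yield, kg/d.
#' @export
true_milk_yield <- function(urea_g, params = sim_config()$true_splitline) {
  params[[1]] + params[[2]] * pmin(urea_g, params[[4]]) +
    params[[3]] * pmax(urea_g - params[[4]], 0)
}

# internal: draw static cow profiles for a set of treatments
make_cow_profiles <- function(config, treatments) {
  n <- config$n_cows_per_treatment * length(treatments)
  tr <- config$cow_traits
  tibble::tibble(
    cow_id = sprintf("C%02d", seq_len(n)),
    treatment = rep(treatments, each = config$n_cows_per_treatment),
    parity = sample(2:6, n, replace = TRUE),
    dim = round(stats::rnorm(n, tr$dim[1], tr$dim[2])),
    bw = stats::rnorm(n, tr$bw[1], tr$bw[2]),
    bcs = stats::rnorm(n, tr$bcs[1], tr$bcs[2]),
    cow_intercept_milk = stats::rnorm(n, 0, config$cow_sd_milk),
    cow_intercept_urineN = stats::rnorm(n, 0, config$cow_sd_urine)
  )
}

# internal: draw one pasture composition row per day from a phase distribution
draw_pasture <- function(n, dist) {
  draw <- function(p) stats::rnorm(n, p[1], p[2])
  tibble::tibble(
    pasture_cp_pct = pmax(draw(dist$cp_pct), 0.5),
    pasture_ndf_pct = draw(dist$ndf_pct),
    pasture_adf_pct = draw(dist$adf_pct),
    pasture_nsc_pct = draw(dist$nsc_pct),
    pasture_dmd_pct = draw(dist$dmd_pct),
    pasture_me = pmax(draw(dist$me), 0.1)
  )
}

#' Simulate the 21-day grazing acclimation phase
#'
#' Generates one record per cow-day for 3 treatment groups (low, medium, high
#' N) following the stepped urea acclimation schedule. Milk yield is generated
#' from the true piecewise dose-response plus a cow-level random intercept and
#' a per-day Gaussian residual, so that fitting [fit_splitline()] to the output
#' is a parameter-recovery exercise with known truth.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per cow-day: identity and traits, `day`,
#'   `urea_g`, milk yield and composition, `bw_kg`, `km_walked` and the
#'   pasture composition columns.
#' @examples
#' ph1 <- simulate_phase1(sim_config(seed = 7))
#' dplyr::count(ph1, treatment)
#' @export
simulate_phase1 <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  treatments <- c("LOW_N", "MEDIUM_N", "HIGH_N")
  cows <- make_cow_profiles(config, treatments)

  doses <- purrr::map(treatments, function(tr) {
    urea_schedule(tr, final_dose = config$phase1_final_doses[[tr]]) |>
      schedule_daily_doses()
  })
  names(doses) <- treatments
  n_days <- nrow(doses[[1]])

  pasture <- draw_pasture(n_days, config$pasture$phase1) |>
    dplyr::mutate(day = seq_len(n_days))

  rec <- tidyr::crossing(cows, day = seq_len(n_days)) |>
    dplyr::left_join(
      dplyr::bind_rows(doses, .id = "treatment"),
      by = c("treatment", "day")
    ) |>
    dplyr::left_join(pasture, by = "day")

  n <- nrow(rec)
  rec |>
    dplyr::mutate(
      milk_yield_kg = clip_at(
        true_milk_yield(.data$urea_g, config$true_splitline) +
          .data$cow_intercept_milk +
          stats::rnorm(n, 0, config$noise_sd_milk),
        0, "milk yield"),
      milk_fat_pct = pmax(stats::rnorm(n, 4.2, 0.30), 0),
      milk_cp_pct = pmax(stats::rnorm(n, 3.4, 0.15), 0),
      milk_lactose_pct = pmax(stats::rnorm(n, 4.8, 0.15), 0),
      bw_kg = .data$bw + stats::rnorm(n, 0, 2),
      km_walked = pmax(stats::rnorm(n, 2, 0.5), 0)
    ) |>
    dplyr::select(
      "cow_id", "treatment", "parity", "dim", "bcs", "day", "urea_g",
      "milk_yield_kg", "milk_fat_pct", "milk_cp_pct", "milk_lactose_pct",
      "bw_kg", "km_walked", dplyr::starts_with("pasture_")
    ) |>
    dplyr::arrange(.data$cow_id, .data$day)
}

#' Simulate the metabolism-stall total-collection phase
#'
#' Generates one record per cow-day for the low-N (0 g urea/d) and medium-N
#' (250 g urea/d by default) groups over the collection days. Dry-matter
#' intake is offered minus refused pasture; true N intake follows from intake,
#' pasture crude protein and the urea dose. Total non-urine N is set to
#' `(1 - slope) * intake - intercept` plus noise and split between feces and
#' milk in a fixed proportion; fecal N concentration, fecal mass and milk
#' crude-protein percentage are then back-solved so that [n_balance()]
#' recovers these values exactly, which makes the implied urinary N equal to
#' `intercept + slope * intake + noise` by construction.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per cow-day: `cow_id`, `treatment`, `day`
#'   (collection days 25-31 by default), feed offered/refused (kg DM/d),
#'   `urea_g`, milk yield and composition, fecal wet mass, DM% and N
#'   concentration (g/kg wet feces), `urine_volume_l` and pasture columns.
#' @examples
#' ph2 <- simulate_phase2(sim_config(seed = 7))
#' nrow(ph2) # 10 cows x 7 days
#' @export
simulate_phase2 <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  treatments <- c("LOW_N", "MEDIUM_N")
  cows <- make_cow_profiles(config, treatments)
  days <- 24L + seq_len(config$n_days_phase2)

  rec <- tidyr::crossing(cows, day = days)
  n <- nrow(rec)
  slope <- config$true_urine_line[["slope"]]
  intercept <- config$true_urine_line[["intercept"]]
  split <- config$nonurine_split_fecal

  rec <- rec |>
    dplyr::bind_cols(draw_pasture(n, config$pasture$phase2)) |>
    dplyr::mutate(
      offered_kg_dm = 20,
      refused_kg_dm = pmin(pmax(stats::rnorm(n, 0.9, 0.8), 0), .data$offered_kg_dm),
      dmi_kg = .data$offered_kg_dm - .data$refused_kg_dm,
      urea_g = ifelse(.data$treatment == "MEDIUM_N", config$phase2_urea_dose, 0),
      n_intake_true = .data$dmi_kg * 1000 * (.data$pasture_cp_pct / 100) / 6.25 +
        .data$urea_g * config$urea_n_fraction,
      eps = .data$cow_intercept_urineN + stats::rnorm(n, 0, config$noise_sd_urine),
      nonurine_n = clip_at((1 - slope) * .data$n_intake_true - intercept - .data$eps,
                           0, "non-urine N"),
      fecal_n_true = split * .data$nonurine_n,
      milk_n_true = (1 - split) * .data$nonurine_n,
      milk_yield_kg = pmax(
        stats::rnorm(n, ifelse(.data$treatment == "MEDIUM_N", 22.9, 25.0), 1.5),
        0.5),
      milk_cp_pct = .data$milk_n_true * 6.38 / (.data$milk_yield_kg * 10),
      milk_fat_pct = pmax(
        stats::rnorm(n, ifelse(.data$treatment == "MEDIUM_N", 4.32, 4.23), 0.30), 0),
      milk_lactose_pct = pmax(stats::rnorm(n, 4.8, 0.15), 0),
      fecal_wet_kg = pmax(stats::rnorm(n, 44, 4), 1),
      fecal_n_g_per_kg = .data$fecal_n_true / .data$fecal_wet_kg,
      fecal_dm_pct = pmax(stats::rnorm(n, 13, 1.5), 1),
      urine_volume_l = pmax(stats::rnorm(n, 35, 4), 1)
    )

  rec |>
    dplyr::select(
      "cow_id", "treatment", "parity", "dim", "bcs", "day",
      "offered_kg_dm", "refused_kg_dm", "urea_g",
      "milk_yield_kg", "milk_fat_pct", "milk_cp_pct", "milk_lactose_pct",
      "fecal_wet_kg", "fecal_dm_pct", "fecal_n_g_per_kg", "urine_volume_l",
      dplyr::starts_with("pasture_")
    ) |>
    dplyr::arrange(.data$cow_id, .data$day)
}
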