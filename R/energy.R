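#' Maintenance energy requirement
#'
#' Metabolizable energy required for maintenance, `0.56 MJ per kg of
#' metabolic body weight` (BW^0.75).
#'
#' @param bw Body weight, kg. Must be positive.
#' @return MJ/d.
#' @examples
#' maintenance_mj(505)
#' @export
maintenance_mj <- function(bw) {
  if (any(bw <= 0)) stop("`bw` must be positive.", call. = FALSE)
  0.56 * bw^0.75
}

#' Activity energy requirement of a grazing cow
#'
#' `0.0037 MJ per kg of body weight per horizontal kilometer walked`.
#'
#' @param bw Body weight, kg (positive).
#' @param km_walked Horizontal distance walked, km/d (non-negative).
#' @return MJ/d.
#' @export
activity_mj <- function(bw, km_walked) {
  if (any(bw <= 0)) stop("`bw` must be positive.", call. = FALSE)
  if (any(km_walked < 0)) stop("`km_walked` must be non-negative.", call. = FALSE)
  0.0037 * bw * km_walked
}

#' Average daily body-weight change from a weighing series
#'
#' Ordinary least-squares slope of body weight on day, the standard way to
#' smooth gut-fill noise out of repeated weighings.
#'
#' @param day Day indices (at least two distinct values).
#' @param bw Body weights, kg, same length as `day`.
#' @return Slope in kg/d (negative when losing weight).
#' @examples
#' estimate_daily_bw_change(c(0, 7), c(500, 503.5))
#' @export
estimate_daily_bw_change <- function(day, bw) {
  stopifnot(length(day) == length(bw))
  if (length(unique(day)) < 2) {
    stop("Need at least 2 distinct days to regress body weight on time.",
         call. = FALSE)
  }
  unname(stats::coef(stats::lm(bw ~ day))[2])
}

#' Energy cost (or yield) of body-weight change
#'
#' The energy value of a kilogram of body-weight change is not a universal
#' constant; it is a required parameter (default 30 MJ/kg, a typical value for
#' body-tissue energy in lactating cows). Weight loss (negative `delta_bw`)
#' supplies energy and returns a negative requirement.
#'
#' @param delta_bw Daily body-weight change, kg/d.
#' @param energy_per_kg Energy per kg of BW change, MJ/kg (positive).
#' @return MJ/d.
#' @export
bw_change_mj <- function(delta_bw, energy_per_kg = 30) {
  if (any(energy_per_kg <= 0)) {
    stop("`energy_per_kg` must be positive.", call. = FALSE)
  }
  delta_bw * energy_per_kg
}

#' Metabolizable energy required for milk synthesis
#'
#' Gross milk energy per kg is `0.0929 x fat% + 0.0547 x CP% + 0.0395 x
#' lactose%` Mcal/kg; the total over the day's yield is divided by the
#' efficiency of ME use for lactation (0.65). The Mcal total is converted to
#' MJ by dividing by 0.238 Mcal/MJ (equivalently multiplying by about
#' 4.2 MJ/Mcal), the only dimensionally coherent direction given that the
#' composition coefficients are in Mcal. `convert = "literal_mcal"` instead
#' multiplies by 0.238, preserving the arithmetic as sometimes printed in the
#' applied literature, for audit purposes only.
#'
#' @param yield_kg Milk yield, kg/d.
#' @param fat_pct,cp_pct,lactose_pct Milk composition, %.
#' @param efficiency Efficiency of ME use for lactation (default 0.65).
#' @param mcal_per_mj Conversion constant, Mcal per MJ (default 0.238).
#' @param convert `"mj"` (default) or `"literal_mcal"`.
#' @return MJ/d (or the literal Mcal-style figure under `"literal_mcal"`).
#' @examples
#' milk_energy_mj(25, fat_pct = 4.0, cp_pct = 3.3, lactose_pct = 4.8)
#' @export
milk_energy_mj <- function(yield_kg, fat_pct, cp_pct, lactose_pct,
                           efficiency = 0.65, mcal_per_mj = 0.238,
                           convert = c("mj", "literal_mcal")) {
  convert <- match.arg(convert)
  if (any(c(yield_kg, fat_pct, cp_pct, lactose_pct) < 0)) {
    stop("Milk yield and composition must be non-negative.", call. = FALSE)
  }
  per_kg_mcal <- 0.0929 * fat_pct + 0.0547 * cp_pct + 0.0395 * lactose_pct
  total_mcal <- per_kg_mcal * yield_kg / efficiency
  switch(convert,
    mj = total_mcal / mcal_per_mj,
    literal_mcal = total_mcal * mcal_per_mj
  )
}

#' Total metabolizable-energy requirement per cow-day
#'
#' Sums the four requirement components: maintenance, walking activity,
#' body-weight change and milk synthesis.
#'
#' @param bw Body weight, kg.
#' @param km_walked Distance walked, km/d.
#' @param delta_bw Daily BW change, kg/d.
#' @param yield_kg,fat_pct,cp_pct,lactose_pct Milk yield and composition.
#' @param bw_energy_per_kg Energy per kg BW change, MJ/kg.
#' @param ... Passed to [milk_energy_mj()].
#' @return A tibble with the component columns `maintenance_mj`,
#'   `activity_mj`, `bw_change_mj`, `milk_mj` and their sum `total_mj`.
#' @export
energy_requirement <- function(bw, km_walked = 0, delta_bw = 0,
                               yield_kg = 0, fat_pct = 0, cp_pct = 0,
                               lactose_pct = 0, bw_energy_per_kg = 30, ...) {
  out <- tibble::tibble(
    maintenance_mj = maintenance_mj(bw),
    activity_mj = activity_mj(bw, km_walked),
    bw_change_mj = bw_change_mj(delta_bw, bw_energy_per_kg),
    milk_mj = milk_energy_mj(yield_kg, fat_pct, cp_pct, lactose_pct, ...)
  )
  out$total_mj <- out$maintenance_mj + out$activity_mj +
    out$bw_change_mj + out$milk_mj
  out
}

#' Back-calculate dry-matter intake from an energy requirement
#'
#' Divides the total ME requirement by the ME density of the diet consumed —
#' the standard way to estimate intake for grazing cows whose individual
#' consumption cannot be measured directly.
#'
#' @param total_mj Total ME requirement, MJ/d.
#' @param diet_me ME content of the diet, MJ/kg DM (positive).
#' @return Dry-matter intake, kg DM/d.
#' @examples
#' back_calculate_dmi(236, diet_me = 11.8)
#' @export
back_calculate_dmi <- function(total_mj, diet_me) {
  if (any(diet_me <= 0)) stop("`diet_me` must be positive.", call. = FALSE)
  total_mj / diet_me
}

#' Estimate per-cow-day DMI for a grazing-phase dataset
#'
#' Applies the full energy-balance back-calculation to a phase-1 cow-day
#' table: maintenance from body weight, activity from distance walked, BW
#' change from a per-cow regression of weight on day, milk energy from yield
#' and composition, all divided by pasture ME.
#'
#' @param records A phase-1 cow-day tibble as from [simulate_phase1()].
#' @param bw_energy_per_kg Energy per kg BW change, MJ/kg.
#' @param ... Passed to [milk_energy_mj()].
#' @return `records` with the energy component columns and `dmi_kg` appended.
#' @export
estimate_phase1_dmi <- function(records, bw_energy_per_kg = 30, ...) {
  records |>
    dplyr::group_by(.data$cow_id) |>
    dplyr::mutate(delta_bw = estimate_daily_bw_change(.data$day, .data$bw_kg)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      energy_requirement(
        bw = .data$bw_kg, km_walked = .data$km_walked,
        delta_bw = .data$delta_bw, yield_kg = .data$milk_yield_kg,
        fat_pct = .data$milk_fat_pct, cp_pct = .data$milk_cp_pct,
        lactose_pct = .data$milk_lactose_pct,
        bw_energy_per_kg = bw_energy_per_kg, ...
      ),
      dmi_kg = back_calculate_dmi(.data$total_mj, .data$pasture_me)
    )
}
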