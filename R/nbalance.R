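#' Daily nitrogen intake from pasture and urea
#'
#' Pasture N is crude protein divided by 6.25; urea N is the dose times the N
#' fraction of feed-grade urea (0.466 g N/g by default).
#'
#' @param dmi_kg Dry-matter intake, kg DM/d.
#' @param pasture_cp_pct Pasture crude protein, % of DM.
#' @param urea_g Urea dose, g/d.
#' @param urea_n_fraction g N per g urea, in (0, 1).
#' @return N intake, g/d.
#' @examples
#' n_intake(19.1, 18.4, 250)
#' @export
n_intake <- function(dmi_kg, pasture_cp_pct, urea_g = 0, urea_n_fraction = 0.466) {
  if (any(c(dmi_kg, pasture_cp_pct, urea_g) < 0)) {
    stop("Intake components must be non-negative.", call. = FALSE)
  }
  if (any(urea_n_fraction <= 0 | urea_n_fraction >= 1)) {
    stop("`urea_n_fraction` must lie in (0, 1).", call. = FALSE)
  }
  dmi_kg * 1000 * (pasture_cp_pct / 100) / 6.25 + urea_g * urea_n_fraction
}

#' Crude-protein concentration of the consumed diet
#'
#' Inverts the `CP = N x 6.25` conversion at the whole-diet level.
#'
#' @param n_intake_g N intake, g/d.
#' @param dmi_kg Dry-matter intake, kg DM/d (positive).
#' @return Diet CP, % of DM.
#' @export
diet_cp_pct <- function(n_intake_g, dmi_kg) {
  if (any(dmi_kg <= 0)) stop("`dmi_kg` must be positive.", call. = FALSE)
  (n_intake_g * 6.25) / (dmi_kg * 1000) * 100
}

#' Daily milk nitrogen output
#'
#' Milk N percentage is milk crude protein percentage divided by 6.38 (the
#' milk-protein N factor); output is that percentage of the day's yield.
#'
#' @param yield_kg Milk yield, kg/d.
#' @param milk_cp_pct Milk crude protein, %.
#' @return Milk N, g/d.
#' @export
milk_n <- function(yield_kg, milk_cp_pct) {
  if (any(c(yield_kg, milk_cp_pct) < 0)) {
    stop("Milk yield and CP must be non-negative.", call. = FALSE)
  }
  yield_kg * 1000 * (milk_cp_pct / 100) / 6.38
}

#' Daily fecal nitrogen output
#'
#' Fecal N is mass times N concentration, with both on the same basis. When
#' the mass is recorded on a different basis than the concentration (wet
#' weighings with a dry-basis assay, or vice versa), supply the fecal
#' dry-matter percentage and the mass is converted to the concentration's
#' basis first.
#'
#' @param fecal_mass_kg Fecal mass, kg/d.
#' @param n_conc_g_per_kg N concentration, g N per kg of feces.
#' @param conc_basis Basis of the concentration: `"wet"` (default; matches
#'   g/kg magnitudes near 3) or `"dry"`.
#' @param mass_basis Basis of the mass (defaults to `conc_basis`).
#' @param dm_pct Fecal dry matter, %; required only when the bases differ.
#' @return Fecal N, g/d.
#' @examples
#' fecal_n(43.75, 3.04) # wet mass, wet-basis concentration
#' @export
fecal_n <- function(fecal_mass_kg, n_conc_g_per_kg,
                    conc_basis = c("wet", "dry"),
                    mass_basis = conc_basis, dm_pct = NULL) {
  conc_basis <- match.arg(conc_basis)
  mass_basis <- match.arg(mass_basis, c("wet", "dry"))
  if (any(fecal_mass_kg < 0) || any(n_conc_g_per_kg < 0)) {
    stop("Fecal mass and N concentration must be non-negative.", call. = FALSE)
  }
  if (mass_basis != conc_basis) {
    if (is.null(dm_pct)) {
      stop("`dm_pct` is required to convert fecal mass between wet and dry basis.",
           call. = FALSE)
    }
    fecal_mass_kg <- if (mass_basis == "wet") {
      fecal_mass_kg * dm_pct / 100    # wet -> dry
    } else {
      fecal_mass_kg / (dm_pct / 100)  # dry -> wet
    }
  }
  fecal_mass_kg * n_conc_g_per_kg
}

#' Urinary nitrogen estimated by difference
#'
#' Urine N = intake N minus fecal and milk N, under the assumption that N
#' retention in body tissue is negligible (non-pregnant, mid-lactation cows
#' with stable condition). Negative estimates are returned as-is with a
#' warning rather than clipped, so that data faults stay visible.
#'
#' @param n_intake_g,fecal_n_g,milk_n_g Components, g/d (non-negative).
#' @return Estimated urine N, g/d; may be negative (warned).
#' @examples
#' urine_n_by_difference(563, 133, 123)
#' @export
urine_n_by_difference <- function(n_intake_g, fecal_n_g, milk_n_g) {
  if (any(c(n_intake_g, fecal_n_g, milk_n_g) < 0)) {
    stop("Balance components must be non-negative.", call. = FALSE)
  }
  out <- n_intake_g - (fecal_n_g + milk_n_g)
  if (any(out < 0)) {
    warning(sprintf("%d negative estimated urine N value(s); flagged, not clipped",
                    sum(out < 0)), call. = FALSE)
  }
  out
}

#' Four-way nitrogen balance for a stall-phase dataset
#'
#' Computes, for every cow-day of a total-collection record set, the N intake
#' (pasture plus urea), fecal N, milk N, urinary N by difference, the diet CP
#' concentration and (when urine volume was recorded) the implied urinary N
#' concentration. The balance closes by construction:
#' `intake = fecal + milk + urine` on every row.
#'
#' @param records A phase-2 cow-day tibble as from [simulate_phase2()].
#' @param urea_n_fraction g N per g urea.
#' @param fecal_conc_basis Basis of `fecal_n_g_per_kg` (`"wet"` default).
#' @return A tibble with one row per cow-day: `cow_id`, `treatment`, `day`,
#'   `dmi_kg`, `n_intake_g`, `fecal_n_g`, `milk_n_g`, `urine_n_est_g`,
#'   `diet_cp_pct`, `urine_n_conc_g_per_l` and `flag_negative_urine`.
#' @examples
#' simulate_phase2(sim_config(seed = 3)) |> n_balance() |> head()
#' @export
n_balance <- function(records, urea_n_fraction = 0.466,
                      fecal_conc_basis = c("wet", "dry")) {
  fecal_conc_basis <- match.arg(fecal_conc_basis)
  needed <- c("cow_id", "day", "offered_kg_dm", "refused_kg_dm", "urea_g",
              "milk_yield_kg", "milk_cp_pct", "fecal_wet_kg", "fecal_dm_pct",
              "fecal_n_g_per_kg", "pasture_cp_pct")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop("Stall-phase records are missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- records$refused_kg_dm > records$offered_kg_dm |
    records$refused_kg_dm < 0
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("Refused exceeds offered (or is negative) for cow %s day %s.",
                 records$cow_id[i], records$day[i]), call. = FALSE)
  }

  out <- records |>
    dplyr::mutate(
      dmi_kg = .data$offered_kg_dm - .data$refused_kg_dm,
      n_intake_g = n_intake(.data$dmi_kg, .data$pasture_cp_pct, .data$urea_g,
                            urea_n_fraction),
      fecal_n_g = fecal_n(.data$fecal_wet_kg, .data$fecal_n_g_per_kg,
                          conc_basis = fecal_conc_basis, mass_basis = "wet",
                          dm_pct = .data$fecal_dm_pct),
      milk_n_g = milk_n(.data$milk_yield_kg, .data$milk_cp_pct),
      urine_n_est_g = .data$n_intake_g - (.data$fecal_n_g + .data$milk_n_g),
      flag_negative_urine = .data$urine_n_est_g < 0,
      diet_cp_pct = diet_cp_pct(.data$n_intake_g, .data$dmi_kg)
    )
  if (any(out$flag_negative_urine)) {
    warning(sprintf("%d cow-day(s) with negative estimated urine N; flagged",
                    sum(out$flag_negative_urine)), call. = FALSE)
  }
  out$urine_n_conc_g_per_l <- if ("urine_volume_l" %in% names(records)) {
    out$urine_n_est_g / records$urine_volume_l
  } else {
    NA_real_
  }
  keep <- c("cow_id", "day", "dmi_kg", "n_intake_g", "fecal_n_g", "milk_n_g",
            "urine_n_est_g", "diet_cp_pct", "urine_n_conc_g_per_l",
            "flag_negative_urine")
  if ("treatment" %in% names(out)) keep <- append(keep, "treatment", after = 1)
  dplyr::select(out, dplyr::all_of(keep))
}
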