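#' Simulation configuration for the two-phase urea-supplementation experiment
#'
#' Collects every true parameter, noise scale, count and seed used by
#' [simulate_phase1()] and [simulate_phase2()]. Defaults reproduce the study
#' conditions: 5 cows per treatment, a 21-day stepped urea acclimation during
#' the grazing phase, a 7-day total-collection stall phase, a piecewise
#' milk-yield dose-response with its breakpoint at 350 g urea/d, and urinary N
#' that is a linear function of N intake (intercept -174.2 g/d, slope 0.86).
#'
#' @param seed Integer seed controlling all random draws.
#' @param n_cows_per_treatment Cows allocated to each treatment group.
#' @param n_days_phase2 Days of total collection in the metabolism stalls.
#' @param true_splitline Named numeric vector `(intercept, slope_below,
#'   slope_above, breakpoint)` of the true milk-yield dose-response
#'   (kg/d, kg/g, kg/g, g/d).
#' @param true_urine_line Named numeric vector `(intercept, slope)` of the true
#'   urinary-N vs N-intake line (g/d, g/g).
#' @param nonurine_split_fecal Fraction of non-urine N routed to feces (the
#'   remainder appears in milk). Must lie in \[0, 1\].
#' @param urea_n_fraction Nitrogen content of feed-grade urea, g N per g urea.
#' @param noise_sd_milk Residual SD of milk yield per cow-day, kg/d.
#' @param cow_sd_milk SD of the cow-level random intercept in milk yield, kg/d.
#' @param noise_sd_urine Residual SD of the urinary-N balance per cow-day, g/d.
#' @param cow_sd_urine SD of the cow-level random intercept in urinary N, g/d.
#' @param phase2_urea_dose Urea dose (g/d) of the medium-N group during the
#'   stall phase (reduced from the 351 g/d grazing-phase dose).
#' @param phase1_final_doses Named numeric vector of final acclimation doses
#'   (g/d) by treatment.
#' @param pasture Per-phase pasture composition distributions, as produced by
#'   [pasture_distributions()].
#'
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 42)
#' cfg$true_splitline
#' @export
sim_config <- function(seed = 1L,
                       n_cows_per_treatment = 5L,
                       n_days_phase2 = 7L,
                       true_splitline = c(intercept = 20.5, slope_below = 0.0029,
                                          slope_above = -0.0235, breakpoint = 350),
                       true_urine_line = c(intercept = -174.2, slope = 0.86),
                       nonurine_split_fecal = 0.515,
                       urea_n_fraction = 0.466,
                       noise_sd_milk = 1.5,
                       cow_sd_milk = 1.5,
                       noise_sd_urine = 15,
                       cow_sd_urine = 10,
                       phase2_urea_dose = 250,
                       phase1_final_doses = c(LOW_N = 0, MEDIUM_N = 351, HIGH_N = 690),
                       pasture = pasture_distributions()) {
  stopifnot(length(true_splitline) == 4, length(true_urine_line) == 2)
  names(true_splitline) <- c("intercept", "slope_below", "slope_above", "breakpoint")
  names(true_urine_line) <- c("intercept", "slope")
  if (nonurine_split_fecal < 0 || nonurine_split_fecal > 1) {
    stop("`nonurine_split_fecal` must lie in [0, 1].", call. = FALSE)
  }
  if (urea_n_fraction <= 0 || urea_n_fraction >= 1) {
    stop("`urea_n_fraction` must lie in (0, 1).", call. = FALSE)
  }
  if (n_cows_per_treatment < 1) {
    stop("`n_cows_per_treatment` must be at least 1.", call. = FALSE)
  }
  if (any(c(noise_sd_milk, cow_sd_milk, noise_sd_urine, cow_sd_urine) < 0)) {
    stop("Noise standard deviations must be non-negative.", call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed),
      n_cows_per_treatment = as.integer(n_cows_per_treatment),
      n_days_phase2 = as.integer(n_days_phase2),
      true_splitline = true_splitline,
      true_urine_line = true_urine_line,
      nonurine_split_fecal = nonurine_split_fecal,
      urea_n_fraction = urea_n_fraction,
      noise_sd_milk = noise_sd_milk,
      cow_sd_milk = cow_sd_milk,
      noise_sd_urine = noise_sd_urine,
      cow_sd_urine = cow_sd_urine,
      phase2_urea_dose = phase2_urea_dose,
      phase1_final_doses = phase1_final_doses,
      pasture = pasture,
      # static cow-trait distributions (mean, sd): mid-lactation multiparous herd
      cow_traits = list(dim = c(103, 9.4), bw = c(505, 10.4), bcs = c(4.1, 0.04))
    ),
    class = "sim_config"
  )
}

#' Per-phase pasture composition distributions
#'
#' Mean and SD of each composition variable of the fresh ryegrass pasture
#' offered in each phase, on a dry-matter basis. Defaults are the herd-test
#' values of the emulated study: a slightly richer sward during grazing
#' (CP 20.7% of DM, ME 11.8 MJ/kg DM) and a leafier cut-and-carry sward during
#' the stall phase (CP 18.4% of DM, ME 12.0 MJ/kg DM).
#'
#' @param phase1,phase2 Named list of `c(mean, sd)` pairs for `cp_pct`,
#'   `ndf_pct`, `adf_pct`, `nsc_pct`, `dmd_pct` (all % of DM) and `me`
#'   (MJ/kg DM).
#' @return A list with elements `phase1` and `phase2`.
#' @export
pasture_distributions <- function(
    phase1 = list(cp_pct = c(20.7, 0.56), ndf_pct = c(39.5, 0.52),
                  adf_pct = c(21.8, 0.36), nsc_pct = c(19.6, 0.69),
                  dmd_pct = c(83.3, 0.45), me = c(11.8, 0.06)),
    phase2 = list(cp_pct = c(18.4, 1.69), ndf_pct = c(43.1, 1.10),
                  adf_pct = c(25.3, 0.89), nsc_pct = c(22.7, 2.41),
                  dmd_pct = c(79.0, 0.72), me = c(12.0, 0.13))) {
  list(phase1 = phase1, phase2 = phase2)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, "\n")
  cat("  cows/treatment:", x$n_cows_per_treatment,
      " stall days:", x$n_days_phase2, "\n")
  cat(sprintf("  true split-line: y = %.3g %+.4g*min(x,%g) %+.4g*max(x-%g,0)\n",
              x$true_splitline["intercept"], x$true_splitline["slope_below"],
              x$true_splitline["breakpoint"], x$true_splitline["slope_above"],
              x$true_splitline["breakpoint"]))
  cat(sprintf("  true urine line: urineN = %.4g %+.3g * N intake\n",
              x$true_urine_line["intercept"], x$true_urine_line["slope"]))
  cat(sprintf("  noise SD (milk day/cow, urine day/cow): %.3g/%.3g, %.3g/%.3g\n",
              x$noise_sd_milk, x$cow_sd_milk, x$noise_sd_urine, x$cow_sd_urine))
  invisible(x)
}

# internal: truncate a draw at a lower bound, warning when clipping occurred
clip_at <- function(x, lower, what) {
  bad <- x < lower
  if (any(bad)) {
    warning(sprintf("%d %s value(s) below %g clipped", sum(bad), what, lower),
            call. = FALSE)
    x[bad] <- lower
  }
  x
}
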