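#' Pooled regression of estimated urinary N on N intake
#'
#' Ordinary least squares of `urine_n_est_g` on `n_intake_g`, pooling all
#' cow-days (each point is one cow on one day). This is the headline
#' N-partitioning relationship: at the study's intake range urinary N rises
#' linearly with N intake, so dietary N above requirements is excreted almost
#' entirely in urine. Set `per_cow = TRUE` to average each cow's days first.
#'
#' @param balance An N-balance tibble from [n_balance()] (needs finite
#'   `n_intake_g` and `urine_n_est_g`).
#' @param per_cow Aggregate to per-cow means before fitting (default `FALSE`).
#' @return An object of class `urine_fit`: `intercept`, `slope`, `r2`,
#'   `se_intercept`, `se_slope`, `n`, `p_value_slope`, plus the underlying
#'   `lm` object as `fit`.
#' @examples
#' simulate_phase2(sim_config(seed = 2)) |> n_balance() |> fit_urine_regression()
#' @export
fit_urine_regression <- function(balance, per_cow = FALSE) {
  d <- dplyr::filter(balance, is.finite(.data$n_intake_g),
                     is.finite(.data$urine_n_est_g))
  if (per_cow) {
    d <- d |>
      dplyr::group_by(.data$cow_id) |>
      dplyr::summarise(n_intake_g = mean(.data$n_intake_g),
                       urine_n_est_g = mean(.data$urine_n_est_g),
                       .groups = "drop")
  }
  if (nrow(d) < 3) stop("Need at least 3 cow-day rows.", call. = FALSE)
  if (stats::var(d$n_intake_g) == 0) {
    stop("N intake has zero variance; regression is degenerate.", call. = FALSE)
  }
  fit <- stats::lm(urine_n_est_g ~ n_intake_g, data = d)
  sm <- suppressWarnings(summary(fit)) # zero-residual fits warn harmlessly
  cf <- sm$coefficients
  tss <- sum((d$urine_n_est_g - mean(d$urine_n_est_g))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 0
  structure(
    list(
      intercept = unname(cf[1, 1]), slope = unname(cf[2, 1]),
      se_intercept = unname(cf[1, 2]), se_slope = unname(cf[2, 2]),
      r2 = r2, n = nrow(d),
      p_value_slope = unname(cf[2, 4]),
      fit = fit, data = d
    ),
    class = "urine_fit"
  )
}

#' @export
print.urine_fit <- function(x, ...) {
  cat("Urinary N ~ N intake (pooled OLS over cow-days)\n")
  cat(sprintf("  urine N = %.4g %+.4g * N intake   (g/d)\n", x$intercept, x$slope))
  cat(sprintf("  R-sq: %.3f   n: %d   slope p-value: %.3g\n",
              x$r2, x$n, x$p_value_slope))
  invisible(x)
}

#' Tidy a urinary-N regression
#' @param x A `urine_fit`.
#' @param ... Ignored.
#' @return A tibble with one row per coefficient.
#' @export
tidy.urine_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$se_intercept, x$se_slope)
  )
}

#' Glance at a urinary-N regression
#' @param x A `urine_fit`.
#' @param ... Ignored.
#' @return A one-row tibble of fit summaries.
#' @export
glance.urine_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r2, nobs = x$n, p.value.slope = x$p_value_slope)
}

#' Plot a urinary-N regression
#' @param object A `urine_fit`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.urine_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$n_intake_g, y = .data$urine_n_est_g)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "N intake (g/d)", y = "Estimated urine N (g/d)",
                  title = sprintf("urine N = %.1f %+.2f x intake, R-sq = %.2f",
                                  object$intercept, object$slope, object$r2)) +
    ggplot2::theme_minimal()
}

#' Repeated-measures treatment comparison for one balance parameter
#'
#' Fits a linear mixed model with a fixed treatment effect and a random cow
#' intercept (REML), the classical animal-as-experimental-unit analysis of a
#' repeated-measures design, and reports least-squares treatment means, the
#' standard error of the mean and the treatment p-value with a between-cow
#' denominator (cows minus treatments). On degenerate inputs whose residual
#' variance is essentially zero (e.g. noise-free simulations) the mixed model
#' cannot be estimated and the LS means fall back to direct cell means with
#' SEM 0.
#'
#' @param records A tibble with `cow_id`, `treatment` and the parameter
#'   column; typically an [n_balance()] result.
#' @param parameter Column to compare, as a string (e.g. `"n_intake_g"`).
#' @return A one-row tibble: `parameter`, one `lsmean_<group>` column per
#'   treatment, `sem`, `p_value`, `n_cows`, `n_days`.
#' @examples
#' simulate_phase2(sim_config(seed = 5)) |>
#'   n_balance() |>
#'   compare_treatments("n_intake_g")
#' @export
compare_treatments <- function(records, parameter) {
  stopifnot(is.character(parameter), length(parameter) == 1)
  if (!parameter %in% names(records)) {
    stop(sprintf("Column `%s` not found in records.", parameter), call. = FALSE)
  }
  d <- tibble::tibble(
    cow_id = as.character(records$cow_id),
    treatment = factor(records$treatment),
    value = records[[parameter]]
  )
  counts <- dplyr::count(d, .data$treatment, .data$cow_id)
  cows_per_tr <- dplyr::count(dplyr::distinct(d, .data$treatment, .data$cow_id),
                              .data$treatment)
  if (any(cows_per_tr$n < 2)) {
    stop("Each treatment needs at least 2 cows.", call. = FALSE)
  }
  if (any(counts$n < 2)) {
    stop("Each cow needs at least 2 days of records.", call. = FALSE)
  }
  n_cows <- dplyr::n_distinct(d$cow_id)
  n_tr <- nlevels(d$treatment)
  ddf <- n_cows - n_tr

  mm <- tryCatch({
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(value ~ treatment + (1 | cow_id), data = d, REML = TRUE)))
    if (stats::sigma(fit) < 1e-8) stop("zero residual variance")
    em <- emmeans::emmeans(fit, "treatment")
    es <- summary(em)
    aov_tab <- stats::anova(fit)
    fval <- aov_tab[["F value"]][1]
    list(means = stats::setNames(es$emmean, as.character(es$treatment)),
         sem = mean(es$SE),
         p = stats::pf(fval, n_tr - 1, ddf, lower.tail = FALSE))
  }, error = function(e) NULL)

  if (is.null(mm)) {
    # degenerate fallback: direct cell means (equal to LS means here because
    # every cow appears in exactly one treatment)
    cm <- d |>
      dplyr::group_by(.data$treatment) |>
      dplyr::summarise(m = mean(.data$value), .groups = "drop")
    means <- stats::setNames(cm$m, as.character(cm$treatment))
    p <- if (max(means) - min(means) < 1e-10 * max(1, abs(mean(means)))) 1 else 0
    mm <- list(means = means, sem = 0, p = p)
  }

  out <- tibble::tibble(parameter = parameter)
  for (tr in names(mm$means)) {
    nm <- paste0("lsmean_", tolower(sub("_N$", "", tr)))
    out[[nm]] <- unname(mm$means[[tr]])
  }
  out$sem <- mm$sem
  out$p_value <- mm$p
  out$n_cows <- n_cows
  out$n_days <- max(counts$n)
  out
}

#' Skewness screen for approximate normality
#'
#' Adjusted Fisher-Pearson sample skewness with a pass/fail flag at a
#' configurable absolute threshold, mirroring the routine pre-ANOVA check
#' that balance variables are not grossly asymmetric.
#'
#' @param values Numeric vector, at least 8 finite values, non-constant.
#' @param threshold Absolute skewness above which the screen fails
#'   (default 1).
#' @return A one-row tibble: `skewness`, `threshold`, `pass`, `n`.
#' @examples
#' normality_screen(rnorm(50))
#' @export
normality_screen <- function(values, threshold = 1) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 8) stop("Need at least 8 finite values.", call. = FALSE)
  if (stats::sd(values) == 0) {
    stop("Skewness is undefined for a constant vector.", call. = FALSE)
  }
  sk <- e1071::skewness(values, type = 2)
  tibble::tibble(skewness = sk, threshold = threshold,
                 pass = abs(sk) <= threshold, n = n)
}
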