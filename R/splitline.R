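#' Fit a continuous two-segment (broken-stick) regression
#'
#' Fits the split-line model
#' `y = intercept + slope_below * min(x, bp) + slope_above * max(x - bp, 0)`
#' by profiling the breakpoint `bp` over a candidate grid: for each candidate
#' the model is an ordinary least-squares fit on the hinge basis
#' `{1, x, max(x - bp, 0)}`, and the candidate minimizing the residual sum of
#' squares wins (ties go to the smallest breakpoint). A refinement pass at
#' 1 g/d resolution within +/-`grid_step` of the grid winner follows. This
#' profiled search is deterministic, which makes the estimator easy to test;
#' it is how the milk-yield response to urea dose is analysed here, with the
#' inflection interpreted as the onset of intake depression.
#'
#' @param data A data frame of dose-response observations.
#' @param x,y Unquoted column names of dose (g/d) and response (kg/d).
#'   Defaults `urea_g` and `milk_yield_kg`.
#' @param candidates Optional numeric vector of candidate breakpoints. By
#'   default, a grid of `grid_step`-spaced multiples spanning the interior of
#'   the observed doses (the two smallest and two largest distinct dose levels
#'   are excluded from the span so each segment keeps support).
#' @param grid_step Grid spacing in dose units (default 10).
#' @param refine Run the 1-unit refinement pass around the grid winner.
#' @return An object of class `splitline_fit` with components `intercept`,
#'   `slope_below`, `slope_above`, `breakpoint`, `sse`, `r2`, `n`,
#'   `p_value_slope_change`, and the profiled `sse_profile` tibble.
#' @examples
#' d <- tibble::tibble(urea_g = rep(c(0, 88, 176, 351, 450, 600, 690), 3))
#' d$milk_yield_kg <- true_milk_yield(d$urea_g)
#' fit_splitline(d)
#' @export
fit_splitline <- function(data, x = urea_g, y = milk_yield_kg,
                          candidates = NULL, grid_step = 10, refine = TRUE) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  n <- length(xv)
  if (n < 5) stop("Need at least 5 observations.", call. = FALSE)
  ux <- sort(unique(xv))
  if (length(ux) < 2) {
    stop("All dose values identical; no dose-response can be fit.",
         call. = FALSE)
  }
  if (is.null(candidates)) {
    if (length(ux) < 5) {
      stop("Need at least 5 distinct dose levels for the default grid; ",
           "supply `candidates` explicitly.", call. = FALSE)
    }
    lo <- ux[3]
    hi <- ux[length(ux) - 2]
    candidates <- seq(ceiling(lo / grid_step) * grid_step,
                      floor(hi / grid_step) * grid_step, by = grid_step)
  }
  candidates <- sort(unique(candidates))
  valid <- vapply(candidates, function(c) {
    length(unique(xv[xv <= c])) >= 2 && length(unique(xv[xv > c])) >= 2
  }, logical(1))
  if (!any(valid)) {
    stop("No candidate breakpoint has at least 2 distinct dose levels on each side.",
         call. = FALSE)
  }
  candidates <- candidates[valid]

  best <- profile_breakpoints(xv, yv, candidates)
  if (refine) {
    fine <- seq(best$breakpoint - grid_step, best$breakpoint + grid_step, by = 1)
    fine <- fine[fine >= min(xv) & fine <= max(xv)]
    fine_ok <- vapply(fine, function(c) {
      length(unique(xv[xv <= c])) >= 2 && length(unique(xv[xv > c])) >= 2
    }, logical(1))
    fine <- setdiff(fine[fine_ok], best$profile$breakpoint)
    if (length(fine) > 0) {
      best2 <- profile_breakpoints(xv, yv, fine)
      profile <- dplyr::arrange(
        dplyr::bind_rows(best$profile, best2$profile), .data$breakpoint)
      # keep the grid winner unless refinement strictly improves beyond ties
      if (!near_tie(best2$sse, best$sse) && best2$sse < best$sse) {
        best <- best2
      }
      best$profile <- profile
    }
  }

  coefs <- hinge_ols(xv, yv, best$breakpoint)
  tss <- sum((yv - mean(yv))^2)
  sse1 <- coefs$sse
  # F-test of the hinge term against the single-line null
  fit0 <- stats::lm.fit(cbind(1, xv), yv)
  sse0 <- sum(fit0$residuals^2)
  p_change <- if (sse1 <= .Machine$double.eps * max(1, sse0)) {
    0
  } else {
    f <- (sse0 - sse1) / (sse1 / (n - 3))
    stats::pf(max(f, 0), 1, n - 3, lower.tail = FALSE)
  }

  structure(
    list(
      intercept = coefs$intercept,
      slope_below = coefs$slope_below,
      slope_above = coefs$slope_above,
      breakpoint = best$breakpoint,
      sse = sse1,
      r2 = if (tss > 0) 1 - sse1 / tss else 0,
      n = n,
      p_value_slope_change = p_change,
      sse_profile = best$profile,
      data = tibble::tibble(x = xv, y = yv)
    ),
    class = "splitline_fit"
  )
}

# internal: OLS on the hinge basis {1, x, max(x - bp, 0)} at a fixed breakpoint
hinge_ols <- function(x, y, bp) {
  X <- cbind(1, x, pmax(x - bp, 0))
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  list(
    intercept = unname(cf[1]),
    slope_below = unname(cf[2]),
    slope_above = unname(cf[2] + cf[3]),
    sse = sum(fit$residuals^2)
  )
}

# internal: SSE profile over candidates; smallest breakpoint wins ties
profile_breakpoints <- function(x, y, candidates) {
  sse <- vapply(candidates, function(c) hinge_ols(x, y, c)$sse, numeric(1))
  tied <- near_tie(sse, min(sse))
  bp <- min(candidates[tied])
  list(
    breakpoint = bp,
    sse = sse[candidates == bp][1],
    profile = tibble::tibble(breakpoint = candidates, sse = sse)
  )
}

near_tie <- function(a, b) abs(a - b) <= 1e-9 * pmax(abs(a), abs(b), 1)

#' Predict from a split-line fit
#'
#' @param object A `splitline_fit`.
#' @param newdata Optional data frame with the dose column `x` (or named as
#'   in the original call); alternatively a numeric vector via `x`.
#' @param x Numeric dose values (used when `newdata` is missing).
#' @param ... Ignored.
#' @return Predicted response values.
#' @export
predict.splitline_fit <- function(object, newdata = NULL, x = NULL, ...) {
  if (is.null(x)) {
    x <- if (is.null(newdata)) object$data$x else newdata[[1]]
  }
  object$intercept + object$slope_below * pmin(x, object$breakpoint) +
    object$slope_above * pmax(x - object$breakpoint, 0)
}

#' Post-breakpoint decline expressed per 100 g of urea
#'
#' The field-standard way to report the drop: kg of milk lost per additional
#' 100 g of urea beyond the breakpoint. Returns `NA` with a warning when the
#' upper segment does not decline.
#'
#' @param fit A `splitline_fit`.
#' @return kg per 100 g, or `NA_real_` when flagged as not a decline.
#' @export
decline_per_100g <- function(fit) {
  stopifnot(inherits(fit, "splitline_fit"))
  if (fit$slope_above >= 0) {
    warning("Upper segment does not decline; no decline rate to report.",
            call. = FALSE)
    return(NA_real_)
  }
  -fit$slope_above * 100
}

#' @export
print.splitline_fit <- function(x, ...) {
  cat("Split-line (broken-stick) fit\n")
  cat(sprintf("  y = %.4g %+.4g * min(x, %g) %+.4g * max(x - %g, 0)\n",
              x$intercept, x$slope_below, x$breakpoint, x$slope_above,
              x$breakpoint))
  cat(sprintf("  breakpoint: %g   n: %d   SSE: %.4g   R-sq: %.3f\n",
              x$breakpoint, x$n, x$sse, x$r2))
  cat(sprintf("  slope-change p-value: %.3g\n", x$p_value_slope_change))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a split-line fit
#' @param x A `splitline_fit`.
#' @param ... Ignored.
#' @return A tibble with one row per parameter.
#' @export
tidy.splitline_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope_below", "slope_above", "breakpoint"),
    estimate = c(x$intercept, x$slope_below, x$slope_above, x$breakpoint)
  )
}

#' Glance at a split-line fit
#' @param x A `splitline_fit`.
#' @param ... Ignored.
#' @return A one-row tibble of fit summaries.
#' @export
glance.splitline_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r2, sse = x$sse, nobs = x$n,
    breakpoint = x$breakpoint,
    p.value.slope.change = x$p_value_slope_change
  )
}

#' Plot a split-line fit
#'
#' Observations, the fitted two-segment line and a dashed vertical marker at
#' the estimated breakpoint.
#'
#' @param object A `splitline_fit`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.splitline_fit <- function(object, ...) {
  grid <- tibble::tibble(
    x = seq(min(object$data$x), max(object$data$x), length.out = 200)
  )
  grid$y <- predict(object, x = grid$x)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid, colour = "firebrick", linewidth = 1) +
    ggplot2::geom_vline(xintercept = object$breakpoint, linetype = "dashed") +
    ggplot2::labs(x = "Urea intake (g/d)", y = "Milk yield (kg/d)",
                  title = sprintf("Breakpoint at %g g/d", object$breakpoint)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
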