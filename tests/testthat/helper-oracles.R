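# Independent brute-force oracles: explicit normal equations, deliberately a
# different computational route than the QR-based fitters in the package.

ols_oracle <- function(X, y) {
  unname(drop(solve(crossprod(X), crossprod(X, y))))
}

hinge_oracle <- function(x, y, bp) {
  cf <- ols_oracle(cbind(1, x, pmax(x - bp, 0)), y)
  list(intercept = cf[1], slope_below = cf[2], slope_above = cf[2] + cf[3],
       sse = sum((y - cbind(1, x, pmax(x - bp, 0)) %*% cf)^2))
}

# direct adjusted Fisher-Pearson skewness
skewness_oracle <- function(x) {
  n <- length(x)
  m <- mean(x)
  s <- sqrt(sum((x - m)^2) / (n - 1))
  g1 <- sum((x - m)^3) / n / (sum((x - m)^2) / n)^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

# noise-free dose-response observations at the acclimation dose levels
noise_free_doses <- function(reps = 1, params = sim_config()$true_splitline) {
  d <- tibble::tibble(urea_g = rep(c(0, 88, 176, 351, 450, 600, 690), reps))
  d$milk_yield_kg <- true_milk_yield(d$urea_g, params)
  d
}

zero_noise_config <- function(seed = 1) {
  sim_config(seed = seed, noise_sd_milk = 0, cow_sd_milk = 0,
             noise_sd_urine = 0, cow_sd_urine = 0)
}

# hand-built balanced stall-phase balance table with known treatment means
balanced_balance <- function(mean_low, mean_medium, n_cows_per = 5, n_days = 7,
                             cow_sd = 0, noise_sd = 0, seed = 1) {
  set.seed(seed)
  cows <- tibble::tibble(
    cow_id = sprintf("B%02d", 1:(2 * n_cows_per)),
    treatment = rep(c("LOW_N", "MEDIUM_N"), each = n_cows_per),
    cow_eff = rnorm(2 * n_cows_per, 0, cow_sd)
  )
  tidyr::crossing(cows, day = seq_len(n_days)) |>
    dplyr::mutate(
      value = ifelse(treatment == "MEDIUM_N", mean_medium, mean_low) +
        cow_eff + rnorm(dplyr::n(), 0, noise_sd)
    )
}
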