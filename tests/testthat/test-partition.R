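test_that("urine regression matches a hand-solved normal-equations oracle", {
  bal <- tibble::tibble(
    cow_id = sprintf("C%02d", 1:5), treatment = "LOW_N", day = 1,
    n_intake_g = c(420, 510, 575, 640, 750),
    urine_n_est_g = c(190, 260, 330, 350, 470)
  )
  fit <- fit_urine_regression(bal)
  orc <- ols_oracle(cbind(1, bal$n_intake_g), bal$urine_n_est_g)
  expect_equal(fit$intercept, orc[1], tolerance = 1e-10)
  expect_equal(fit$slope, orc[2], tolerance = 1e-10)
  expect_equal(fit$n, 5)
})

test_that("constant urine output gives zero slope and zero R-squared", {
  bal <- tibble::tibble(cow_id = "C1", day = 1:10,
                        n_intake_g = seq(400, 700, length.out = 10),
                        urine_n_est_g = 300)
  fit <- fit_urine_regression(bal)
  expect_equal(fit$slope, 0)
  expect_equal(fit$r2, 0)
  degenerate <- dplyr::mutate(bal, n_intake_g = 500)
  expect_error(fit_urine_regression(degenerate), "zero variance")
  expect_error(fit_urine_regression(bal[1:2, ]), "at least 3")
})

test_that("per-cow aggregation averages days before regressing", {
  bal <- n_balance(simulate_phase2(sim_config(seed = 31)))
  fit <- fit_urine_regression(bal, per_cow = TRUE)
  expect_equal(fit$n, 10)
  means <- bal |>
    dplyr::group_by(cow_id) |>
    dplyr::summarise(x = mean(n_intake_g), y = mean(urine_n_est_g))
  orc <- ols_oracle(cbind(1, means$x), means$y)
  expect_equal(fit$slope, orc[2], tolerance = 1e-10)
})

test_that("balanced zero-noise LS means equal the treatment means", {
  d <- balanced_balance(563, 674)
  cmp <- compare_treatments(d, "value")
  expect_equal(cmp$lsmean_low, 563)
  expect_equal(cmp$lsmean_medium, 674)
  expect_lt(cmp$p_value, 0.001)
  expect_equal(cmp$n_cows, 10)
})

test_that("identical treatment groups give no difference and p near 1", {
  d <- balanced_balance(500, 500, cow_sd = 0, noise_sd = 0)
  cmp <- compare_treatments(d, "value")
  expect_equal(cmp$lsmean_low, cmp$lsmean_medium)
  expect_gte(cmp$p_value, 0.99)
})

test_that("mixed-model LS means match direct averaging on balanced designs", {
  for (s in 1:10) {
    d <- balanced_balance(560 + 5 * s, 660 - 3 * s, cow_sd = 12,
                          noise_sd = 18, seed = s)
    cmp <- compare_treatments(d, "value")
    raw <- tapply(d$value, d$treatment, mean)
    expect_equal(cmp$lsmean_low, unname(raw["LOW_N"]), tolerance = 1e-6)
    expect_equal(cmp$lsmean_medium, unname(raw["MEDIUM_N"]), tolerance = 1e-6)
    expect_gt(cmp$sem, 0)
  }
})

test_that("insufficient replication is rejected", {
  d <- balanced_balance(500, 600)
  solo <- dplyr::filter(d, !(treatment == "MEDIUM_N" & cow_id != "B06"))
  expect_error(compare_treatments(solo, "value"), "at least 2 cows")
  one_day <- dplyr::filter(d, day == 1)
  expect_error(compare_treatments(one_day, "value"), "2 days")
  expect_error(compare_treatments(d, "nope"), "not found")
})

test_that("skewness screen matches the direct adjusted Fisher-Pearson formula", {
  sym <- c(-5:-1, 1:5) + 10 # mirror-paired values
  scr <- normality_screen(sym)
  expect_equal(scr$skewness, 0)
  expect_true(scr$pass)
  set.seed(99)
  expo <- rexp(60, rate = 0.5)
  scr2 <- normality_screen(expo)
  expect_equal(scr2$skewness, skewness_oracle(expo), tolerance = 1e-10)
  expect_gt(scr2$skewness, 1)
  expect_false(scr2$pass)
  expect_error(normality_screen(rep(4, 20)), "constant")
  expect_error(normality_screen(rnorm(5)), "at least 8")
})

test_that("regression R-squared declines as balance noise grows", {
  mean_r2 <- vapply(c(0, 20, 60), function(sd) {
    mean(vapply(1:5, function(s) {
      cfg <- sim_config(seed = s, noise_sd_urine = sd, cow_sd_urine = 0)
      fit_urine_regression(n_balance(simulate_phase2(cfg)))$r2
    }, numeric(1)))
  }, numeric(1))
  expect_equal(mean_r2[1], 1)
  expect_true(all(diff(mean_r2) < 0))
})
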