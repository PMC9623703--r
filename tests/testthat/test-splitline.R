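test_that("noise-free dose-response is reconstructed exactly", {
  fit <- fit_splitline(noise_free_doses(reps = 3))
  expect_equal(fit$breakpoint, 350)
  expect_equal(fit$intercept, 20.5)
  expect_equal(fit$slope_below, 0.0029)
  expect_equal(fit$slope_above, -0.0235)
  expect_true(fit$sse < 1e-20)
  expect_equal(fit$r2, 1)
  expect_equal(fit$p_value_slope_change, 0)
  expect_equal(decline_per_100g(fit), 2.35)
})

test_that("profiled fits match the normal-equations oracle at any breakpoint", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(10:50, 1)
    x <- runif(n, 0, 700)
    y <- 20 + 0.01 * x - 0.03 * pmax(x - 400, 0) + rnorm(n, 0, 2)
    bp <- runif(1, quantile(x, 0.25), quantile(x, 0.75))
    fit <- fit_splitline(tibble::tibble(urea_g = x, milk_yield_kg = y),
                         candidates = bp, refine = FALSE)
    orc <- hinge_oracle(x, y, bp)
    expect_equal(fit$intercept, orc$intercept, tolerance = 1e-8)
    expect_equal(fit$slope_below, orc$slope_below, tolerance = 1e-8)
    expect_equal(fit$slope_above, orc$slope_above, tolerance = 1e-8)
    expect_equal(fit$sse, orc$sse, tolerance = 1e-8)
  }
})

test_that("the selected breakpoint minimizes the SSE profile", {
  set.seed(7)
  x <- rep(c(0, 88, 176, 351, 450, 600, 690), 5)
  y <- true_milk_yield(x) + rnorm(length(x), 0, 1.5)
  fit <- fit_splitline(tibble::tibble(urea_g = x, milk_yield_kg = y))
  expect_true(all(fit$sse <= fit$sse_profile$sse + 1e-9))
})

test_that("a single line yields no slope change and the smallest candidate", {
  x <- seq(0, 700, by = 50)
  d <- tibble::tibble(urea_g = x, milk_yield_kg = 18 + 0.004 * x)
  fit <- fit_splitline(d, candidates = c(200, 300, 400, 500))
  expect_equal(fit$slope_below, fit$slope_above, tolerance = 1e-10)
  expect_equal(fit$breakpoint, 200)
})

test_that("predictions are continuous and match the printed arithmetic", {
  fit <- fit_splitline(noise_free_doses())
  expect_equal(predict(fit, x = 0), 20.5)
  expect_equal(predict(fit, x = 350), 21.515)
  expect_equal(predict(fit, x = 690), 13.525)
  # continuity at the breakpoint from both sides
  eps <- 1e-9
  expect_equal(predict(fit, x = 350 - eps), predict(fit, x = 350 + eps),
               tolerance = 1e-6)
})

test_that("decline rate is reported per 100 g and flags non-declines", {
  fit <- fit_splitline(noise_free_doses())
  expect_equal(decline_per_100g(fit), 2.35)
  fit$slope_above <- -0.05
  expect_equal(decline_per_100g(fit), 5.0)
  fit$slope_above <- 0
  expect_warning(flagged <- decline_per_100g(fit), "not decline|does not decline")
  expect_true(is.na(flagged))
})

test_that("degenerate inputs are rejected with informative errors", {
  same_x <- tibble::tibble(urea_g = rep(100, 10), milk_yield_kg = rnorm(10))
  expect_error(fit_splitline(same_x), "identical")
  two_lvl <- tibble::tibble(urea_g = rep(c(0, 700), 5),
                            milk_yield_kg = rnorm(10))
  expect_error(fit_splitline(two_lvl, candidates = 350), "each side")
  expect_error(fit_splitline(noise_free_doses()[1:4, ]), "at least 5")
})

test_that("tidy, glance and autoplot summarize a split-line fit", {
  fit <- fit_splitline(noise_free_doses())
  td <- generics::tidy(fit)
  expect_equal(td$estimate[td$term == "breakpoint"], 350)
  gl <- generics::glance(fit)
  expect_equal(gl$r.squared, 1)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
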