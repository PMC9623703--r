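test_that("maintenance energy follows metabolic body weight", {
  expect_equal(maintenance_mj(505), 59.65633386347631)
  expect_equal(maintenance_mj(256), 35.84) # 256^0.75 = 64 exactly
  expect_equal(maintenance_mj(1), 0.56)
  expect_error(maintenance_mj(0), "positive")
  bw <- seq(300, 700, by = 25)
  expect_true(all(diff(maintenance_mj(bw)) > 0))
})

test_that("activity energy is proportional to body weight and distance", {
  expect_equal(activity_mj(500, 2), 3.7)
  expect_equal(activity_mj(505, 0), 0)
  expect_equal(activity_mj(1000, 1), 3.7)
  expect_error(activity_mj(500, -1), "non-negative")
})

test_that("daily BW change is the OLS slope of weight on day", {
  expect_equal(estimate_daily_bw_change(c(0, 10), c(500, 500)), 0)
  expect_equal(estimate_daily_bw_change(c(0, 7), c(500, 503.5)), 0.5)
  expect_equal(estimate_daily_bw_change(0:2, c(500, 501, 502)), 1.0)
  expect_error(estimate_daily_bw_change(c(3, 3), c(500, 501)), "distinct days")
  expect_equal(bw_change_mj(0, 25), 0)
  expect_equal(bw_change_mj(0.5, 30), 15)
  expect_equal(bw_change_mj(-0.5, 30), -15)
})

test_that("milk energy combines composition, efficiency and unit conversion", {
  expect_equal(milk_energy_mj(0, 0, 0, 0), 0)
  ref <- milk_energy_mj(25, fat_pct = 4.0, cp_pct = 3.3, lactose_pct = 4.8)
  expect_equal(ref, 119.86263736263734) # 0.74171 Mcal/kg x 25 / 0.65 / 0.238
  expect_equal(milk_energy_mj(50, 4.0, 3.3, 4.8), 2 * ref)
  # literal mode preserves the multiply-by-0.238 arithmetic for audit
  expect_equal(milk_energy_mj(25, 4.0, 3.3, 4.8, convert = "literal_mcal"),
               0.74171 * 25 / 0.65 * 0.238)
})

test_that("DMI back-calculation inverts energy intake and components add", {
  expect_equal(back_calculate_dmi(236, 11.8), 20.0)
  expect_equal(back_calculate_dmi(0, 11.8), 0)
  expect_error(back_calculate_dmi(200, 0), "positive")
  dmi <- c(12.3, 17.9, 21.4)
  expect_equal(back_calculate_dmi(dmi * 11.8, 11.8), dmi)
  req <- energy_requirement(bw = 505, km_walked = 2, delta_bw = 0.2,
                            yield_kg = 25, fat_pct = 4, cp_pct = 3.3,
                            lactose_pct = 4.8)
  expect_equal(req$total_mj,
               req$maintenance_mj + req$activity_mj + req$bw_change_mj +
                 req$milk_mj)
})

test_that("phase-1 DMI estimation lands in a plausible grazing range", {
  ph1 <- simulate_phase1(sim_config(seed = 9))
  dmi <- estimate_phase1_dmi(ph1)
  expect_equal(nrow(dmi), nrow(ph1))
  low <- dplyr::filter(dmi, treatment == "LOW_N")
  expect_true(all(low$dmi_kg > 5 & low$dmi_kg < 30))
})
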