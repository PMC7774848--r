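test_that("rodent table yields the published low-pressure mortality threshold", {
  fx <- ref_fixtures()
  expect_equal(mortality_threshold_low(fx$decompression), 58600)
  # no mortality below the 58 kPa magnitude
  sub <- fx$decompression[abs(fx$decompression$delta_p_Pa) < 58000, ]
  expect_true(all(sub$mortality_pct == 0))
  # single-record table returns that record's magnitude
  one <- decompression_records(data.frame(
    species = "rat", mass_g = 168, delta_p_Pa = -60000, duration_s = 0.1,
    hemorrhage_pct = 50, mortality_pct = 20
  ))
  expect_equal(mortality_threshold_low(one), 60000)
  none <- one
  none$mortality_pct <- 0
  expect_error(mortality_threshold_low(none), "mortality")
})

test_that("safety ratios reproduce the published multiples", {
  r10 <- safety_ratio(58600, -7077)
  expect_equal(r10$ratio, 8.28, tolerance = 1e-3)
  expect_gt(r10$ratio, 8)
  expect_equal(safety_ratio(58600, -4057)$rounded, 14)
  expect_equal(safety_ratio(58600, -2477)$rounded, 24)
  expect_equal(safety_ratio(58600, -4556)$rounded, 13)
  expect_equal(safety_ratio(5, 5)$ratio, 1)
  expect_error(safety_ratio(58600, 0), "non-zero")
  # scale invariance
  expect_equal(safety_ratio(58600 * 3.7, -7077 * 3.7)$ratio, r10$ratio)
})

test_that("comparison report covers each mechanism with decreasing ratios in wind", {
  fx <- ref_fixtures()
  rep <- build_report(fx$exposure_reference, fx$decompression, fx$blast)
  expect_equal(nrow(rep), 9)
  expect_setequal(unique(rep$mechanism), c("blade_low", "blade_high", "vortex_low"))
  # 10 m/s high-pressure exposure vs the 20.7 g mouse blast LD50: ~80-fold
  high10 <- rep[rep$u_inf_mps == 10 & rep$mechanism == "blade_high", ]
  expect_equal(high10$threshold_Pa, 184000)
  expect_equal(high10$rounded, 80)
  # 10 m/s vortex minimum vs the rodent threshold: 13-fold
  vtx10 <- rep[rep$u_inf_mps == 10 & rep$mechanism == "vortex_low", ]
  expect_equal(vtx10$rounded, 13)
  # ratios strictly decrease as wind speed (and exposure magnitude) grows
  for (mech in unique(rep$mechanism)) {
    sub <- rep[rep$mechanism == mech, ]
    sub <- sub[order(sub$u_inf_mps), ]
    expect_true(all(diff(sub$ratio) < 0))
  }
  expect_error(build_report(fx$exposure_reference[0, ], fx$decompression, fx$blast),
               "empty|missing")
})

test_that("record validators enforce the documented invariants", {
  expect_error(decompression_records(data.frame(species = "x")), "columns")
  bad <- data.frame(
    species = "rat", mass_g = 168, delta_p_Pa = -60000, duration_s = 0,
    hemorrhage_pct = 10, mortality_pct = 0
  )
  expect_error(decompression_records(bad), "duration")
  badpct <- bad
  badpct$duration_s <- 1
  badpct$mortality_pct <- 120
  expect_error(decompression_records(badpct), "percentages")
  expect_error(blast_records(data.frame(species = "m", mass_g = 20, ld50_Pa = -1)),
               "positive")
})

test_that("allometric helper fits a log-log line through the blast records", {
  fx <- ref_fixtures()
  fit <- ld50_allometric_fit(fx$blast)
  expect_s3_class(fit, "lm")
  expect_gt(coef(fit)[2], 0) # LD50 grows with body mass
  expect_error(ld50_allometric_fit(blast_records(
    data.frame(species = "m", mass_g = 20.7, ld50_Pa = 184000)
  )), "at least 2")
})
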