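test_that("Kutta-Joukowski circulation from lift", {
  expect_equal(circulation_from_lift(0, 1.225, 50), 0)
  expect_equal(circulation_from_lift(1000, 1.225, 50), 16.33, tolerance = 5e-4)
  # doubling density at fixed lift halves the circulation (exact scaling)
  expect_equal(
    circulation_from_lift(1000, 2 * 1.225, 50),
    circulation_from_lift(1000, 1.225, 50) / 2,
    tolerance = 1e-15
  )
  expect_error(circulation_from_lift(10, 1.225, 0), "speed")
  expect_error(circulation_from_lift(10, -1, 10), "rho")
})

test_that("circulation needed for the published vortex-core pressure inverts the pressure law", {
  # algebraic inversion of the vortex pressure equation at r = 0
  rc <- 0.17
  g_req <- sqrt(4556 * 16 * pi * rc^2 / 1.225)
  expect_equal(g_req, 73.5, tolerance = 1e-3)
  vtx <- tip_vortex(g_req, rc)
  expect_equal(vortex_pressure(0, vtx, p_inf = 0), -4556, tolerance = 1e-10)
})

test_that("fixed-point BEM matches a brute-force grid search on the toy rotor", {
  # realistic solidity keeps the solution on the momentum branch, where the
  # grid-search residual oracle is valid
  toy <- toy_rotor(n_stations = 7, chord = 0.3, twist_deg = 0)
  op <- operating_point(8, tsr = 7)
  for (i in c(2, 4, 6)) {
    sol <- solve_bem_section(toy$planform, op, i, toy$polars)
    oracle <- bem_grid_oracle(toy$planform, op, i, toy$polars)
    # agreement to within the oracle's grid resolution
    expect_lt(abs(sol$a - oracle$a), 0.004)
    expect_lt(abs(sol$a_tan - oracle$at), 0.001)
    expect_lt(sol$residual, 1e-8)
  }
})

test_that("reference rotor converges at every station with physical inductions", {
  fx <- ref_fixtures()
  op <- operating_point_for(10)
  circ <- spanwise_circulation(fx$planform, op, fx$polars)
  expect_true(all(circ$profile$a > 0 | circ$profile$gamma == 0))
  expect_true(all(circ$profile$a < 0.5))
  # single-peaked distribution with the peak in the outboard half-span
  i_max <- which.max(circ$profile$gamma)
  expect_gt(circ$profile$r_b[i_max], 0.5 * 63)
  expect_lt(circ$profile$r_b[i_max], max(circ$profile$r_b))
  # two algebraic routes to the circulation agree: L'/(rho v) vs 0.5 c cl v
  gamma_alt <- 0.5 * fx$planform$stations$chord_m * circ$profile$cl * circ$profile$v
  expect_equal(circ$profile$gamma, gamma_alt, tolerance = 1e-10)
})

test_that("tip-vortex strength is the spanwise circulation maximum", {
  tri <- data.frame(r_b = 1:5, gamma = c(10, 30, 50, 30, 10))
  expect_equal(tip_vortex_strength(tri), 50)
  expect_error(tip_vortex_strength(tri[0, ]), "empty")
  fx <- ref_fixtures()
  c10 <- spanwise_circulation(fx$planform, operating_point_for(10), fx$polars)
  expect_equal(tip_vortex_strength(c10), max(c10$profile$gamma)) # linear-scan oracle
  # vortex strength grows with wind speed across the scheduled cases
  c5 <- spanwise_circulation(fx$planform, operating_point_for(5), fx$polars)
  expect_gt(tip_vortex_strength(c10), tip_vortex_strength(c5))
})

test_that("toy-rotor circulation matches the per-station closed form and zero-lift cascades", {
  toy <- toy_rotor(n_stations = 6)
  op <- operating_point(8, tsr = 7)
  circ <- spanwise_circulation(toy$planform, op, toy$polars)
  closed <- 0.5 * 1 * circ$profile$cl * circ$profile$v
  expect_equal(circ$profile$gamma, closed, tolerance = 1e-10)
  # zero-lift polar: circulation vanishes everywhere, cascade of zeros
  toy0 <- toy_rotor(zero_lift = TRUE)
  circ0 <- spanwise_circulation(toy0$planform, op, toy0$polars)
  expect_equal(circ0$profile$gamma, rep(0, nrow(circ0$profile)))
  expect_equal(tip_vortex_strength(circ0), 0)
  vtx0 <- tip_vortex(0, core_radius(mean_chord(toy0$planform)))
  expect_equal(vortex_pressure(0, vtx0, p_inf = 0), 0)
})

test_that("ideal toy rotor respects the Betz limit", {
  toy <- toy_rotor(n_stations = 11)
  op <- operating_point(8, tsr = 7)
  circ <- spanwise_circulation(toy$planform, op, toy$polars)
  cp <- power_coefficient(circ, toy$planform, op, toy$polars)
  expect_gt(cp, 0.3) # a sane rotor, not a degenerate one
  expect_lt(cp, 16 / 27 + 1e-6)
})

test_that("degenerate inflow and non-convergence are reported diagnostically", {
  fx <- ref_fixtures()
  expect_error(operating_point(0, tsr = 7), "envelope")
  op <- operating_point_for(10)
  expect_error(
    solve_bem_section(fx$planform, op, 10, fx$polars, max_iter = 3),
    "did not converge.*residual"
  )
  expect_error(
    solve_bem_section(fx$planform, op, 5, list()),
    "no polar"
  )
})
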