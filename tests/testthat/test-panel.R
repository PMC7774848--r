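test_that("symmetric section at zero incidence carries no lift", {
  s <- naca4_coordinates(0.12, 0, 0, n_points = 70)
  sol <- solve_panel(s, 0)
  expect_lt(abs(sol$cl), 1e-3)
  # mirror-symmetric pressure field about the chord line
  pts_up <- cbind(c(0.3, 0.7, 1.5), c(0.2, 0.4, 0.1))
  pts_dn <- cbind(pts_up[, 1], -pts_up[, 2])
  expect_equal(
    field_pressure(sol, pts_up)$p_Pa,
    field_pressure(sol, pts_dn)$p_Pa,
    tolerance = 1e-8
  )
})

test_that("surface speed matches the conformal-map solution within 1% RMS", {
  kt <- kt_case(N = 200)
  sol <- solve_panel(kt$shape, kt$alpha_deg, u_rel = kt$U)
  exact <- kt$exact_speed(sol$mids, kt$th_mid)
  err <- (abs(sol$vt) - exact) / kt$U
  expect_lt(sqrt(mean(err^2)), 0.01)
  expect_equal(sol$cl, kt$cl_exact, tolerance = 0.005)
})

test_that("lift of a thin symmetric section stays near thin-airfoil theory", {
  s <- naca4_coordinates(0.12, 0, 0, n_points = 120)
  sol <- solve_panel(s, 10)
  expect_equal(sol$cl, 2 * pi * (10 * pi / 180), tolerance = 0.10)
})

test_that("pressure integration and circulation give consistent lift", {
  s17 <- naca4_coordinates(0.17, 0.04, 0.4, n_points = 100)
  for (alpha in c(3, 9.2)) {
    sol <- solve_panel(s17, alpha, u_rel = 50)
    expect_equal(cl_from_cp(sol), sol$cl, tolerance = 0.01)
  }
})

test_that("surface pressure coefficient honours the incompressible bounds", {
  s <- naca4_coordinates(0.12, 0, 0, n_points = 100)
  cp <- surface_cp(solve_panel(s, 10))
  expect_lt(max(cp$cp), 1 + 1e-6) # stagnation limit
  expect_gt(max(cp$cp), 0.98) # stagnation point resolved
  # suction peak within the first 5% chord on the upper surface
  up <- cp[cp$side == "upper", ]
  expect_lt(up$x_c[which.min(up$cp)], 0.05)
})

test_that("net source strength vanishes with panel refinement", {
  sums <- vapply(c(60, 120, 240), function(n) {
    s <- naca4_coordinates(0.12, 0, 0, n_points = n)
    sol <- solve_panel(s, 8, u_rel = 1)
    abs(sum(sol$q * sol$lens))
  }, numeric(1))
  expect_lt(sums[3], 2e-3) # relative to U * chord = 1
  expect_true(all(diff(sums) < 0))
})

test_that("off-body field decays to ambient and scales with dynamic pressure", {
  s <- naca4_coordinates(0.17, 0.04, 0.4, n_points = 100)
  sol <- solve_panel(s, 9.2, u_rel = 68.7, chord = 2.31)
  q_dyn <- 0.5 * 1.225 * 68.7^2
  far <- field_pressure(sol, cbind(100 * 2.31, 0))
  expect_lt(abs(far$p_Pa - 101325), 0.001 * q_dyn)
  # doubling u_rel scales every pressure perturbation by exactly 4
  sol2 <- solve_panel(s, 9.2, u_rel = 2 * 68.7, chord = 2.31)
  pts <- cbind(c(0.5, 2.4, -1, 1.2) * 2.31, c(0.4, 0.1, 0.5, -0.6) * 2.31)
  dp1 <- field_pressure(sol, pts)$p_Pa - 101325
  dp2 <- field_pressure(sol2, pts)$p_Pa - 101325
  expect_equal(dp2, 4 * dp1, tolerance = 1e-9)
})

test_that("near-surface field pressure converges to the surface value", {
  s <- naca4_coordinates(0.12, 0, 0, n_points = 100)
  sol <- solve_panel(s, 6, u_rel = 40)
  cp_surf <- surface_cp(sol)
  for (i in c(20, 50, 80)) {
    pt <- sol$mids[i] + sol$normals[i] * 1e-5
    fs <- field_pressure(sol, cbind(Re(pt), Im(pt)))
    expect_equal(fs$cp, cp_surf$cp[i], tolerance = 5e-3)
  }
})

test_that("interior points are flagged instead of returning silent values", {
  s <- naca4_coordinates(0.12, 0, 0, n_points = 70)
  sol <- solve_panel(s, 5)
  res <- field_pressure(sol, cbind(c(0.5, 3), c(0.0, 0.0)))
  expect_true(res$inside[1])
  expect_true(is.na(res$p_Pa[1]))
  expect_false(res$inside[2])
  expect_false(is.na(res$p_Pa[2]))
})

test_that("degenerate geometry and extreme incidence are rejected", {
  s <- naca4_coordinates(0.12, 0, 0, n_points = 70)
  expect_error(solve_panel(s, 30), "alpha")
  dup <- s
  dup$x[2] <- dup$x[1]
  dup$y[2] <- dup$y[1] # repeated node -> zero-length panel
  expect_error(solve_panel(dup, 5), "panel")
})
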