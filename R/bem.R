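#' Bound circulation from sectional lift
#'
#' Kutta-Joukowski relation: the bound circulation of a lifting section equals
#' the lift per unit span divided by air density times the local relative air
#' speed, Gamma = L' / (rho v).
#'
#' @param L_prime lift per unit span (N/m).
#' @param rho air density (kg/m^3).
#' @param v local relative air speed (m/s), > 0.
#' @return Circulation Gamma (m^2/s).
#' @export
circulation_from_lift <- function(L_prime, rho, v) {
  if (any(rho <= 0)) stop("rho must be > 0")
  if (any(v <= 0)) stop("relative air speed must be > 0")
  L_prime / (rho * v)
}

#' Solve blade-element momentum balance at one station
#'
#' Classical blade-element momentum (BEM) solution at a single span station:
#' fixed-point iteration on the axial and tangential induction factors with
#' Prandtl tip and hub loss factors and the Buhl high-induction (Glauert)
#' correction. Deterministic; relaxation 0.3, residual tolerance 1e-8,
#' maximum 500 iterations.
#'
#' @param planform a [blade_planform()].
#' @param op an [operating_point()].
#' @param station one-row data.frame (a row of `planform$stations`), or a
#'   station index.
#' @param polars named list of [polar_table()]s keyed by `airfoil_id`.
#' @param relax relaxation factor for the fixed-point update.
#' @param tol residual tolerance on the induction factors.
#' @param max_iter iteration cap.
#' @return list of class `section_solution`: induction factors `a`, `a_tan`,
#'   inflow angle `phi` (deg), angle of attack `alpha` (deg), `cl`, `cd`,
#'   relative speed `v` (m/s), lift per span `L_prime` (N/m), circulation
#'   `gamma` (m^2/s), and iteration diagnostics.
#' @export
solve_bem_section <- function(planform, op, station, polars,
                              relax = 0.3, tol = 1e-8, max_iter = 500) {
  stopifnot(inherits(planform, "blade_planform"), inherits(op, "operating_point"))
  if (op$u_inf <= 0) stop("BEM requires a positive wind speed")
  if (is.numeric(station) && length(station) == 1) {
    station <- planform$stations[station, , drop = FALSE]
  }
  polar <- polars[[station$airfoil_id]]
  if (is.null(polar)) stop("no polar for airfoil ", station$airfoil_id)

  B <- planform$n_blades
  R <- planform$rotor_radius
  R_hub <- planform$hub_radius
  r <- station$r_b_m
  chord <- station$chord_m
  omega <- rotor_speed(op, R)
  sigma <- B * chord / (2 * pi * r)

  a <- 0.3
  at <- 0
  residuals <- numeric(0)
  converged <- FALSE
  phi <- alpha <- cl <- cd <- v <- NA_real_

  for (iter in seq_len(max_iter)) {
    axial <- op$u_inf * (1 - a)
    tangential <- omega * r * (1 + at)
    phi <- atan2(axial, tangential)
    sphi <- max(abs(sin(phi)), 1e-6)
    cphi <- cos(phi)
    alpha <- phi * 180 / pi - station$twist_deg - op$pitch
    cf <- polar_coeffs(polar, alpha)
    cl <- cf$cl
    cd <- cf$cd
    cn <- cl * cphi + cd * sphi
    ct <- cl * sphi - cd * cphi

    f_tip <- B / 2 * (R - r) / (r * sphi)
    f_hub <- if (R_hub > 0) B / 2 * (r - R_hub) / (R_hub * sphi) else Inf
    F <- (2 / pi) * acos(pmin(1, exp(-f_tip))) *
      (2 / pi) * acos(pmin(1, exp(-f_hub)))
    F <- max(F, 1e-3)

    kappa <- sigma * cn / (4 * F * sphi^2)
    a_new <- kappa / (1 + kappa)
    # Buhl empirical relation past the momentum-theory validity limit
    ct_thrust <- sigma * (1 - a)^2 * cn / sphi^2
    if (a_new > 0.4 && ct_thrust > 0.96 * F) {
      disc <- ct_thrust * (50 - 36 * F) + 12 * F * (3 * F - 4)
      a_new <- (18 * F - 20 - 3 * sqrt(max(disc, 0))) / (36 * F - 50)
    }
    a_new <- min(max(a_new, 0), 0.95)
    kappap <- sigma * ct / (4 * F * sphi * cphi)
    at_new <- kappap / (1 - kappap)
    at_new <- min(max(at_new, -0.5), 0.9)

    res <- max(abs(a_new - a), abs(at_new - at))
    residuals <- c(residuals, res)
    a <- a + relax * (a_new - a)
    at <- at + relax * (at_new - at)
    if (res < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(sprintf(
      "BEM did not converge at r = %.2f m: final residual %.3e (history tail: %s)",
      r, residuals[length(residuals)],
      paste(signif(utils::tail(residuals, 5), 3), collapse = ", ")
    ))
  }

  axial <- op$u_inf * (1 - a)
  tangential <- omega * r * (1 + at)
  v <- sqrt(axial^2 + tangential^2)
  L_prime <- 0.5 * op$rho * v^2 * chord * cl
  gamma <- circulation_from_lift(L_prime, op$rho, v)
  structure(
    list(
      r_b = r, a = a, a_tan = at, phi = phi * 180 / pi, alpha = alpha,
      cl = cl, cd = cd, v = v, L_prime = L_prime, gamma = gamma,
      iterations = length(residuals), residual = residuals[length(residuals)]
    ),
    class = "section_solution"
  )
}

#' Spanwise bound circulation distribution
#'
#' Runs the momentum solver at every aerodynamic station and converts the lift
#' distribution to bound circulation via the Kutta-Joukowski relation. The
#' Prandtl loss factors drive the circulation toward zero at root and tip, so
#' the distribution is single-peaked in the outboard span for the reference
#' blade.
#'
#' @inheritParams solve_bem_section
#' @return Object of class `spanwise_circulation`: data.frame `profile` with
#'   columns `r_b`, `gamma`, `a`, `a_tan`, `alpha`, `cl`, `v`, `L_prime`, plus
#'   `gamma_max` and `r_at_max`.
#' @export
spanwise_circulation <- function(planform, op, polars, ...) {
  sols <- lapply(seq_len(nrow(planform$stations)), function(i) {
    solve_bem_section(planform, op, i, polars, ...)
  })
  profile <- data.frame(
    r_b = vapply(sols, `[[`, numeric(1), "r_b"),
    gamma = vapply(sols, `[[`, numeric(1), "gamma"),
    a = vapply(sols, `[[`, numeric(1), "a"),
    a_tan = vapply(sols, `[[`, numeric(1), "a_tan"),
    alpha = vapply(sols, `[[`, numeric(1), "alpha"),
    cl = vapply(sols, `[[`, numeric(1), "cl"),
    v = vapply(sols, `[[`, numeric(1), "v"),
    L_prime = vapply(sols, `[[`, numeric(1), "L_prime")
  )
  i_max <- which.max(profile$gamma)
  structure(
    list(
      profile = profile,
      gamma_max = profile$gamma[i_max],
      r_at_max = profile$r_b[i_max]
    ),
    class = "spanwise_circulation"
  )
}

#' @export
print.spanwise_circulation <- function(x, ...) {
  cat(sprintf(
    "<spanwise_circulation> %d stations, max Gamma = %.2f m^2/s at r = %.2f m\n",
    nrow(x$profile), x$gamma_max, x$r_at_max
  ))
  invisible(x)
}

#' Blade-tip vortex strength
#'
#' By potential-flow roll-up, the strength of the blade-tip vortex equals the
#' maximum bound circulation along the blade span.
#'
#' @param dist a [spanwise_circulation()] or a data.frame with columns `r_b`
#'   and `gamma`.
#' @return Vortex strength Gamma (m^2/s).
#' @export
tip_vortex_strength <- function(dist) {
  profile <- if (inherits(dist, "spanwise_circulation")) dist$profile else as.data.frame(dist)
  if (nrow(profile) == 0) stop("empty circulation distribution")
  max(profile$gamma)
}

#' Rotor power coefficient from a spanwise solution
#'
#' Integrates the tangential-force torque over the span (trapezoidal rule over
#' the aerodynamic stations) and normalises by the wind kinetic-energy flux
#' through the rotor disc. Used to check the momentum solver against the Betz
#' limit on idealised rotors.
#'
#' @param dist a [spanwise_circulation()].
#' @param planform a [blade_planform()].
#' @param op an [operating_point()].
#' @param polars named polar list (for the drag coefficient at the converged
#'   angle of attack).
#' @return Dimensionless power coefficient.
#' @export
power_coefficient <- function(dist, planform, op, polars) {
  stopifnot(inherits(dist, "spanwise_circulation"))
  prof <- dist$profile
  st <- planform$stations
  omega <- rotor_speed(op, planform$rotor_radius)
  phi <- atan2(op$u_inf * (1 - prof$a), omega * prof$r_b * (1 + prof$a_tan))
  cd <- vapply(seq_len(nrow(st)), function(i) {
    polar_coeffs(polars[[st$airfoil_id[i]]], prof$alpha[i])$cd
  }, numeric(1))
  ct <- prof$cl * sin(phi) - cd * cos(phi)
  dq <- planform$n_blades * 0.5 * op$rho * prof$v^2 * st$chord_m * ct * prof$r_b
  torque <- pracma::trapz(prof$r_b, dq)
  power <- omega * torque
  power / (0.5 * op$rho * op$u_inf^3 * pi * planform$rotor_radius^2)
}
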