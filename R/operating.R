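#' Turbine operating point
#'
#' Bundles the inflow and rotor state used by the aerodynamic stages: wind
#' speed, tip-speed ratio, collective pitch, air density and ambient pressure.
#' Rotor speed follows as Omega = tsr * u_inf / R.
#'
#' @param u_inf wind speed (m/s); must lie within the 3-25 m/s operating
#'   envelope of the reference turbine.
#' @param tsr tip-speed ratio (dimensionless, > 0).
#' @param pitch collective blade pitch (deg).
#' @param rho air density (kg/m^3); default standard sea level 1.225.
#' @param p_inf ambient pressure (Pa); default standard atmosphere 101325.
#' @return An object of class `operating_point`.
#' @export
operating_point <- function(u_inf, tsr, pitch = 0, rho = 1.225, p_inf = 101325) {
  if (!is.numeric(u_inf) || u_inf < 3 || u_inf > 25) {
    stop("wind speed outside the 3-25 m/s operating envelope")
  }
  if (tsr <= 0) stop("tip-speed ratio must be > 0")
  if (rho <= 0 || p_inf <= 0) stop("rho and p_inf must be > 0")
  structure(
    list(u_inf = u_inf, tsr = tsr, pitch = pitch, rho = rho, p_inf = p_inf),
    class = "operating_point"
  )
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf(
    "<operating_point> u_inf = %g m/s, TSR = %g, pitch = %g deg\n",
    x$u_inf, x$tsr, x$pitch
  ))
  invisible(x)
}

# Scheduled operating conditions for the reference turbine at the three study
# wind speeds, plus the 90%-span section state (relative wind speed and angle
# of attack) used by the panel-field stage.
reference_schedule <- function() {
  data.frame(
    u_inf = c(5, 7.5, 10),
    pitch_deg = c(0, 0, 0),
    tsr = c(10.0, 7.7, 7.6),
    u_rel_90 = c(45.3, 52.5, 68.7),
    alpha_90 = c(7.2, 9.1, 9.2)
  )
}

#' Operating point from the reference schedule
#'
#' Looks up the scheduled (tip-speed ratio, pitch) pair for the study wind
#' speeds 5, 7.5 and 10 m/s; for other wind speeds inside the operating
#' envelope the tip-speed ratio and pitch are interpolated linearly (constant
#' beyond the scheduled range).
#'
#' @param u_inf wind speed (m/s) within the 3-25 m/s envelope.
#' @inheritParams operating_point
#' @return An `operating_point`.
#' @export
operating_point_for <- function(u_inf, rho = 1.225, p_inf = 101325) {
  if (!is.numeric(u_inf) || length(u_inf) != 1 || u_inf < 3 || u_inf > 25) {
    stop("wind speed outside the 3-25 m/s operating envelope")
  }
  sched <- reference_schedule()
  tsr <- stats::approx(sched$u_inf, sched$tsr, xout = u_inf, rule = 2)$y
  pitch <- stats::approx(sched$u_inf, sched$pitch_deg, xout = u_inf, rule = 2)$y
  operating_point(u_inf, tsr = tsr, pitch = pitch, rho = rho, p_inf = p_inf)
}

#' 90%-span section state from the reference schedule
#'
#' The relative wind speed and angle of attack at the 90% span station for the
#' scheduled wind speeds. These section states drive the panel-method pressure
#' field; they are authoritative schedule inputs rather than quantities
#' re-derived from the momentum solver.
#'
#' @param u_inf wind speed (m/s), one of the scheduled speeds or interpolated.
#' @return list with `u_rel` (m/s) and `alpha` (deg).
#' @export
section_state_for <- function(u_inf) {
  if (!is.numeric(u_inf) || length(u_inf) != 1 || u_inf < 3 || u_inf > 25) {
    stop("wind speed outside the 3-25 m/s operating envelope")
  }
  sched <- reference_schedule()
  list(
    u_rel = stats::approx(sched$u_inf, sched$u_rel_90, xout = u_inf, rule = 2)$y,
    alpha = stats::approx(sched$u_inf, sched$alpha_90, xout = u_inf, rule = 2)$y
  )
}

#' Rotor angular speed of an operating point
#'
#' @param op an `operating_point`.
#' @param rotor_radius rotor radius (m).
#' @return Omega in rad/s.
#' @export
rotor_speed <- function(op, rotor_radius) {
  stopifnot(inherits(op, "operating_point"))
  op$tsr * op$u_inf / rotor_radius
}

#' Section kinematics
#'
#' Velocity triangle at a span fraction: the local relative wind speed and
#' inflow angle given axial and tangential induction factors,
#' u_rel = sqrt((u_inf (1 - a))^2 + (Omega f R (1 + a'))^2) and
#' phi = atan2(axial, tangential).
#'
#' @param op an `operating_point`.
#' @param f span fraction in (0, 1].
#' @param a axial induction factor, 0 <= a < 1.
#' @param a_tan tangential induction factor.
#' @param rotor_radius rotor radius (m).
#' @return list with `u_rel` (m/s) and `phi` (deg, inflow angle from the rotor
#'   plane).
#' @export
section_kinematics <- function(op, f, a = 0, a_tan = 0, rotor_radius = 63) {
  stopifnot(inherits(op, "operating_point"))
  if (a < 0 || a >= 1) stop("axial induction must lie in [0, 1)")
  omega <- rotor_speed(op, rotor_radius)
  axial <- op$u_inf * (1 - a)
  tangential <- omega * f * rotor_radius * (1 + a_tan)
  list(
    u_rel = sqrt(axial^2 + tangential^2),
    phi = atan2(axial, tangential) * 180 / pi
  )
}
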