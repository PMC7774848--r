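#' Blade-tip vortex model
#'
#' Vatistas (n = 2) vortex: tangential velocity
#' v_theta(r) = Gamma / (2 pi r_c) * rbar / sqrt(1 + rbar^4) with rbar = r/r_c,
#' which integrates through the radial momentum balance dp/dr = rho v_theta^2/r
#' to the closed-form pressure field
#' p(r) - p_inf = rho Gamma^2 / (8 pi^2 r_c^2) * (atan(r^2/r_c^2) - pi/2).
#' The minimum pressure sits at the vortex centre.
#'
#' @param gamma_vortex vortex strength Gamma (m^2/s), >= 0.
#' @param r_c core radius (m), > 0.
#' @param rho air density (kg/m^3).
#' @param core_growth optional core-radius multiplier >= 1 representing
#'   downstream viscous core growth (applied to `r_c`); default 1.
#' @return Object of class `tip_vortex`.
#' @export
tip_vortex <- function(gamma_vortex, r_c, rho = 1.225, core_growth = 1) {
  if (gamma_vortex < 0) stop("vortex strength must be >= 0")
  if (r_c <= 0) stop("core radius must be > 0")
  if (core_growth < 1) stop("core_growth must be >= 1")
  structure(
    list(
      gamma_vortex = gamma_vortex,
      r_c = r_c * core_growth,
      rho = rho,
      core_growth = core_growth
    ),
    class = "tip_vortex"
  )
}

#' @export
print.tip_vortex <- function(x, ...) {
  cat(sprintf(
    "<tip_vortex> Gamma = %.2f m^2/s, r_c = %.3f m, centre dp = %.0f Pa\n",
    x$gamma_vortex, x$r_c, vortex_pressure(0, x, p_inf = 0)
  ))
  invisible(x)
}

#' Tip-vortex core radius from the mean blade chord
#'
#' Martin et al. correlation: r_c = 0.05 * mean chord (times an optional core
#' growth multiplier). For the reference turbine mean chord this gives
#' r_c = 0.17 m.
#'
#' @param mean_chord average blade chord (m), > 0.
#' @param growth core growth multiplier >= 1.
#' @return Core radius (m).
#' @export
core_radius <- function(mean_chord, growth = 1) {
  if (mean_chord <= 0) stop("mean chord must be > 0")
  if (growth < 1) stop("growth must be >= 1")
  0.05 * mean_chord * growth
}

#' Tangential velocity of the tip vortex
#'
#' @param r radial distance from the vortex centre (m), >= 0; vectorized.
#' @param vortex a [tip_vortex()].
#' @return v_theta (m/s).
#' @export
tangential_velocity <- function(r, vortex) {
  stopifnot(inherits(vortex, "tip_vortex"))
  if (any(r < 0)) stop("radius must be >= 0")
  rbar <- r / vortex$r_c
  vortex$gamma_vortex / (2 * pi * vortex$r_c) * rbar / sqrt(1 + rbar^4)
}

#' Pressure in the tip vortex
#'
#' @param r radial distance from the vortex centre (m), >= 0; vectorized.
#' @param vortex a [tip_vortex()].
#' @param p_inf ambient pressure (Pa); use 0 for pressure relative to ambient.
#' @return Pressure (Pa).
#' @export
vortex_pressure <- function(r, vortex, p_inf = 101325) {
  stopifnot(inherits(vortex, "tip_vortex"))
  if (any(r < 0)) stop("radius must be >= 0")
  g <- vortex$gamma_vortex
  rc <- vortex$r_c
  p_inf + vortex$rho * g^2 / (8 * pi^2 * rc^2) * (atan((r / rc)^2) - pi / 2)
}

#' Radial profile of the vortex velocity and pressure deficit
#'
#' @param vortex a [tip_vortex()].
#' @param r_max outer radius (m).
#' @param n number of radial samples.
#' @return data.frame with columns `r_m`, `v_theta_mps`, `dp_Pa`.
#' @export
vortex_profile <- function(vortex, r_max = 50 * vortex$r_c, n = 500) {
  r <- seq(0, r_max, length.out = n)
  data.frame(
    r_m = r,
    v_theta_mps = tangential_velocity(r, vortex),
    dp_Pa = vortex_pressure(r, vortex, p_inf = 0)
  )
}
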