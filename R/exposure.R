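#' Bat particle properties
#'
#' Default values approximate a hoary bat (Lasiurus cinereus): 25 g mass,
#' tissue density 1000 kg/m^3, wing area 0.0117 m^2, lift coefficient 1. The
#' drag coefficient applies to the quasi-steady perturbation force model; the
#' default ballistic tracking ignores all of these except for reporting.
#'
#' @param mass body mass (kg).
#' @param body_density tissue density (kg/m^3).
#' @param wing_area wing planform area (m^2).
#' @param cl lift coefficient (descriptive; particle tracking applies bluff-
#'   body drag to the sphere-equivalent body, so `cl` and `wing_area` do not
#'   alter the paths — consistent with path insensitivity to particle
#'   properties).
#' @param cd drag coefficient of the sphere-equivalent body.
#' @return Object of class `bat_properties`.
#' @export
bat_properties <- function(mass = 0.025, body_density = 1000,
                           wing_area = 0.0117, cl = 1.0, cd = 0.47) {
  vals <- c(mass = mass, body_density = body_density, wing_area = wing_area,
            cl = cl, cd = cd)
  if (any(vals[c("mass", "body_density", "wing_area")] <= 0)) {
    stop("mass, body_density and wing_area must be positive")
  }
  structure(as.list(vals), class = "bat_properties")
}

#' Flight condition
#'
#' @param bat_speed bat flight speed with respect to the wind (m/s), signed
#'   along the wind direction (positive = flying downwind); the canonical
#'   suite uses 0, +/-5, +/-10.
#' @param side which pressure region the paths pass through: `"suction"`
#'   (low-pressure, downwind face) or `"pressure"` (high-pressure, upwind
#'   face).
#' @param lateral_offset path offset (m) perpendicular to the flight
#'   direction; positive offsets move away from the blade surface.
#' @return Object of class `flight_condition`.
#' @export
flight_condition <- function(bat_speed = 10, side = c("suction", "pressure"),
                             lateral_offset = 0) {
  if (abs(bat_speed) > 10) stop("|bat_speed| must be <= 10 m/s for the canonical suite")
  side <- match.arg(side)
  structure(
    list(
      bat_speed = bat_speed,
      side = side,
      approach = if (bat_speed >= 0) "downwind" else "upwind",
      lateral_offset = lateral_offset
    ),
    class = "flight_condition"
  )
}

# internal: velocity vector field of a panel solution at points (m)
field_velocity <- function(sol, pts) {
  p <- complex(real = pts[, 1], imaginary = pts[, 2])
  W <- sol$influence(p)
  w <- sol$u_rel * exp(complex(imaginary = -sol$alpha * pi / 180)) +
    as.vector(W %*% sol$q) + sol$gam * rowSums(-1i * W)
  cbind(Re(w), -Im(w))
}

#' Section-frame exposure field
#'
#' Wraps a panel solution with the kinematic frame used for bat flight paths.
#' In the section frame the air moves at `u_rel` at angle of attack `alpha` to
#' the chord; the wind-axis (axial) direction, along which the bat's own
#' flight speed is added, lies at the inflow angle `phi` from the rotor plane,
#' i.e. at angle `alpha - phi + 90` degrees from the chord.
#'
#' @param sol a [solve_panel()] solution (chord-scaled, in metres).
#' @param phi_deg inflow angle (deg); for the reference section
#'   phi = alpha + twist + pitch.
#' @return Object of class `exposure_field`.
#' @export
exposure_field <- function(sol, phi_deg) {
  stopifnot(inherits(sol, "panel_solution"))
  a <- sol$alpha * pi / 180
  ax <- (sol$alpha - phi_deg + 90) * pi / 180
  # densely resampled contour for strike/clearance geometry
  n_sub <- 8
  fr <- seq(0, 1 - 1 / n_sub, by = 1 / n_sub)
  cx <- as.vector(outer(fr, Re(sol$z2 - sol$z1)) + rep(Re(sol$z1), each = n_sub))
  cy <- as.vector(outer(fr, Im(sol$z2 - sol$z1)) + rep(Im(sol$z1), each = n_sub))
  structure(
    list(
      sol = sol,
      chord = sol$chord,
      u_inf_vec = sol$u_rel * c(cos(a), sin(a)),
      axial_hat = c(cos(ax), sin(ax)),
      origin = c(0.5 * sol$chord, 0),
      contour = cbind(cx, cy)
    ),
    class = "exposure_field"
  )
}

# internal: path frame for a flight condition
path_frame <- function(field, condition) {
  v_bat <- field$u_inf_vec + condition$bat_speed * field$axial_hat
  speed <- sqrt(sum(v_bat^2))
  v_hat <- v_bat / speed
  p_hat <- c(-v_hat[2], v_hat[1]) # +90 deg: points toward the suction side
  sgn <- if (condition$side == "suction") 1 else -1
  list(v_bat = v_bat, speed = speed, v_hat = v_hat, p_hat = p_hat, sgn = sgn)
}

# internal: signed distances of the contour to the path line at offset b
contour_distances <- function(field, fr, b) {
  o <- field$origin + b * fr$sgn * fr$p_hat
  dx <- field$contour[, 1] - o[1]
  dy <- field$contour[, 2] - o[2]
  fr$v_hat[1] * dy - fr$v_hat[2] * dx
}

path_strikes <- function(field, fr, b) {
  d <- contour_distances(field, fr, b)
  min(d) < 0 && max(d) > 0
}

path_clearance <- function(field, fr, b) {
  min(abs(contour_distances(field, fr, b)))
}

#' Release offsets for a family of grazing flight paths
#'
#' Finds, by bisection on the lateral offset, the closest straight flight path
#' that passes the blade without striking it (clearance under
#' `min_clearance_target`, default 1 mm), then steps outward by `spacing`
#' (default 20 mm) for the remaining paths, the farthest landing near
#' `max_offset` (default 100 mm) from the surface.
#'
#' @param field an [exposure_field()].
#' @param condition a [flight_condition()].
#' @param n_paths number of paths (>= 1).
#' @param spacing offset step between successive paths (m).
#' @param min_clearance_target upper bound on the closest path's clearance (m).
#' @param max_offset approximate clearance of the farthest path (m).
#' @return Numeric vector of lateral offsets (m, unsigned, closest first) with
#'   attribute `clearance` = measured clearance of the closest path.
#' @export
release_offsets <- function(field, condition, n_paths = 6, spacing = 0.020,
                            min_clearance_target = 0.001, max_offset = 0.100) {
  stopifnot(inherits(field, "exposure_field"), inherits(condition, "flight_condition"))
  if (n_paths < 1) stop("n_paths must be >= 1")
  if (spacing <= 0 || min_clearance_target <= 0) stop("spacing and clearance target must be > 0")
  fr <- path_frame(field, condition)
  b_lo <- 0
  if (!path_strikes(field, fr, b_lo)) {
    stop("bisection cannot bracket: the zero-offset path does not strike the blade")
  }
  b_hi <- 0.3 * field$chord
  if (path_strikes(field, fr, b_hi)) {
    stop("bisection cannot bracket: no clear path found within 0.3 chord")
  }
  for (i in 1:60) {
    b_mid <- (b_lo + b_hi) / 2
    if (path_strikes(field, fr, b_mid)) b_lo <- b_mid else b_hi <- b_mid
    if (b_hi - b_lo < min_clearance_target / 10 &&
        path_clearance(field, fr, b_hi) < min_clearance_target) {
      break
    }
  }
  clr <- path_clearance(field, fr, b_hi)
  if (path_strikes(field, fr, b_hi) || clr <= 0 || clr >= min_clearance_target) {
    stop("bisection failed to find a grazing non-striking path")
  }
  offsets <- b_hi + (seq_len(n_paths) - 1) * spacing
  offsets <- offsets[offsets <= max_offset + b_hi + spacing / 2]
  attr(offsets, "clearance") <- clr
  offsets
}

#' Track a bat-sized particle through the section flow field
#'
#' Straight-line (ballistic) tracking by default: the aerodynamic forces on a
#' bat-sized particle are insignificant compared with its inertia over the
#' fraction of a second it takes to pass the blade, so flight paths are
#' effectively straight in the section frame. A quasi-steady perturbation
#' force model (`mode = "forces"`, classical 4th-order Runge-Kutta) is
#' available to verify that claim: drag and lift act on the *disturbance* of
#' the local air velocity relative to the undisturbed freestream, i.e. the
#' unbalanced part of the aerodynamic load on a bat trimmed for steady flight.
#'
#' @param field an [exposure_field()].
#' @param bat a [bat_properties()].
#' @param condition a [flight_condition()] (its `lateral_offset` places the
#'   path).
#' @param dt time step (s); default chord / (400 u_rel).
#' @param mode `"ballistic"` or `"forces"`.
#' @param s_half half-length of the tracked path (m); default 6 chords.
#' @return Object of class `flight_path`: data.frame `samples` (t_s, x_m, y_m,
#'   vx_mps, vy_mps), `struck` flag, `min_clearance` (m).
#' @export
integrate_path <- function(field, bat = bat_properties(),
                           condition = flight_condition(),
                           dt = NULL, mode = c("ballistic", "forces"),
                           s_half = 6 * field$chord) {
  stopifnot(inherits(field, "exposure_field"))
  mode <- match.arg(mode)
  if (!is.null(dt) && dt <= 0) stop("dt must be > 0")
  fr <- path_frame(field, condition)
  b <- condition$lateral_offset
  if (is.null(dt)) dt <- field$chord / (400 * field$sol$u_rel)
  start <- field$origin + b * fr$sgn * fr$p_hat - s_half * fr$v_hat
  if (pracma::inpolygon(start[1], start[2], Re(field$sol$z1), Im(field$sol$z1))) {
    stop("release point lies inside the airfoil contour")
  }
  n_steps <- ceiling(2 * s_half / (fr$speed * dt))
  t <- seq(0, by = dt, length.out = n_steps + 1)

  if (mode == "ballistic") {
    x <- start[1] + fr$v_bat[1] * t
    y <- start[2] + fr$v_bat[2] * t
    vx <- rep(fr$v_bat[1], length(t))
    vy <- rep(fr$v_bat[2], length(t))
  } else {
    # quasi-steady drag on the sphere-equivalent body (frontal area from mass
    # and tissue density), acting on the disturbance of the local air velocity
    # relative to the undisturbed freestream: the unbalanced part of the load
    # on a bat trimmed for steady flight
    diam <- (6 * bat$mass / (pi * bat$body_density))^(1 / 3)
    a_frontal <- pi * diam^2 / 4
    accel <- function(pos, vel) {
      du <- field_velocity(field$sol, matrix(pos, 1))[1, ] - field$u_inf_vec -
        (vel - fr$v_bat)
      sp <- sqrt(sum(du^2))
      0.5 * field$sol$rho * bat$cd * a_frontal * sp * du / bat$mass
    }
    x <- y <- vx <- vy <- numeric(length(t))
    pos <- start
    vel <- fr$v_bat
    x[1] <- pos[1]; y[1] <- pos[2]; vx[1] <- vel[1]; vy[1] <- vel[2]
    for (i in seq_len(n_steps)) {
      k1v <- accel(pos, vel);               k1x <- vel
      k2v <- accel(pos + dt / 2 * k1x, vel + dt / 2 * k1v); k2x <- vel + dt / 2 * k1v
      k3v <- accel(pos + dt / 2 * k2x, vel + dt / 2 * k2v); k3x <- vel + dt / 2 * k2v
      k4v <- accel(pos + dt * k3x, vel + dt * k3v);         k4x <- vel + dt * k3v
      pos <- pos + dt / 6 * (k1x + 2 * k2x + 2 * k3x + k4x)
      vel <- vel + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v)
      x[i + 1] <- pos[1]; y[i + 1] <- pos[2]; vx[i + 1] <- vel[1]; vy[i + 1] <- vel[2]
    }
  }

  samples <- data.frame(t_s = t, x_m = x, y_m = y, vx_mps = vx, vy_mps = vy)

  # strike detection: first crossing of the contour
  struck <- FALSE
  zs <- field$sol$z1
  ze <- field$sol$z2
  inside <- pracma::inpolygon(samples$x_m, samples$y_m, Re(zs), Im(zs))
  if (any(inside)) {
    struck <- TRUE
    i_in <- which(inside)[1]
    # refine crossing point on the entering segment
    p1 <- c(samples$x_m[i_in - 1], samples$y_m[i_in - 1])
    p2 <- c(samples$x_m[i_in], samples$y_m[i_in])
    hit <- segment_contour_hit(p1, p2, zs, ze)
    samples <- samples[seq_len(i_in - 1), , drop = FALSE]
    if (!is.null(hit)) {
      tc <- samples$t_s[nrow(samples)] + hit$u * dt
      samples <- rbind(samples, data.frame(
        t_s = tc, x_m = hit$p[1], y_m = hit$p[2],
        vx_mps = samples$vx_mps[nrow(samples)],
        vy_mps = samples$vy_mps[nrow(samples)]
      ))
    }
  }

  # clearance = minimum distance from the path polyline to the resampled
  # contour; for straight (ballistic) paths this is the exact point-to-line
  # distance, otherwise point-to-segment over the near-blade samples
  min_clearance <- if (mode == "ballistic" && !struck) {
    v_hat <- fr$v_bat / fr$speed
    min(abs(v_hat[1] * (field$contour[, 2] - start[2]) -
              v_hat[2] * (field$contour[, 1] - start[1])))
  } else {
    near <- which(abs(samples$x_m - field$origin[1]) < 1.5 * field$chord)
    if (length(near) > 1) {
      p1x <- samples$x_m[near[-length(near)]]; p1y <- samples$y_m[near[-length(near)]]
      dx <- diff(samples$x_m[near]); dy <- diff(samples$y_m[near])
      len2 <- pmax(dx^2 + dy^2, 1e-300)
      min(vapply(seq_len(nrow(field$contour)), function(i) {
        tt <- pmin(pmax(((field$contour[i, 1] - p1x) * dx +
                           (field$contour[i, 2] - p1y) * dy) / len2, 0), 1)
        min((field$contour[i, 1] - (p1x + tt * dx))^2 +
              (field$contour[i, 2] - (p1y + tt * dy))^2)
      }, numeric(1)))^0.5
    } else {
      Inf
    }
  }

  structure(
    list(samples = samples, struck = struck, min_clearance = min_clearance,
         condition = condition, dt = dt),
    class = "flight_path"
  )
}

# internal: earliest intersection of segment p1->p2 with the contour
segment_contour_hit <- function(p1, p2, zs, ze) {
  d <- p2 - p1
  ax <- Re(zs); ay <- Im(zs)
  bx <- Re(ze) - ax; by <- Im(ze) - ay
  den <- d[1] * (-by) - d[2] * (-bx)
  ok <- abs(den) > 1e-300
  u <- ((ax - p1[1]) * (-by) - (ay - p1[2]) * (-bx)) / den
  v <- (d[1] * (ay - p1[2]) - d[2] * (ax - p1[1])) / den
  hit <- ok & u >= 0 & u <= 1 & v >= 0 & v <= 1
  if (!any(hit)) return(NULL)
  u_min <- min(u[hit])
  list(u = u_min, p = p1 + u_min * d)
}

#' Pressure-time trace along a flight path
#'
#' Samples the field pressure at the path positions and shifts the time axis
#' so the global pressure extreme (largest |p - p_inf|) occurs at t = 0.
#'
#' @param path a [integrate_path()] result (non-struck, or its pre-strike
#'   samples are used).
#' @param field an [exposure_field()].
#' @return Object of class `pressure_trace`: data.frame `samples` (t_s, p_Pa),
#'   plus `p_inf` and the sampling step `dt`.
#' @export
trace_pressure <- function(path, field) {
  stopifnot(inherits(path, "flight_path"), inherits(field, "exposure_field"))
  if (nrow(path$samples) == 0) stop("empty flight path")
  fp <- field_pressure(field$sol, path$samples[, c("x_m", "y_m")])
  p <- fp$p_Pa
  keep <- !is.na(p)
  p <- p[keep]
  t <- path$samples$t_s[keep]
  if (length(p) == 0) stop("no valid pressure samples along the path")
  i_ext <- which.max(abs(p - field$sol$p_inf))
  structure(
    list(
      samples = data.frame(t_s = t - t[i_ext], p_Pa = p),
      p_inf = field$sol$p_inf,
      dt = path$dt
    ),
    class = "pressure_trace"
  )
}

#' @export
print.pressure_trace <- function(x, ...) {
  dp <- x$samples$p_Pa - x$p_inf
  cat(sprintf(
    "<pressure_trace> %d samples, dp range [%.0f, %.0f] Pa\n",
    nrow(x$samples), min(dp), max(dp)
  ))
  invisible(x)
}

#' Exposure metrics of a pressure trace
#'
#' Durations are measured against the ambient band |p - p_inf| <=
#' band_fraction * p_inf (default 5% of atmospheric, ~5066 Pa): `t_rise` from
#' the last in-band sample before the extreme to the extreme, `t_recover`
#' from the extreme to the first in-band sample after it, `t_outside_band`
#' the total duration spent outside the band over the whole trace.
#'
#' @param trace a [trace_pressure()] result.
#' @param p_inf ambient pressure (Pa); defaults to the trace's.
#' @param band_fraction half-width of the ambient band as a fraction of
#'   `p_inf`.
#' @return Object of class `exposure_metrics`: list with `p_min`, `p_max`
#'   (Pa), `t_rise`, `t_recover`, `t_outside_band` (s), `band_Pa`.
#' @export
exposure_metrics <- function(trace, p_inf = trace$p_inf, band_fraction = 0.05) {
  stopifnot(inherits(trace, "pressure_trace"))
  if (nrow(trace$samples) == 0) stop("empty trace")
  t <- trace$samples$t_s
  p <- trace$samples$p_Pa
  band <- band_fraction * p_inf
  outside <- abs(p - p_inf) > band
  dt <- trace$dt
  i0 <- which.min(abs(t)) # extreme sits at t = 0 by construction
  t_rise <- if (any(!outside & t < t[i0])) t[i0] - max(t[!outside & t < t[i0]]) else 0
  t_recover <- if (any(!outside & t > t[i0])) min(t[!outside & t > t[i0]]) - t[i0] else 0
  if (!outside[i0]) t_rise <- t_recover <- 0
  structure(
    list(
      p_min = min(p), p_max = max(p),
      t_rise = t_rise, t_recover = t_recover,
      t_outside_band = sum(outside) * dt,
      band_Pa = band
    ),
    class = "exposure_metrics"
  )
}

#' @export
print.exposure_metrics <- function(x, ...) {
  cat(sprintf(
    "<exposure_metrics> p in [%.0f, %.0f] Pa; outside band %.4f s (rise %.4f, recover %.4f)\n",
    x$p_min, x$p_max, x$t_outside_band, x$t_rise, x$t_recover
  ))
  invisible(x)
}
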