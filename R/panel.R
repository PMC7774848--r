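#' Hess-Smith panel solution for a blade section
#'
#' Incompressible potential-flow solution around an airfoil: constant-strength
#' source panels plus a uniform vortex sheet, closed by the Kutta condition
#' (equal tangential leaving speeds on the two trailing-edge panels). The
#' geometry is scaled by the section chord so that off-body field queries are
#' in metres; pressures follow from Bernoulli with the supplied density,
#' ambient pressure and relative wind speed.
#'
#' @param shape an [airfoil_shape()] (unit chord).
#' @param alpha angle of attack (deg), |alpha| < 25.
#' @param u_rel relative wind speed (m/s).
#' @param rho air density (kg/m^3).
#' @param p_inf ambient pressure (Pa).
#' @param chord section chord (m); geometry and field queries are scaled by it.
#' @return Object of class `panel_solution`: panel geometry, source strengths,
#'   vortex density, circulation, `cl` (from circulation) and the reference
#'   state.
#' @export
solve_panel <- function(shape, alpha, u_rel = 1, rho = 1.225, p_inf = 101325,
                        chord = 1) {
  stopifnot(inherits(shape, "airfoil_shape"))
  if (abs(alpha) >= 25) stop("|alpha| must be < 25 deg for an attached-flow model")
  if (u_rel <= 0 || chord <= 0) stop("u_rel and chord must be > 0")

  z <- complex(real = shape$x, imaginary = shape$y) * chord
  # drop duplicated closing point if present, then close explicitly
  n <- length(z)
  if (Mod(z[1] - z[n]) < 1e-12 * chord) z <- z[-n]
  z1 <- z
  z2 <- c(z[-1], z[1])
  lens <- Mod(z2 - z1)
  if (any(lens < 1e-12 * chord)) stop("degenerate (zero-length) panel in geometry")
  tangents <- (z2 - z1) / lens
  normals <- tangents * complex(imaginary = -1) # outward for Selig (CCW) order
  mids <- (z1 + z2) / 2
  np <- length(z1)

  a_rad <- alpha * pi / 180
  w_inf <- u_rel * exp(complex(imaginary = -a_rad))

  # conjugate-velocity influence of unit-strength source density on panel j at
  # points p: e^{-i theta_j}/(2 pi) * log((p - z1_j)/(p - z2_j)); the vortex
  # influence is -i times it. Collocation points sit a small distance outside
  # the surface so the self-influence limit is taken numerically.
  influence <- function(p) {
    pm <- matrix(p, nrow = length(p), ncol = np)
    z1m <- matrix(z1, nrow = length(p), ncol = np, byrow = TRUE)
    z2m <- matrix(z2, nrow = length(p), ncol = np, byrow = TRUE)
    tm <- matrix(tangents, nrow = length(p), ncol = np, byrow = TRUE)
    Conj(tm) / (2 * pi) * log((pm - z1m) / (pm - z2m))
  }

  colloc <- mids + normals * (1e-6 * lens)
  W_src <- influence(colloc)
  W_vtx <- -1i * W_src

  # flow tangency: Re(w * n) = 0 at each collocation point
  A <- matrix(0, np + 1, np + 1)
  b <- numeric(np + 1)
  A[1:np, 1:np] <- Re(W_src * normals) # recycles normals over rows
  A[1:np, np + 1] <- Re(rowSums(W_vtx) * normals)
  b[1:np] <- -Re(w_inf * normals)

  # Kutta: tangential speeds on the two TE-adjacent panels cancel
  kutta_src <- Re(W_src[1, ] * tangents[1]) + Re(W_src[np, ] * tangents[np])
  kutta_vtx <- Re(sum(W_vtx[1, ]) * tangents[1]) + Re(sum(W_vtx[np, ]) * tangents[np])
  A[np + 1, 1:np] <- kutta_src
  A[np + 1, np + 1] <- kutta_vtx
  b[np + 1] <- -(Re(w_inf * tangents[1]) + Re(w_inf * tangents[np]))

  sol <- tryCatch(solve(A, b), error = function(e) {
    stop("singular panel system (degenerate geometry?): ", conditionMessage(e))
  })
  q <- sol[1:np]
  gam <- sol[np + 1]

  w_mid <- w_inf + as.vector(W_src %*% q) + gam * rowSums(W_vtx)
  vt <- Re(w_mid * tangents)
  circulation <- -gam * sum(lens) # positive circulation = positive lift
  cl <- 2 * circulation / (u_rel * chord)

  structure(
    list(
      shape = shape, z1 = z1, z2 = z2, lens = lens, tangents = tangents,
      normals = normals, mids = mids, q = q, gam = gam,
      circulation = circulation, cl = cl, vt = vt,
      alpha = alpha, u_rel = u_rel, rho = rho, p_inf = p_inf, chord = chord,
      influence = influence
    ),
    class = "panel_solution"
  )
}

#' @export
print.panel_solution <- function(x, ...) {
  cat(sprintf(
    "<panel_solution> %s: %d panels, alpha = %g deg, u_rel = %g m/s, cl = %.3f\n",
    x$shape$name, length(x$q), x$alpha, x$u_rel, x$cl
  ))
  invisible(x)
}

#' Surface pressure coefficient distribution
#'
#' Pressure coefficient at each panel midpoint from the tangential surface
#' speed, cp = 1 - (v_t / u_rel)^2. The incompressible maximum cp = 1 occurs
#' at the stagnation point.
#'
#' @param sol a [solve_panel()] solution.
#' @return data.frame with columns `x_c` (midpoint x in chord units), `y_c`,
#'   `cp`, `vt` and `side` ("upper"/"lower").
#' @export
surface_cp <- function(sol) {
  stopifnot(inherits(sol, "panel_solution"))
  cp <- 1 - (sol$vt / sol$u_rel)^2
  i_le <- which.min(Re(sol$mids))
  data.frame(
    x_c = Re(sol$mids) / sol$chord,
    y_c = Im(sol$mids) / sol$chord,
    cp = cp,
    vt = sol$vt,
    side = ifelse(seq_along(cp) <= i_le, "upper", "lower")
  )
}

#' Lift coefficient by surface-pressure integration
#'
#' Integrates -cp over the outward normals and projects perpendicular to the
#' freestream; an independent route to `cl` that must agree with the
#' circulation value (Kutta-Joukowski) for a converged solution.
#'
#' @param sol a [solve_panel()] solution.
#' @return Lift coefficient.
#' @export
cl_from_cp <- function(sol) {
  stopifnot(inherits(sol, "panel_solution"))
  cp <- 1 - (sol$vt / sol$u_rel)^2
  cf <- -sum(cp * sol$normals * sol$lens) / sol$chord
  a_rad <- sol$alpha * pi / 180
  Im(cf) * cos(a_rad) - Re(cf) * sin(a_rad)
}

#' Off-body velocity and pressure field
#'
#' Evaluates the panel-induced velocity plus freestream at arbitrary points
#' (in metres, same frame as the scaled geometry) and converts to pressure via
#' Bernoulli. Points falling inside the airfoil contour are flagged and their
#' pressure set to NA rather than returning silent garbage.
#'
#' @param sol a [solve_panel()] solution.
#' @param points data.frame or matrix with columns x, y (m).
#' @return data.frame with `x_m`, `y_m`, `u_mps`, `v_mps`, `p_Pa`, `cp`,
#'   `inside`.
#' @export
field_pressure <- function(sol, points) {
  stopifnot(inherits(sol, "panel_solution"))
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  p <- complex(real = pts[, 1], imaginary = pts[, 2])
  W <- sol$influence(p)
  w <- sol$u_rel * exp(complex(imaginary = -sol$alpha * pi / 180)) +
    as.vector(W %*% sol$q) + sol$gam * rowSums(-1i * W)
  u <- Re(w)
  v <- -Im(w)
  speed2 <- u^2 + v^2
  q_dyn <- 0.5 * sol$rho * sol$u_rel^2
  cp <- 1 - speed2 / sol$u_rel^2
  pr <- sol$p_inf + q_dyn * cp
  inside <- pracma::inpolygon(
    pts[, 1], pts[, 2],
    Re(sol$z1), Im(sol$z1)
  )
  pr[inside] <- NA_real_
  cp[inside] <- NA_real_
  data.frame(
    x_m = pts[, 1], y_m = pts[, 2], u_mps = u, v_mps = v,
    p_Pa = pr, cp = cp, inside = inside
  )
}
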