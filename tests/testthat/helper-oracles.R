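# Shared oracles and fixtures, built in code at test time.

# Karman-Trefftz conformal-map case: an exact potential-flow solution used as
# the independent oracle for the panel method. Returns the shape plus a
# function giving the exact surface speed at arbitrary (normalized) surface
# points.
kt_case <- function(N = 200, mu = complex(real = -0.08, imaginary = 0.08),
                    te_deg = 16, U = 30, alpha_deg = 5) {
  a <- 1
  Rc <- Mod(a - mu)
  nkt <- 2 - te_deg / 180
  th <- Arg(a - mu) + seq(0, 2 * pi, length.out = N + 1)
  zeta <- mu + Rc * exp(1i * th)
  fmap <- function(zc) ((zc - a) / (zc + a))^nkt
  zfun <- function(zc) nkt * a * (1 + fmap(zc)) / (1 - fmap(zc))
  dzdz <- function(zc) {
    fp <- nkt * ((zc - a) / (zc + a))^(nkt - 1) * (2 * a / (zc + a)^2)
    nkt * a * 2 * fp / (1 - fmap(zc))^2
  }
  z <- zfun(zeta)
  xmin <- min(Re(z))
  scale <- max(Re(z)) - xmin
  alpha <- alpha_deg * pi / 180
  beta <- asin(Im(mu) / Rc)
  G <- 4 * pi * U * Rc * sin(alpha + beta) # Kutta-fixing circulation
  exact_speed <- function(mids_norm, th_guess) {
    zm <- (Re(mids_norm) * scale + xmin) + 1i * (Im(mids_norm) * scale)
    zeta_m <- mu + Rc * exp(1i * th_guess)
    for (it in 1:40) zeta_m <- zeta_m - (zfun(zeta_m) - zm) / dzdz(zeta_m)
    wz <- U * (exp(-1i * alpha) - exp(1i * alpha) * Rc^2 / (zeta_m - mu)^2) +
      1i * G / (2 * pi * (zeta_m - mu))
    Mod(wz) / Mod(dzdz(zeta_m))
  }
  list(
    shape = airfoil_shape(Re(z), Im(z), "karman-trefftz"),
    U = U, alpha_deg = alpha_deg,
    cl_exact = 2 * G / (U * scale),
    th_mid = (th[-1] + th[-(N + 1)]) / 2,
    exact_speed = exact_speed
  )
}

# Brute-force grid search over (a, a') minimizing the blade-element/momentum
# balance residual at one station; independent of the fixed-point solver.
bem_grid_oracle <- function(planform, op, station_idx, polars,
                            a_grid = seq(0, 0.5, by = 0.002),
                            at_grid = seq(-0.02, 0.06, by = 5e-4)) {
  st <- planform$stations[station_idx, ]
  polar <- polars[[st$airfoil_id]]
  B <- planform$n_blades
  R <- planform$rotor_radius
  R_hub <- planform$hub_radius
  omega <- op$tsr * op$u_inf / R
  sigma <- B * st$chord_m / (2 * pi * st$r_b_m)
  g <- expand.grid(a = a_grid, at = at_grid)
  phi <- atan2(op$u_inf * (1 - g$a), omega * st$r_b_m * (1 + g$at))
  sphi <- pmax(abs(sin(phi)), 1e-6)
  cphi <- cos(phi)
  alpha <- phi * 180 / pi - st$twist_deg - op$pitch
  cl <- stats::approx(polar$tab$alpha_deg, polar$tab$cl, alpha, rule = 2)$y
  cd <- stats::approx(polar$tab$alpha_deg, polar$tab$cd, alpha, rule = 2)$y
  cn <- cl * cphi + cd * sphi
  ct <- cl * sphi - cd * cphi
  f_tip <- B / 2 * (R - st$r_b_m) / (st$r_b_m * sphi)
  f_hub <- B / 2 * (st$r_b_m - R_hub) / (R_hub * sphi)
  F <- (2 / pi) * acos(pmin(1, exp(-f_tip))) * (2 / pi) * acos(pmin(1, exp(-f_hub)))
  kappa <- sigma * cn / (4 * F * sphi^2)
  kappap <- sigma * ct / (4 * F * sphi * cphi)
  res <- abs(kappa / (1 + kappa) - g$a) + abs(kappap / (1 - kappap) - g$at)
  g[which.min(res), ]
}

ref_fixtures <- function() {
  if (is.null(.fixture_cache$fx)) .fixture_cache$fx <- reference_fixture_set()
  .fixture_cache$fx
}

# cached 90%-span exposure field at a scheduled wind speed
ref_field <- function(u_inf) {
  key <- paste0("field_", u_inf)
  if (is.null(.fixture_cache[[key]])) {
    fx <- ref_fixtures()
    st <- section_at_fraction(fx$planform, 0.9)
    state <- section_state_for(u_inf)
    sol <- solve_panel(fx$shape, state$alpha, state$u_rel, chord = st$chord_m)
    .fixture_cache[[key]] <- exposure_field(sol, phi_deg = state$alpha + st$twist_deg)
  }
  .fixture_cache[[key]]
}

.fixture_cache <- new.env()
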