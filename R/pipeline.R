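#' Section exposure analysis at one wind speed
#'
#' Runs the full chain for a single scheduled wind speed: 90%-span section
#' state from the operating schedule, panel-method pressure field, grazing
#' flight-path families on the suction and pressure sides, pressure traces and
#' exposure metrics, and the tip-vortex pressure from the momentum-solver
#' circulation.
#'
#' @param u_inf wind speed (m/s).
#' @param fixtures a [reference_fixture_set()].
#' @param bat a [bat_properties()].
#' @param bat_speed bat flight speed w.r.t. the wind (m/s).
#' @param band_fraction ambient-band half-width as a fraction of p_inf.
#' @param n_paths paths per side.
#' @param rho,p_inf air density (kg/m^3) and ambient pressure (Pa).
#' @param trace_all if TRUE, trace every path in each family; otherwise only
#'   the closest and farthest (sufficient for the summary extrema).
#' @return list of class `section_exposure` with the field, offsets, traces,
#'   metrics of the closest low-pressure path, the vortex stage and the
#'   summary row.
#' @export
section_exposure <- function(u_inf, fixtures = reference_fixture_set(),
                             bat = bat_properties(), bat_speed = 10,
                             band_fraction = 0.05, n_paths = 6,
                             rho = 1.225, p_inf = 101325,
                             trace_all = FALSE) {
  op <- operating_point_for(u_inf, rho = rho, p_inf = p_inf)
  state <- section_state_for(u_inf)
  station <- section_at_fraction(fixtures$planform, 0.9)
  sol <- solve_panel(fixtures$shape, alpha = state$alpha, u_rel = state$u_rel,
                     rho = rho, p_inf = p_inf, chord = station$chord_m)
  field <- exposure_field(sol, phi_deg = state$alpha + station$twist_deg + op$pitch)

  run_family <- function(side, speed) {
    cond0 <- flight_condition(speed, side = side)
    offsets <- release_offsets(field, cond0, n_paths = n_paths)
    idx <- if (trace_all) seq_along(offsets) else unique(c(1L, length(offsets)))
    traces <- lapply(idx, function(i) {
      cond <- flight_condition(speed, side = side, lateral_offset = offsets[i])
      path <- integrate_path(field, bat, cond)
      if (path$struck) stop("released path unexpectedly struck the blade")
      list(offset = offsets[i], path = path, trace = trace_pressure(path, field))
    })
    list(offsets = offsets, traces = traces, bat_speed = speed, side = side)
  }
  # a bat can cross from the upwind or the downwind direction; the reported
  # extremes are over both approaches at the given flight speed
  speeds <- unique(c(bat_speed, -bat_speed))
  pick <- function(side, score) {
    fams <- lapply(speeds, function(s) run_family(side, s))
    fams[[which.max(vapply(fams, score, numeric(1)))]]
  }
  suction <- pick("suction", function(f) -min(f$traces[[1]]$trace$samples$p_Pa))
  pressure <- pick("pressure", function(f) max(f$traces[[1]]$trace$samples$p_Pa))

  closest_low <- suction$traces[[1]]$trace
  farthest_low <- suction$traces[[length(suction$traces)]]$trace
  closest_high <- pressure$traces[[1]]$trace
  farthest_high <- pressure$traces[[length(pressure$traces)]]$trace
  metrics <- exposure_metrics(closest_low, band_fraction = band_fraction)

  circ <- spanwise_circulation(fixtures$planform, op, fixtures$polars)
  vortex <- tip_vortex(tip_vortex_strength(circ),
                       core_radius(mean_chord(fixtures$planform)), rho = rho)

  row <- data.frame(
    u_inf_mps = u_inf,
    p_min_close_Pa = min(closest_low$samples$p_Pa) - p_inf,
    p_min_far_Pa = min(farthest_low$samples$p_Pa) - p_inf,
    p_vortex_min_Pa = vortex_pressure(0, vortex, p_inf = 0),
    p_max_close_Pa = max(closest_high$samples$p_Pa) - p_inf,
    p_max_far_Pa = max(farthest_high$samples$p_Pa) - p_inf,
    t_outside_band_s = metrics$t_outside_band,
    t_rise_s = metrics$t_rise,
    t_recover_s = metrics$t_recover,
    clearance_close_m = attr(suction$offsets, "clearance")
  )

  structure(
    list(
      u_inf = u_inf, field = field, suction = suction, pressure = pressure,
      metrics = metrics, circulation = circ, vortex = vortex, summary_row = row
    ),
    class = "section_exposure"
  )
}

#' Exposure summary across wind speeds
#'
#' The blade/vortex exposure table: for each wind speed, the minimum pressure
#' along the closest (<1 mm) and farthest (~100 mm) low-pressure-side flight
#' paths, the tip-vortex centre pressure, the maximum pressure along the
#' closest and farthest high-pressure-side paths (all relative to ambient),
#' and the timing metrics of the closest low-pressure path.
#'
#' @inheritParams section_exposure
#' @param wind_speeds wind speeds (m/s) to analyse.
#' @return data.frame with one row per wind speed.
#' @export
exposure_summary <- function(wind_speeds = c(5, 7.5, 10),
                             fixtures = reference_fixture_set(),
                             bat = bat_properties(), bat_speed = 10,
                             band_fraction = 0.05, n_paths = 6,
                             rho = 1.225, p_inf = 101325) {
  rows <- lapply(wind_speeds, function(u) {
    section_exposure(u, fixtures, bat, bat_speed, band_fraction, n_paths,
                     rho, p_inf)$summary_row
  })
  do.call(rbind, rows)
}

#' Run configuration
#'
#' @param wind_speeds wind speeds (m/s), each within the 3-25 m/s envelope.
#' @param bat_speed bat flight speed w.r.t. the wind (m/s).
#' @param band_fraction ambient-band half-width fraction.
#' @param n_paths flight paths per pressure side.
#' @param clearances named targets: closest-path clearance bound and farthest
#'   offset (m), both positive.
#' @param output_dir where [run_pipeline()] writes its artifact bundle.
#' @param fixtures fixture selection; only "reference" is bundled.
#' @param log_level "info" or "quiet".
#' @return list of class `run_config`.
#' @export
run_config <- function(wind_speeds = c(5, 7.5, 10), bat_speed = 10,
                       band_fraction = 0.05, n_paths = 6,
                       clearances = c(close = 0.001, far = 0.100),
                       output_dir = tempfile("batbaro_run_"),
                       fixtures = "reference", log_level = "info") {
  if (any(wind_speeds < 3 | wind_speeds > 25)) {
    stop("wind speed outside the 3-25 m/s operating envelope")
  }
  if (abs(bat_speed) > 10) stop("|bat_speed| must be <= 10 m/s")
  if (band_fraction <= 0 || band_fraction >= 1) stop("band_fraction must lie in (0, 1)")
  if (any(clearances <= 0)) stop("clearances must be positive")
  if (!fixtures %in% "reference") stop("unknown fixture selection: ", fixtures)
  if (!log_level %in% c("info", "quiet")) stop("unknown log level: ", log_level)
  structure(
    list(
      wind_speeds = wind_speeds, bat_speed = bat_speed,
      band_fraction = band_fraction, n_paths = n_paths,
      clearances = clearances, output_dir = output_dir,
      fixtures = fixtures, log_level = log_level
    ),
    class = "run_config"
  )
}

#' Load a run configuration from a YAML file
#'
#' Missing keys take their defaults; unknown keys are rejected.
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("malformed config file: expected key-value mappings")
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(vals$clearances)) vals$clearances <- unlist(vals$clearances)
  do.call(run_config, vals)
}

#' Run the end-to-end pipeline
#'
#' Executes geometry -> momentum solver -> panel field -> tip vortex -> flight
#' exposure -> threshold comparison for every configured wind speed and
#' writes the artifact bundle (exposure_summary.csv, traces.csv, paths.csv,
#' report.json, run_log.txt) to the configured output directory. Fully
#' deterministic: identical configurations produce byte-identical CSV output.
#'
#' @param config a [run_config()].
#' @return Invisibly, the bundle list: `summary`, `report`, `traces`, `paths`,
#'   `files`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (config$log_level == "info") message(sprintf(...))
  log_lines <- character(0)
  stamp <- function(stage, t0) {
    line <- sprintf("%s: %.2f s", stage, as.numeric(Sys.time()) - t0)
    log_lines <<- c(log_lines, line)
    say("%s", line)
  }

  t0 <- as.numeric(Sys.time())
  fixtures <- reference_fixture_set()
  stamp("load_fixtures", t0)

  exposures <- list()
  traces <- list()
  paths <- list()
  for (u in config$wind_speeds) {
    t1 <- as.numeric(Sys.time())
    ex <- tryCatch(
      section_exposure(u, fixtures, bat_speed = config$bat_speed,
                       band_fraction = config$band_fraction,
                       n_paths = config$n_paths, trace_all = TRUE),
      error = function(e) {
        stop(sprintf("stage section_exposure(u_inf = %g) failed: %s",
                     u, conditionMessage(e)))
      }
    )
    exposures[[as.character(u)]] <- ex
    for (side in c("suction", "pressure")) {
      appr <- if (ex[[side]]$bat_speed >= 0) "downwind" else "upwind"
      for (tr in ex[[side]]$traces) {
        pid <- sprintf("u%g_%s_%s_%.0fmm", u, side, appr, tr$offset * 1000)
        traces[[pid]] <- data.frame(
          path_id = pid, t_s = tr$trace$samples$t_s, p_Pa = tr$trace$samples$p_Pa
        )
        paths[[pid]] <- data.frame(
          path_id = pid, t_s = tr$path$samples$t_s,
          x_m = tr$path$samples$x_m, y_m = tr$path$samples$y_m
        )
      }
    }
    stamp(sprintf("exposure_u%g", u), t1)
  }

  summary <- do.call(rbind, lapply(exposures, `[[`, "summary_row"))
  rownames(summary) <- NULL
  t2 <- as.numeric(Sys.time())
  report <- build_report(summary, fixtures$decompression, fixtures$blast)
  stamp("threshold_comparison", t2)

  bundle <- list(
    summary = summary,
    report = report,
    traces = do.call(rbind, traces),
    paths = do.call(rbind, paths),
    log_lines = log_lines,
    config = config
  )
  files <- write_outputs(bundle, config$output_dir)
  bundle$files <- files
  say("outputs written to %s", config$output_dir)
  invisible(bundle)
}

#' Write the pipeline artifact bundle
#'
#' CSV files use a fixed column order and 6-significant-digit formatting so
#' repeated runs are byte-identical; report.json keeps full precision. On any
#' failure, partial outputs in the target directory are removed.
#'
#' @param bundle result list from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return Character vector of written file paths.
#' @export
write_outputs <- function(bundle, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  fmt <- function(df) {
    for (nm in names(df)) {
      if (is.numeric(df[[nm]])) {
        df[[nm]] <- formatC(signif(df[[nm]], 6), digits = 6, format = "g")
      }
    }
    df
  }
  written <- character(0)
  on.exit(if (length(written) > 0 && !is.null(attr(written, "failed"))) {
    unlink(written)
  })
  write_one <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(fmt(df), p, row.names = FALSE, quote = FALSE)
    written <<- c(written, p)
    p
  }
  res <- tryCatch({
    f1 <- write_one(bundle$summary, "exposure_summary.csv")
    f2 <- write_one(bundle$traces, "traces.csv")
    f3 <- write_one(bundle$paths, "paths.csv")
    f4 <- file.path(dir, "report.json")
    jsonlite::write_json(
      list(report = bundle$report,
           thresholds = list(
             low_Pa = bundle$report$threshold_Pa[bundle$report$mechanism == "blade_low"][1],
             high_Pa = bundle$report$threshold_Pa[bundle$report$mechanism == "blade_high"][1]
           )),
      f4, dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
    written <- c(written, f4)
    f5 <- file.path(dir, "run_log.txt")
    writeLines(bundle$log_lines, f5)
    c(f1, f2, f3, f4, f5)
  }, error = function(e) {
    unlink(written)
    stop("failed writing outputs (partial files removed): ", conditionMessage(e))
  })
  res
}

#' Threshold-ratio report from an existing exposure summary
#'
#' @param summary an exposure summary data.frame or the path to an
#'   exposure_summary.csv written by [run_pipeline()].
#' @return A [build_report()] comparison report using the bundled threshold
#'   tables.
#' @export
exposure_report <- function(summary) {
  if (is.character(summary)) summary <- utils::read.csv(summary)
  fixtures <- reference_fixture_set()
  build_report(summary, fixtures$decompression, fixtures$blast)
}

#' Run the analytic validation oracles
#'
#' Self-checks of the numerical stages against closed-form results: the
#' radial-momentum quadrature of the vortex velocity profile against the
#' analytic vortex pressure equation, zero lift for a symmetric section at
#' zero incidence, the dynamic-pressure (u^2) scaling of the panel field, and
#' the Betz bound on the ideal toy rotor.
#'
#' @return data.frame with columns `check`, `value`, `bound`, `pass`.
#' @export
validate_oracles <- function() {
  vtx <- tip_vortex(70, 0.17)
  rr <- seq(0, 50 * vtx$r_c, length.out = 40001)
  vth <- tangential_velocity(rr, vtx)
  integrand <- ifelse(rr > 0, vtx$rho * vth^2 / rr, 0)
  # p(r) - p(r_max) by integrating the radial momentum balance inward
  p_quad <- rev(as.vector(pracma::cumtrapz(rev(rr), rev(integrand))))
  p_exact <- vortex_pressure(rr, vtx, p_inf = 0) - vortex_pressure(max(rr), vtx, p_inf = 0)
  q_err <- max(abs(p_quad - p_exact)) / abs(vortex_pressure(0, vtx, p_inf = 0))

  s0012 <- naca4_coordinates(0.12, 0, 0, n_points = 70)
  sym <- solve_panel(s0012, 0, u_rel = 1)
  cl0 <- abs(sym$cl)

  sol1 <- solve_panel(s0012, 6, u_rel = 10, p_inf = 0)
  sol2 <- solve_panel(s0012, 6, u_rel = 20, p_inf = 0)
  pt <- data.frame(x = 0.3, y = 0.4)
  scale_err <- abs(field_pressure(sol2, pt)$p_Pa /
                     field_pressure(sol1, pt)$p_Pa - 4)

  toy <- toy_rotor()
  op <- operating_point(8, tsr = 7)
  cp <- power_coefficient(
    spanwise_circulation(toy$planform, op, toy$polars), toy$planform, op, toy$polars
  )

  out <- data.frame(
    check = c("vortex_quadrature_rel_err", "symmetric_zero_cl",
              "dynamic_pressure_scaling_err", "toy_rotor_cp_minus_betz"),
    value = c(q_err, cl0, scale_err, cp - 16 / 27),
    bound = c(1e-6, 1e-3, 1e-6, 1e-6)
  )
  out$pass <- out$value <= out$bound
  out
}
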