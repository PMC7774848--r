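#' Calibration of the bundled synthetic polars
#'
#' Per-airfoil lift-curve parameters used to generate the bundled polar
#' files: zero-lift angle, lift-curve slope (per radian), stall onset and
#' minimum drag, chosen from the published characteristics of each airfoil
#' family (thick DU root sections through the 64-series tip section). The
#' cylindrical root sections carry zero lift and bluff-body drag.
#'
#' @return data.frame with columns `airfoil_id`, `alpha0_deg`, `cl_slope`,
#'   `stall_deg`, `cd0`, `k`, `is_cylinder`, `cd_cyl`.
#' @export
reference_airfoil_specs <- function() {
  data.frame(
    airfoil_id = c("cylinder1", "cylinder2", "du40", "du35", "du30",
                   "du25", "du21", "naca64"),
    alpha0_deg = c(0, 0, -2.0, -1.8, -2.2, -2.8, -3.2, -4.2),
    cl_slope = c(0, 0, 6.0, 6.0, 6.0, 6.0, 6.0, 6.0),
    stall_deg = c(0, 0, 12, 12, 12, 12, 12, 12),
    cd0 = c(0, 0, 0.035, 0.020, 0.013, 0.010, 0.009, 0.0075),
    k = c(0, 0, 0.006, 0.006, 0.006, 0.006, 0.006, 0.006),
    is_cylinder = c(TRUE, TRUE, rep(FALSE, 6)),
    cd_cyl = c(0.50, 0.35, rep(NA, 6))
  )
}

#' Generate the polar table for one reference airfoil id
#'
#' @param airfoil_id one of the ids in [reference_airfoil_specs()].
#' @return A [polar_table()].
#' @export
reference_polar <- function(airfoil_id) {
  specs <- reference_airfoil_specs()
  s <- specs[specs$airfoil_id == airfoil_id, ]
  if (nrow(s) != 1) stop("unknown airfoil id: ", airfoil_id)
  if (s$is_cylinder) {
    cylinder_polar(cd = s$cd_cyl)
  } else {
    synthetic_polar(alpha0 = s$alpha0_deg, cl_slope = s$cl_slope,
                    stall_deg = s$stall_deg, cd0 = s$cd0, k = s$k)
  }
}

#' Reference fixture set
#'
#' Loads the bundled inputs for the reference-turbine analysis: the
#' transcribed 17-station planform (63 m rotor radius, three blades), the
#' per-airfoil polar tables (synthetic, generated from the calibrated
#' lift-curve model), the 90%-span section coordinates (a generated 17%-thick
#' cambered four-digit shape standing in for the 64-series profile), the
#' rodent decompression table (synthetic records honouring the published
#' mortality-onset constraints) and the blast LD50 table.
#'
#' @return list of class `fixture_set` with elements `planform`, `polars`
#'   (named list), `shape`, `decompression`, `blast`, `exposure_reference`
#'   (the published blade/vortex exposure table used as a comparison anchor).
#' @export
reference_fixture_set <- function() {
  ext <- function(...) {
    p <- system.file("extdata", ..., package = "batbaro")
    if (p == "") stop("bundled fixture not found: ", file.path(...))
    p
  }
  planform <- load_planform(ext("nrel5mw_planform.tsv"))
  ids <- unique(planform$stations$airfoil_id)
  polars <- lapply(ids, function(id) {
    read_polar(ext("polars", paste0("polar_", id, "_synthetic.tsv")))
  })
  names(polars) <- ids
  structure(
    list(
      planform = planform,
      polars = polars,
      shape = read_airfoil_dat(ext("airfoils", "naca64_90span_synthetic.dat")),
      decompression = read_threshold_table(
        ext("thresholds", "decompression_rodent_synthetic.tsv"), "decompression"
      ),
      blast = read_threshold_table(ext("thresholds", "blast_ld50.tsv"), "blast"),
      exposure_reference = utils::read.delim(ext("reference_exposure_table.tsv"))
    ),
    class = "fixture_set"
  )
}

#' @export
print.fixture_set <- function(x, ...) {
  cat(sprintf(
    "<fixture_set> planform %d stations, %d polars, shape '%s', %d decompression / %d blast records\n",
    nrow(x$planform$stations), length(x$polars), x$shape$name,
    nrow(x$decompression), nrow(x$blast)
  ))
  invisible(x)
}

#' Toy rotor fixture
#'
#' A uniform-chord, analytic-polar rotor on which the momentum and
#' circulation stages have closed-form expectations: ideal lift line
#' cl = 2 pi sin(alpha), zero drag, so per-station circulation must equal
#' 0.5 * chord * cl * v exactly and the power coefficient respects the Betz
#' limit.
#'
#' @param n_stations number of span stations (>= 2).
#' @param chord uniform chord (m).
#' @param twist_deg uniform twist (deg).
#' @param rotor_radius rotor radius (m).
#' @param hub_radius hub radius (m).
#' @param n_blades blade count.
#' @param zero_lift if TRUE, use a zero-lift polar instead (cascade-of-zeros
#'   fixture).
#' @return list of class `fixture_set` with `planform` and `polars`.
#' @export
toy_rotor <- function(n_stations = 9, chord = 1, twist_deg = 0,
                      rotor_radius = 10, hub_radius = 0.5, n_blades = 3,
                      zero_lift = FALSE) {
  if (n_stations < 2) stop("need at least 2 stations")
  if (chord <= 0) stop("chord must be > 0")
  r <- seq(0.2 * rotor_radius, 0.95 * rotor_radius, length.out = n_stations)
  planform <- blade_planform(
    data.frame(
      r_b_m = r, chord_m = chord, twist_deg = twist_deg,
      airfoil_id = "ideal", thickness_ratio = 0.12
    ),
    rotor_radius = rotor_radius, hub_radius = hub_radius, n_blades = n_blades
  )
  polar <- if (zero_lift) {
    cylinder_polar(cd = 0)
  } else {
    synthetic_polar(alpha0 = 0, cl_slope = 2 * pi, stall_deg = 30, cd0 = 0, k = 0)
  }
  structure(
    list(planform = planform, polars = list(ideal = polar)),
    class = "fixture_set"
  )
}

#' Synthetic decompression and blast threshold tables
#'
#' Randomised record sets that honour the published constraints of the rodent
#' rapid-decompression experiments: pressure drops between -86.5 and
#' -45.5 kPa, durations between 0.0021 and 1.9 s, zero mortality below a
#' 58 kPa magnitude, and the first mortal exposure exactly at 58.6 kPa below
#' ambient. Reproducible for a given seed; the caller's RNG state is left
#' untouched.
#'
#' @param seed integer seed.
#' @param n_records number of randomised rat records (in addition to the
#'   anchor rows).
#' @return list with `decompression` ([decompression_records()]) and `blast`
#'   ([blast_records()]).
#' @export
synthetic_threshold_tables <- function(seed = 1, n_records = 10) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  dp <- -runif(n_records, 45500, 86500)
  dur <- runif(n_records, 0.0021, 1.9)
  mort <- ifelse(abs(dp) < 58600, 0, pmin(100, round((abs(dp) - 58600) / 300)))
  hem <- pmin(100, pmax(0, round((abs(dp) - 45000) / 400) + sample(0:10, n_records, TRUE)))
  decompression <- decompression_records(data.frame(
    species = c(rep("rat", n_records), "rat", "rabbit"),
    mass_g = c(rep(168, n_records), 168, 2500),
    delta_p_Pa = c(dp, -58600, -72000),
    duration_s = c(dur, 0.1, 0.5),
    hemorrhage_pct = c(hem, 40, 60),
    mortality_pct = c(mort, 10, 50)
  ))
  blast <- blast_records(data.frame(
    species = c("mouse", "rat", "guinea_pig", "rabbit"),
    mass_g = c(20.7, 168, 590, 2500),
    ld50_Pa = c(184000, 220000 + round(runif(1, -5000, 5000)),
                250000, 290000)
  ))
  list(decompression = decompression, blast = blast)
}
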