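#' Decompression and blast threshold records
#'
#' Decompression records describe rapid low-pressure exposures of small
#' mammals (vacuum-chamber experiments): species, body mass, pressure change
#' (negative = below ambient), exposure duration, and observed hemorrhage and
#' mortality fractions. Blast records hold LD50 overpressures from blast-wave
#' exposure studies.
#'
#' @param tab data.frame with columns `species`, `mass_g`, `delta_p_Pa`,
#'   `duration_s`, `hemorrhage_pct`, `mortality_pct`.
#' @return data.frame of class `decompression_records`.
#' @export
decompression_records <- function(tab) {
  required <- c("species", "mass_g", "delta_p_Pa", "duration_s",
                "hemorrhage_pct", "mortality_pct")
  if (!all(required %in% names(tab))) {
    stop("decompression table needs columns: ", paste(required, collapse = ", "))
  }
  tab <- as.data.frame(tab)[required]
  if (any(tab$duration_s <= 0)) stop("durations must be positive")
  pct <- c(tab$hemorrhage_pct, tab$mortality_pct)
  if (any(pct < 0 | pct > 100)) stop("percentages must lie in [0, 100]")
  class(tab) <- c("decompression_records", "data.frame")
  tab
}

#' @rdname decompression_records
#' @export
blast_records <- function(tab) {
  required <- c("species", "mass_g", "ld50_Pa")
  if (!all(required %in% names(tab))) {
    stop("blast table needs columns: ", paste(required, collapse = ", "))
  }
  tab <- as.data.frame(tab)[required]
  if (any(tab$ld50_Pa <= 0)) stop("LD50 overpressures must be positive")
  class(tab) <- c("blast_records", "data.frame")
  tab
}

#' Read a threshold fixture file
#'
#' @param path tab-delimited file with the columns of
#'   [decompression_records()] or [blast_records()].
#' @param type `"decompression"` or `"blast"`.
#' @return A validated record table.
#' @export
read_threshold_table <- function(path, type = c("decompression", "blast")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("threshold file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (type == "decompression") decompression_records(tab) else blast_records(tab)
}

#' Lowest-magnitude mortal decompression exposure
#'
#' Smallest |delta p| among decompression records with any observed mortality:
#' the low-pressure mortality threshold used in the safety-ratio comparisons.
#' For the bundled rodent table this is 58,600 Pa below ambient.
#'
#' @param records a [decompression_records()] table.
#' @return Threshold magnitude (Pa, positive).
#' @export
mortality_threshold_low <- function(records) {
  stopifnot(inherits(records, "decompression_records"))
  mortal <- records[records$mortality_pct > 0, , drop = FALSE]
  if (nrow(mortal) == 0) stop("no record with non-zero mortality in the table")
  min(abs(mortal$delta_p_Pa))
}

#' Safety ratio of a mortality threshold to a predicted exposure
#'
#' ratio = |threshold| / |predicted|; `rounded` uses round-half-away-from-zero
#' to the nearest integer, matching how such multiples are conventionally
#' reported.
#'
#' @param threshold mortality threshold (Pa).
#' @param predicted predicted exposure (Pa), non-zero.
#' @return list with `ratio` and `rounded`.
#' @export
safety_ratio <- function(threshold, predicted) {
  if (any(predicted == 0)) stop("predicted exposure must be non-zero")
  ratio <- abs(threshold) / abs(predicted)
  list(ratio = ratio, rounded = floor(ratio + 0.5))
}

#' Threshold comparison report
#'
#' For each wind speed in an exposure summary, compares the predicted blade
#' low-pressure, blade high-pressure and tip-vortex low-pressure exposures
#' with the applicable mortality thresholds: the rodent rapid-decompression
#' mortality threshold for low pressures and the mouse blast LD50 for high
#' pressures.
#'
#' @param summary an exposure summary (see [exposure_summary()]), with columns
#'   `u_inf_mps`, `p_min_close_Pa`, `p_vortex_min_Pa`, `p_max_close_Pa`
#'   (pressures relative to ambient).
#' @param decompression a [decompression_records()] table.
#' @param blast a [blast_records()] table.
#' @return data.frame of class `comparison_report`: one row per wind speed and
#'   mechanism with predicted exposure, threshold, ratio and rounded ratio.
#' @export
build_report <- function(summary, decompression, blast) {
  summary <- as.data.frame(summary)
  needed <- c("u_inf_mps", "p_min_close_Pa", "p_vortex_min_Pa", "p_max_close_Pa")
  if (nrow(summary) == 0 || !all(needed %in% names(summary))) {
    stop("exposure summary is empty or missing columns")
  }
  thr_low <- mortality_threshold_low(decompression)
  i_mouse <- which.min(abs(blast$mass_g - 20.7))
  thr_high <- blast$ld50_Pa[i_mouse]
  rows <- do.call(rbind, lapply(seq_len(nrow(summary)), function(i) {
    s <- summary[i, ]
    mech <- data.frame(
      u_inf_mps = s$u_inf_mps,
      mechanism = c("blade_low", "blade_high", "vortex_low"),
      predicted_Pa = c(s$p_min_close_Pa, s$p_max_close_Pa, s$p_vortex_min_Pa),
      threshold_Pa = c(thr_low, thr_high, thr_low),
      threshold_source = c(
        "rodent decompression mortality", "mouse blast LD50",
        "rodent decompression mortality"
      )
    )
    sr <- safety_ratio(mech$threshold_Pa, mech$predicted_Pa)
    mech$ratio <- sr$ratio
    mech$rounded <- sr$rounded
    mech
  }))
  class(rows) <- c("comparison_report", "data.frame")
  rows
}

#' Log-log allometric LD50 fit
#'
#' Optional least-squares fit of log10(LD50) against log10(body mass) over a
#' blast record table. Provided as an exploratory tool only; it is not used by
#' the reported safety ratios.
#'
#' @param blast a [blast_records()] table with >= 2 records.
#' @return `lm` fit of log10(ld50_Pa) ~ log10(mass_g).
#' @export
ld50_allometric_fit <- function(blast) {
  stopifnot(inherits(blast, "blast_records"))
  if (nrow(blast) < 2) stop("need at least 2 blast records to fit")
  stats::lm(log10(ld50_Pa) ~ log10(mass_g), data = as.data.frame(blast))
}
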