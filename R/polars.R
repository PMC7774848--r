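#' Airfoil lift/drag polar table
#'
#' A polar is a table of (alpha_deg, cl, cd) rows spanning at least the range
#' of angles the momentum solver can visit. Lookup is by linear interpolation.
#'
#' @param tab data.frame with columns `alpha_deg`, `cl`, `cd`.
#' @return Object of class `polar_table`.
#' @export
polar_table <- function(tab) {
  required <- c("alpha_deg", "cl", "cd")
  if (!all(required %in% names(tab))) {
    stop("polar table needs columns alpha_deg, cl, cd")
  }
  tab <- as.data.frame(tab)[required]
  if (nrow(tab) < 2) stop("polar table needs at least 2 rows")
  if (any(diff(tab$alpha_deg) <= 0)) stop("polar alphas must be strictly increasing")
  if (any(tab$cd < 0)) stop("polar cd must be non-negative")
  structure(list(tab = tab), class = "polar_table")
}

#' @export
print.polar_table <- function(x, ...) {
  cat(sprintf(
    "<polar_table> %d rows, alpha %g..%g deg, cl range [%.3f, %.3f]\n",
    nrow(x$tab), min(x$tab$alpha_deg), max(x$tab$alpha_deg),
    min(x$tab$cl), max(x$tab$cl)
  ))
  invisible(x)
}

#' Read / write a polar file
#'
#' Polar files are tab-delimited with header columns `alpha_deg`, `cl`, `cd`.
#'
#' @param path file path.
#' @return [polar_table()] for `read_polar`; invisible path for `write_polar`.
#' @export
read_polar <- function(path) {
  if (!file.exists(path)) stop("polar file not found: ", path)
  polar_table(utils::read.delim(path))
}

#' @rdname read_polar
#' @param polar a `polar_table`.
#' @export
write_polar <- function(polar, path) {
  stopifnot(inherits(polar, "polar_table"))
  utils::write.table(polar$tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Interpolate force coefficients from a polar
#'
#' @param polar a `polar_table`.
#' @param alpha_deg angle of attack (deg); clipped to the table range.
#' @return list with `cl` and `cd`.
#' @export
polar_coeffs <- function(polar, alpha_deg) {
  stopifnot(inherits(polar, "polar_table"))
  list(
    cl = stats::approx(polar$tab$alpha_deg, polar$tab$cl, xout = alpha_deg, rule = 2)$y,
    cd = stats::approx(polar$tab$alpha_deg, polar$tab$cd, xout = alpha_deg, rule = 2)$y
  )
}

#' Synthetic airfoil polar
#'
#' Generates a polar from an attached-flow lift line cl = slope * sin(alpha -
#' alpha0) blended smoothly into the flat-plate curve cl = 2 sin(a) cos(a)
#' beyond stall, with a parabolic drag bucket cd = cd0 + k * cl^2 pre-stall
#' rising to the flat-plate cd = 2 sin^2(a) post-stall. Angles cover -180 to
#' 180 deg, densely near the attached range.
#'
#' @param alpha0 zero-lift angle (deg).
#' @param cl_slope lift-curve slope (per radian); default thin-airfoil 2*pi.
#' @param stall_deg stall onset angle (deg) above `alpha0`.
#' @param cd0 minimum drag coefficient.
#' @param k induced/profile drag quadratic coefficient.
#' @return A [polar_table()].
#' @export
synthetic_polar <- function(alpha0 = 0, cl_slope = 2 * pi, stall_deg = 12,
                            cd0 = 0.01, k = 0.006) {
  alpha <- sort(unique(c(seq(-180, 180, by = 10), seq(-30, 30, by = 1))))
  a_rad <- alpha * pi / 180
  cl_att <- cl_slope * sin((alpha - alpha0) * pi / 180)
  cl_fp <- 2 * sin(a_rad) * cos(a_rad)
  cd_fp <- 2 * sin(a_rad)^2
  # blend weight ~1 through the attached linear range; the transition is
  # centred 2 deg past stall onset with a 1.5 deg width so lift below stall
  # follows the lift line rather than being pre-emptively eroded
  w <- 1 / (1 + exp((abs(alpha - alpha0) - (stall_deg + 2)) / 1.5))
  cl <- w * cl_att + (1 - w) * cl_fp
  cd <- w * (cd0 + k * cl_att^2) + (1 - w) * pmax(cd_fp, cd0)
  polar_table(data.frame(alpha_deg = alpha, cl = cl, cd = cd))
}

#' Zero-lift polar (drag only)
#'
#' Convenience polar for cylindrical root sections: cl = 0 at all angles and a
#' constant drag coefficient.
#'
#' @param cd constant drag coefficient.
#' @return A [polar_table()].
#' @export
cylinder_polar <- function(cd = 0.5) {
  alpha <- seq(-180, 180, by = 10)
  polar_table(data.frame(alpha_deg = alpha, cl = 0 * alpha, cd = cd + 0 * alpha))
}
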