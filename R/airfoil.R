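#' Airfoil shape
#'
#' An airfoil shape is a closed coordinate loop in chord units, stored in
#' Selig order: trailing edge -> upper (suction, +y) surface -> leading edge
#' -> lower surface -> trailing edge. The chord is normalized to unit length
#' with the leading edge near (0, 0) and the trailing edge at (1, y_te).
#'
#' @param x,y coordinate vectors in chord units, Selig order.
#' @param name label for the shape.
#' @return Object of class `airfoil_shape`.
#' @export
airfoil_shape <- function(x, y, name = "airfoil") {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 10) stop("too few coordinate points for an airfoil (need >= 10)")
  if (max(x) - min(x) < 0.5) stop("degenerate chord extent")
  # normalize: LE at x = 0, unit chord (x and y scaled together)
  scale <- max(x) - min(x)
  y <- y / scale
  x <- (x - min(x)) / scale
  if (abs(x[1] - 1) > 0.05 || abs(x[length(x)] - 1) > 0.05) {
    stop("coordinates must start and end at the trailing edge (Selig order)")
  }
  i_le <- which.min(x)
  if (mean(y[seq_len(i_le)]) < mean(y[seq(i_le, length(y))])) {
    stop("expected upper (suction) surface first: +y side before the leading edge")
  }
  structure(list(x = x, y = y, name = name), class = "airfoil_shape")
}

#' @export
print.airfoil_shape <- function(x, ...) {
  cat(sprintf(
    "<airfoil_shape> %s: %d points, max thickness ~ %.3f c\n",
    x$name, length(x$x), max_thickness(x)
  ))
  invisible(x)
}

#' Maximum thickness-to-chord ratio of a shape
#'
#' Interpolates upper and lower surfaces on a fine chordwise grid and returns
#' the maximum vertical thickness.
#'
#' @param shape an [airfoil_shape()].
#' @return Maximum thickness in chord units.
#' @export
max_thickness <- function(shape) {
  i_le <- which.min(shape$x)
  xu <- rev(shape$x[1:i_le]); yu <- rev(shape$y[1:i_le])
  xl <- shape$x[i_le:length(shape$x)]; yl <- shape$y[i_le:length(shape$x)]
  grid <- seq(0.01, 0.99, length.out = 400)
  up <- stats::approx(xu, yu, xout = grid, rule = 2)$y
  lo <- stats::approx(xl, yl, xout = grid, rule = 2)$y
  max(up - lo)
}

#' NACA 4-digit airfoil coordinates
#'
#' Standard NACA 4-digit thickness and camber equations with cosine chordwise
#' spacing and a closed trailing edge. `naca4_coordinates(0.12, 0, 0)` is the
#' NACA 0012; `naca4_coordinates(0.17, 0.04, 0.4)` is a 17%-thick cambered
#' section used as the stand-in for the 64-series blade profile.
#'
#' @param thickness maximum thickness as fraction of chord, in (0, 0.4).
#' @param camber maximum camber as fraction of chord.
#' @param camber_pos chordwise position of maximum camber (fraction).
#' @param n_points number of points per surface (>= 40).
#' @return An [airfoil_shape()].
#' @export
naca4_coordinates <- function(thickness, camber = 0, camber_pos = 0.4,
                              n_points = 80) {
  if (thickness <= 0 || thickness >= 0.4) stop("thickness must lie in (0, 0.4)")
  if (camber < 0 || camber > 0.1) stop("camber must lie in [0, 0.1]")
  if (camber > 0 && (camber_pos <= 0 || camber_pos >= 1)) {
    stop("camber_pos must lie in (0, 1)")
  }
  if (n_points < 40) stop("need n_points >= 40")
  beta <- seq(0, pi, length.out = n_points)
  xc <- (1 - cos(beta)) / 2
  # closed-TE thickness polynomial
  yt <- 5 * thickness * (0.2969 * sqrt(xc) - 0.1260 * xc - 0.3516 * xc^2 +
    0.2843 * xc^3 - 0.1036 * xc^4)
  if (camber > 0) {
    m <- camber; p <- camber_pos
    fore <- xc < p
    yc <- ifelse(fore, m / p^2 * (2 * p * xc - xc^2),
      m / (1 - p)^2 * ((1 - 2 * p) + 2 * p * xc - xc^2))
    dyc <- ifelse(fore, 2 * m / p^2 * (p - xc), 2 * m / (1 - p)^2 * (p - xc))
  } else {
    yc <- 0 * xc
    dyc <- 0 * xc
  }
  th <- atan(dyc)
  xu <- xc - yt * sin(th); yu <- yc + yt * cos(th)
  xl <- xc + yt * sin(th); yl <- yc - yt * cos(th)
  # Selig order: TE -> upper -> LE -> lower -> TE
  x <- c(rev(xu), xl[-1])
  y <- c(rev(yu), yl[-1])
  name <- sprintf("NACA4 t=%.2f m=%.2f p=%.2f", thickness, camber, camber_pos)
  airfoil_shape(x, y, name = name)
}

#' Read / write Selig-style airfoil coordinate files
#'
#' Selig format: a name line followed by whitespace-separated x y pairs
#' running trailing edge -> upper surface -> leading edge -> lower surface ->
#' trailing edge.
#'
#' @param path file path.
#' @return An [airfoil_shape()] (`read_airfoil_dat`); invisible path
#'   (`write_airfoil_dat`).
#' @export
read_airfoil_dat <- function(path) {
  if (!file.exists(path)) stop("airfoil file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("airfoil file has no coordinates: ", path)
  name <- trimws(lines[1])
  xs <- ys <- numeric(0)
  for (i in seq(2, length(lines))) {
    ln <- trimws(lines[i])
    if (ln == "") next
    parts <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
    if (length(parts) != 2 || anyNA(parts)) {
      stop(sprintf("cannot parse coordinates at line %d of %s: '%s'", i, path, ln))
    }
    xs <- c(xs, parts[1]); ys <- c(ys, parts[2])
  }
  airfoil_shape(xs, ys, name = name)
}

#' @rdname read_airfoil_dat
#' @param shape an `airfoil_shape`.
#' @export
write_airfoil_dat <- function(shape, path) {
  stopifnot(inherits(shape, "airfoil_shape"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(shape$name, con)
  writeLines(sprintf("%.8f %.8f", shape$x, shape$y), con)
  invisible(path)
}
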