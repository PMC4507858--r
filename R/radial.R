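#' Radial Fourier decomposition of an equally spaced outline
#'
#' Decomposes the distance of each outline point to the outline's center of
#' gravity as a function of position along the contour. With N equally
#' arc-length-spaced points and radii \eqn{r_j} (j = 0..N-1):
#' \deqn{A_h = (2/N) \sum_j r_j \cos(2\pi h j / N), \quad
#'       B_h = (2/N) \sum_j r_j \sin(2\pi h j / N).}
#' The zero harmonic \eqn{a_0 = \bar r} is proportional to outline size and
#' is used both as the size estimator and to standardize all other
#' coefficients, so the returned `fcs` are pure (dimensionless) shape
#' variables. Seven harmonics, i.e. 14 variables, describe a mouse molar
#' adequately; higher harmonics carry finer outline detail.
#'
#' @param x an [outline()] with points equally spaced in arc length
#'   (see [resample_equal_arclength()]); at least `2 * n_harmonics + 1`
#'   points.
#' @param n_harmonics number of harmonics H (default 7, giving 14 FCs).
#' @return an object of class `radial_descriptor`: list with `a0` (mean
#'   radius, input units), `fcs` (named numeric of length 2H: `A1..AH`,
#'   `B1..BH`, size-standardized), `n_harmonics`, `n_points`.
#' @export
radial_fourier <- function(x, n_harmonics = 7L) {
  x <- .as_outline(x)
  H <- as.integer(n_harmonics)
  if (H < 1L) stop("`n_harmonics` must be at least 1", call. = FALSE)
  N <- nrow(x)
  if (N < 2L * H + 1L)
    stop("outline must have at least 2 * n_harmonics + 1 points", call. = FALSE)
  ctr <- colMeans(x)
  r <- sqrt((x[, 1L] - ctr[1L])^2 + (x[, 2L] - ctr[2L])^2)
  a0 <- mean(r)
  if (a0 <= 0) stop("degenerate outline: all points at the centroid", call. = FALSE)
  j <- 0:(N - 1L)
  A <- B <- numeric(H)
  for (h in seq_len(H)) {
    A[h] <- 2 / N * sum(r * cos(2 * pi * h * j / N))
    B[h] <- 2 / N * sum(r * sin(2 * pi * h * j / N))
  }
  fcs <- c(A, B) / a0
  names(fcs) <- c(paste0("A", seq_len(H)), paste0("B", seq_len(H)))
  structure(list(a0 = a0, fcs = fcs, n_harmonics = H, n_points = N),
            class = "radial_descriptor")
}

#' Assemble a radial descriptor from size and coefficients
#'
#' @param a0 mean radius (> 0).
#' @param fcs 2H size-standardized coefficients, ordered `A1..AH, B1..BH`.
#' @return a `radial_descriptor`.
#' @export
radial_descriptor <- function(a0, fcs) {
  a0 <- as.numeric(a0)
  fcs <- as.numeric(fcs)
  if (length(a0) != 1L || !is.finite(a0) || a0 <= 0)
    stop("`a0` must be a single positive number", call. = FALSE)
  if (length(fcs) %% 2L != 0L || length(fcs) < 2L)
    stop("`fcs` must have even length 2H", call. = FALSE)
  H <- length(fcs) / 2L
  names(fcs) <- c(paste0("A", seq_len(H)), paste0("B", seq_len(H)))
  structure(list(a0 = a0, fcs = fcs, n_harmonics = H, n_points = NA_integer_),
            class = "radial_descriptor")
}

#' Inverse radial Fourier reconstruction
#'
#' Rebuilds an outline from a radial descriptor by evaluating
#' \eqn{r_j = a_0 (1 + \sum_h A_h \cos(2\pi h j/n) + B_h \sin(2\pi h j/n))}
#' and placing the points at equal angular steps around the origin. The equal
#' angular step is a display-oriented stand-in for the arc-length parameter;
#' reconstructions are intended for mean-shape figures. A zero-coefficient
#' descriptor yields a circle of radius `a0`.
#'
#' @param desc a `radial_descriptor`.
#' @param n_points number of points to reconstruct (>= 3).
#' @return an [outline()]; warns if any reconstructed radius is <= 0
#'   (descriptor outside the method's validity).
#' @export
inverse_radial_fourier <- function(desc, n_points = 64L) {
  stopifnot(inherits(desc, "radial_descriptor"))
  n_points <- as.integer(n_points)
  if (n_points < 3L) stop("`n_points` must be at least 3", call. = FALSE)
  H <- desc$n_harmonics
  j <- 0:(n_points - 1L)
  r <- rep(1, n_points)
  for (h in seq_len(H)) {
    r <- r + desc$fcs[h] * cos(2 * pi * h * j / n_points) +
      desc$fcs[H + h] * sin(2 * pi * h * j / n_points)
  }
  r <- desc$a0 * r
  if (any(r <= 0))
    warning("reconstructed radius <= 0 at some points: ",
            "descriptor is outside the radial method's validity",
            call. = FALSE)
  ang <- 2 * pi * j / n_points
  outline(cbind(r * cos(ang), r * sin(ang)))
}

#' Full descriptor pipeline for one raw outline
#'
#' Convenience wrapper running the study's digitization chain: resample to
#' `n_points` equal arc-length steps, orient by the first-harmonic ellipse
#' ([efa_orient()]), resample again (orientation shifts the start point),
#' then extract the radial descriptor.
#'
#' @param x a raw [outline()] (or coordinate matrix).
#' @param n_points contour points (default 64).
#' @param n_harmonics radial harmonics (default 7, 14 shape variables).
#' @return a `radial_descriptor`.
#' @export
outline_to_descriptor <- function(x, n_points = 64L, n_harmonics = 7L) {
  x <- resample_equal_arclength(.as_outline(x), n_points)
  x <- efa_orient(x, n_harmonics)
  x <- resample_equal_arclength(x, n_points)
  radial_fourier(x, n_harmonics)
}

#' @export
print.radial_descriptor <- function(x, ...) {
  cat("Radial Fourier descriptor: a0 =", format(x$a0, digits = 6),
      "|", x$n_harmonics, "harmonics (", length(x$fcs), "FCs )\n")
  invisible(x)
}
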