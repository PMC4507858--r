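#' Elliptic Fourier decomposition of a closed outline
#'
#' Decomposes the x(t) and y(t) coordinate functions of a closed contour,
#' parameterized by cumulative chord length t, into harmonic series
#' (Kuhl-Giardina form). Each harmonic h carries four coefficients:
#' `a[h], b[h]` for x and `c[h], d[h]` for y; the constant terms `A0, C0`
#' locate the outline. The first harmonic traces the best-fitting ellipse,
#' which is used by [efa_orient()] to normalize rotation and starting point.
#'
#' The coefficients are the exact Fourier integrals of the piecewise-linear
#' contour, so the inverse expansion with many harmonics reproduces the
#' vertices up to discretization error.
#'
#' @param x an [outline()]; traversed counterclockwise (reversed internally
#'   if needed so the sine coefficients have a consistent sign).
#' @param n_harmonics number of harmonics H (>= 1).
#' @return an object of class `elliptic_descriptor`: list with `A0`, `C0`,
#'   matrix `coef` (H x 4, columns `a`, `b`, `c`, `d`), `n_harmonics`,
#'   `perimeter`.
#' @export
elliptic_fourier <- function(x, n_harmonics = 7L) {
  x <- .outline_ccw(.as_outline(x))
  H <- as.integer(n_harmonics)
  if (H < 1L) stop("`n_harmonics` must be at least 1", call. = FALSE)
  seg <- .outline_segments(x)
  T_ <- sum(seg)
  t1 <- cumsum(seg)                 # arc position of each segment's end
  t0 <- c(0, t1[-length(t1)])       # ... and start
  nxt <- rbind(x[-1L, , drop = FALSE], x[1L, , drop = FALSE])
  dx <- nxt[, 1L] - x[, 1L]
  dy <- nxt[, 2L] - x[, 2L]

  # exact piecewise-linear integrals: A0 = (1/T) int x(t) dt (trapezoid, exact
  # here because x(t) is linear on each segment)
  A0 <- sum((x[, 1L] + nxt[, 1L]) / 2 * seg) / T_
  C0 <- sum((x[, 2L] + nxt[, 2L]) / 2 * seg) / T_

  coef <- matrix(0, H, 4L, dimnames = list(NULL, c("a", "b", "c", "d")))
  for (h in seq_len(H)) {
    w <- 2 * pi * h / T_
    k <- T_ / (2 * pi^2 * h^2)
    dcos <- cos(w * t1) - cos(w * t0)
    dsin <- sin(w * t1) - sin(w * t0)
    coef[h, "a"] <- k * sum(dx / seg * dcos)
    coef[h, "b"] <- k * sum(dx / seg * dsin)
    coef[h, "c"] <- k * sum(dy / seg * dcos)
    coef[h, "d"] <- k * sum(dy / seg * dsin)
  }
  structure(list(A0 = A0, C0 = C0, coef = coef, n_harmonics = H,
                 perimeter = T_),
            class = "elliptic_descriptor")
}

#' Inverse elliptic Fourier reconstruction
#'
#' Evaluates the harmonic expansion at `n_points` equally spaced values of
#' the arc-length parameter.
#'
#' @param desc an `elliptic_descriptor` from [elliptic_fourier()].
#' @param n_points number of points to reconstruct.
#' @param centered drop the constant terms `A0, C0` (centered outline)?
#' @return an [outline()].
#' @export
inverse_elliptic_fourier <- function(desc, n_points = 64L, centered = FALSE) {
  stopifnot(inherits(desc, "elliptic_descriptor"))
  tt <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  xs <- rep(if (centered) 0 else desc$A0, n_points)
  ys <- rep(if (centered) 0 else desc$C0, n_points)
  for (h in seq_len(desc$n_harmonics)) {
    xs <- xs + desc$coef[h, "a"] * cos(h * tt) + desc$coef[h, "b"] * sin(h * tt)
    ys <- ys + desc$coef[h, "c"] * cos(h * tt) + desc$coef[h, "d"] * sin(h * tt)
  }
  outline(cbind(xs, ys))
}

# First-harmonic ellipse geometry. Returns the phase theta (of the arc-length
# parameter) at which the first-harmonic point is on the semi-major axis, the
# rotation angle phi of that axis, and the semi-axis lengths.
.efa_first_ellipse <- function(desc) {
  a <- desc$coef[1L, "a"]; b <- desc$coef[1L, "b"]
  cc <- desc$coef[1L, "c"]; d <- desc$coef[1L, "d"]
  # squared radius of E(theta) = (a cos + b sin, c cos + d sin) is extremal at
  theta <- 0.5 * atan2(2 * (a * b + cc * d), a^2 + cc^2 - b^2 - d^2)
  cand <- theta + pi / 2 * (0:3)
  ex <- a * cos(cand) + b * sin(cand)
  ey <- cc * cos(cand) + d * sin(cand)
  r <- sqrt(ex^2 + ey^2)
  i <- which.max(r)
  list(theta_major = cand[i], r_major = r[i], r_minor = min(r),
       phi = atan2(ey[i], ex[i]))
}

#' Normalize outline rotation and starting point from the first harmonic
#'
#' Standard elliptic-Fourier orientation: the outline is rotated so the major
#' axis of its first-harmonic (best-fitting) ellipse lies along +x, and the
#' starting point is moved to the contour position where that ellipse meets
#' the major axis, i.e. the major elongation of the object. Of the two
#' major-axis ends, the one whose (centered, rotated) harmonic reconstruction
#' has the larger x is chosen; ties go to the end nearer the input starting
#' point. Vertex spacing along the contour is preserved.
#'
#' Near-circular outlines have no defined major axis: if the first-harmonic
#' axis ratio exceeds `1 - tol` the input is returned unchanged with a
#' warning.
#'
#' @param x an [outline()].
#' @param n_harmonics harmonics used for the orientation ellipse and the
#'   tie-break reconstruction (default 7, matching the radial step).
#' @param tol near-circularity tolerance on `1 - minor/major` (default 1e-6).
#' @return an [outline()] with the same number of points.
#' @export
efa_orient <- function(x, n_harmonics = 7L, tol = 1e-6) {
  x <- .outline_ccw(.as_outline(x))
  desc <- elliptic_fourier(x, n_harmonics)
  ell <- .efa_first_ellipse(desc)
  if (1 - ell$r_minor / ell$r_major < tol) {
    warning("outline is near-circular: orientation undefined, returning input",
            call. = FALSE)
    return(x)
  }
  T_ <- desc$perimeter
  # two candidate starting phases: the two major-axis ends
  cand <- c(ell$theta_major, ell$theta_major + pi) %% (2 * pi)
  a <- desc$coef[, "a"]; b <- desc$coef[, "b"]
  cc <- desc$coef[, "c"]; d <- desc$coef[, "d"]
  h <- seq_len(desc$n_harmonics)
  score <- numeric(2L)
  for (i in 1:2) {
    # first-harmonic direction of this end (maps to +x after rotation) ...
    ux <- a[1L] * cos(cand[i]) + b[1L] * sin(cand[i])
    uy <- cc[1L] * cos(cand[i]) + d[1L] * sin(cand[i])
    u <- c(ux, uy) / sqrt(ux^2 + uy^2)
    # ... and the full-harmonic centered reconstruction at the same phase;
    # its projection on u is the x coordinate of the rotated start point
    px <- sum(a * cos(h * cand[i]) + b * sin(h * cand[i]))
    py <- sum(cc * cos(h * cand[i]) + d * sin(h * cand[i]))
    score[i] <- px * u[1L] + py * u[2L]
  }
  pick <- if (abs(score[1L] - score[2L]) > 1e-9 * max(abs(score))) {
    which.max(score)
  } else {
    which.min(cand)                  # tie: toward the input starting point
  }
  theta0 <- cand[pick]
  s0 <- theta0 * T_ / (2 * pi)

  # re-index: keep the original inter-vertex arc pattern, shifted to start at s0
  seg <- .outline_segments(x)
  tvert <- c(0, cumsum(seg))[seq_len(nrow(x))]
  pts <- .interp_arclength(x, s0 + tvert)

  # rotate so the chosen major-axis end lies along +x
  ex <- desc$coef[1L, "a"] * cos(theta0) + desc$coef[1L, "b"] * sin(theta0)
  ey <- desc$coef[1L, "c"] * cos(theta0) + desc$coef[1L, "d"] * sin(theta0)
  phi <- atan2(ey, ex)
  rot <- matrix(c(cos(-phi), sin(-phi), -sin(-phi), cos(-phi)), 2L, 2L)
  ctr <- c(desc$A0, desc$C0)
  pts <- sweep(pts, 2L, ctr) %*% t(rot)
  pts <- sweep(pts, 2L, ctr, `+`)
  outline(pts)
}
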