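#' Construct a closed outline
#'
#' An outline is an ordered sequence of 2D points describing a closed contour
#' (the last point connects back to the first). Outlines are the raw input of
#' the Fourier shape descriptors; a typical specimen is a tooth contour
#' digitized as 64 points.
#'
#' @param points two-column numeric matrix (or data frame) of x, y
#'   coordinates, in any consistent length unit. At least 3 points; no two
#'   consecutive points may coincide.
#' @return an object of class `outline`: a matrix with columns `x`, `y`.
#' @export
outline <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L)
    stop("`points` must be a two-column numeric matrix of x, y coordinates",
         call. = FALSE)
  if (anyNA(points)) stop("outline coordinates contain NA", call. = FALSE)
  if (nrow(points) < 3L) stop("an outline needs at least 3 points", call. = FALSE)
  seg <- .outline_segments(points)
  if (any(seg == 0))
    stop("outline has identical consecutive points (zero-length segment)",
         call. = FALSE)
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(points, class = c("outline", "matrix"))
}

# closed-polygon segment lengths: point i -> i+1, last -> first
.outline_segments <- function(pts) {
  nxt <- rbind(pts[-1L, , drop = FALSE], pts[1L, , drop = FALSE])
  sqrt(rowSums((nxt - pts)^2))
}

.as_outline <- function(x) {
  if (inherits(x, "outline")) x else outline(x)
}

#' @export
print.outline <- function(x, ...) {
  cat("Closed outline with", nrow(x), "points, perimeter",
      format(outline_perimeter(x), digits = 6), "\n")
  invisible(x)
}

#' Perimeter of a closed outline
#'
#' @param x an [outline()].
#' @return total length of the closed polygonal contour.
#' @export
outline_perimeter <- function(x) {
  x <- .as_outline(x)
  sum(.outline_segments(x))
}

#' Signed area of a closed outline (shoelace formula)
#'
#' Positive for counterclockwise orientation.
#' @param x an [outline()].
#' @return signed area.
#' @export
outline_signed_area <- function(x) {
  x <- .as_outline(x)
  xs <- x[, 1L]; ys <- x[, 2L]
  xn <- c(xs[-1L], xs[1L]); yn <- c(ys[-1L], ys[1L])
  sum(xs * yn - xn * ys) / 2
}

# Force counterclockwise orientation (keeps the starting point).
.outline_ccw <- function(x) {
  if (outline_signed_area(x) < 0)
    x <- outline(x[c(1L, nrow(x):2L), , drop = FALSE])
  x
}

# Interpolate the closed polygonal contour at arc-length positions `s`
# (taken modulo the perimeter). Linear interpolation between vertices.
.interp_arclength <- function(pts, s) {
  seg <- .outline_segments(pts)
  per <- sum(seg)
  t0 <- c(0, cumsum(seg))            # vertex arc-length positions, t0[n+1] = per
  s <- s %% per
  idx <- findInterval(s, t0, rightmost.closed = TRUE)
  idx[idx > nrow(pts)] <- nrow(pts)
  frac <- (s - t0[idx]) / seg[idx]
  nxt <- rbind(pts[-1L, , drop = FALSE], pts[1L, , drop = FALSE])
  pts[idx, , drop = FALSE] * (1 - frac) + nxt[idx, , drop = FALSE] * frac
}

#' Resample an outline at equal arc-length steps
#'
#' Places `n_points` points on the closed contour so that consecutive
#' arc-length gaps (by cumulative chord length) all equal
#' `perimeter / n_points`. The first output point is the input's first point.
#' Radial Fourier decomposition assumes such an equally spaced outline.
#'
#' @param x an [outline()].
#' @param n_points number of points to place (>= 3); the study standard is 64.
#' @return an [outline()] with `n_points` rows.
#' @export
resample_equal_arclength <- function(x, n_points = 64L) {
  x <- .as_outline(x)
  n_points <- as.integer(n_points)
  if (n_points < 3L) stop("`n_points` must be at least 3", call. = FALSE)
  per <- outline_perimeter(x)
  if (per <= 0) stop("degenerate outline: zero perimeter", call. = FALSE)
  s <- per * (seq_len(n_points) - 1L) / n_points
  outline(.interp_arclength(x, s))
}

#' Read an outline from a plain-text coordinate file
#'
#' One "x y" pair per line; blank lines and lines starting with `#` ignored.
#'
#' @param path file path.
#' @return an [outline()].
#' @export
read_outline <- function(path) {
  m <- utils::read.table(path, comment.char = "#",
                         col.names = c("x", "y"))
  outline(as.matrix(m))
}

#' Write an outline to a plain-text coordinate file
#'
#' @param x an [outline()].
#' @param path file path.
#' @export
write_outline <- function(x, path) {
  x <- .as_outline(x)
  utils::write.table(unclass(x), path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
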