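# Ordinations on grouped shape data: PCA (eigenanalysis of T), between-group
# PCA (eigenanalysis of B), CVA (eigenanalysis of B W^-1 via whitening) and
# PCoA of a distance matrix. All return a common `ordination` container whose
# group-mean configuration feeds the Protest comparisons.

# per-axis sign convention: the largest-|entry| of the reference matrix
# (loadings, or the coordinates themselves) is positive
.fix_signs <- function(ref, ...) {
  flip <- apply(ref, 2L, function(v) {
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  })
  out <- lapply(list(ref, ...), function(m) sweep(m, 2L, flip, `*`))
  out
}

.new_ordination <- function(method, eigenvalues, percent, loadings, scores,
                            group_means, n_axes) {
  structure(list(method = method,
                 eigenvalues = eigenvalues,
                 percent_variance = percent,
                 loadings = loadings,
                 scores = scores,
                 group_means = group_means,
                 n_axes = n_axes),
            class = "ordination")
}

#' @export
print.ordination <- function(x, digits = 3, ...) {
  cat(x$method, "ordination:", length(x$eigenvalues), "non-null axes,",
      x$n_axes, "retained\n")
  k <- min(x$n_axes, length(x$percent_variance))
  cat("% variance:",
      paste(format(x$percent_variance[seq_len(k)], digits = digits),
            collapse = " / "), "\n")
  invisible(x)
}

#' Group-mean configuration of an ordination
#'
#' The scores of the group means on the first `n_axes` axes; the
#' configuration compared across methods by [protest()]. If the ordination
#' has fewer non-null axes than requested, the configuration is padded with
#' zero columns (with a warning), so configurations of equal width can be
#' superimposed.
#'
#' @param ord an `ordination`.
#' @param n_axes number of axes (default: the ordination's `n_axes`).
#' @return g x n_axes matrix, rownames = group labels.
#' @export
group_config <- function(ord, n_axes = ord$n_axes) {
  stopifnot(inherits(ord, "ordination"))
  gm <- ord$group_means
  if (ncol(gm) < n_axes) {
    warning(ord$method, " has only ", ncol(gm),
            " non-null axes; configuration zero-padded to ", n_axes,
            call. = FALSE)
    gm <- cbind(gm, matrix(0, nrow(gm), n_axes - ncol(gm)))
  }
  gm[, seq_len(n_axes), drop = FALSE]
}

# shared back end: eigen-decompose a symmetric matrix, clip null axes,
# project data, summarize
.eigen_ordination <- function(method, M, Xc, groups, n_axes, max_rank = Inf) {
  p <- ncol(M)
  ee <- eigen(M, symmetric = TRUE)
  ev <- ee$values
  tol <- max(abs(ev)) * 1e-10
  keep <- which(ev > tol)
  keep <- keep[seq_len(min(length(keep), max_rank))]
  ev <- ev[keep]
  V <- ee$vectors[, keep, drop = FALSE]
  if (n_axes > length(keep)) {
    warning(method, ": only ", length(keep),
            " non-null axes available; n_axes clipped", call. = FALSE)
    n_axes <- length(keep)
  }
  scores <- Xc %*% V
  sw <- .fix_signs(V, scores)
  V <- sw[[1L]]; scores <- sw[[2L]]
  ax <- paste0(switch(method, PCA = "PC", bgPCA = "bgPC", "Axis"),
               seq_along(keep))
  dimnames(V) <- list(colnames(Xc), ax)
  dimnames(scores) <- list(rownames(Xc), ax)
  gm <- rowsum(scores, groups) / as.vector(table(groups))
  gm <- gm[levels(groups), , drop = FALSE]
  .new_ordination(method, ev, 100 * ev / sum(ev), V, scores, gm, n_axes)
}

#' Principal component analysis of shape variables
#'
#' Eigenanalysis of the total variance-covariance matrix T: axes maximizing
#' variance among all specimens.
#'
#' @param data a [grouped_dataset()].
#' @param n_axes axes to retain for configurations (default 4).
#' @return an `ordination` (method `"PCA"`); `percent_variance` spans all
#'   non-null eigenvalues of T, so it sums to 100.
#' @export
pca <- function(data, n_axes = 4L) {
  stopifnot(inherits(data, "grouped_dataset"))
  vd <- variance_decomposition(data)
  Xc <- sweep(data$values, 2L, colMeans(data$values))
  .eigen_ordination("PCA", vd$T, Xc, data$groups, n_axes)
}

#' Between-group principal component analysis
#'
#' Eigenanalysis of the between-group matrix B (group means weighted by
#' sample size): axes of maximal variance among group means, without
#' within-group standardization. Individual specimens are projected onto
#' these axes; at most g - 1 axes are non-null.
#'
#' @inheritParams pca
#' @return an `ordination` (method `"bgPCA"`); `percent_variance` is the
#'   share of between-group variance per axis.
#' @export
bgpca <- function(data, n_axes = 4L) {
  stopifnot(inherits(data, "grouped_dataset"))
  g <- nlevels(data$groups)
  if (g < 2L) stop("between-group PCA needs at least 2 groups", call. = FALSE)
  vd <- variance_decomposition(data)
  Xc <- sweep(data$values, 2L, colMeans(data$values))
  .eigen_ordination("bgPCA", vd$B, Xc, data$groups, n_axes, max_rank = g - 1L)
}

#' Canonical variate analysis
#'
#' Eigenanalysis of \eqn{B W^{-1}}: axes maximizing the between-group to
#' within-group variance ratio (linear discriminant analysis for more than
#' two groups). Solved as a generalized eigenproblem by whitening: with the
#' pooled within-group covariance \eqn{W_p = U \Lambda U'} (divisor n - g),
#' data are mapped by \eqn{U \Lambda^{-1/2} U'} and the mapped B is
#' eigen-analyzed. Canonical scores have unit pooled within-group variance
#' on every axis, which is what "standardizing by the within-group variance"
#' means: any direction of main within-group variance shared across groups
#' is compressed to the same footing as all others.
#'
#' Requires n - g >= p and a full-rank within-group matrix; otherwise the
#' analysis stops and advises reducing dimensionality first (e.g. fewer
#' harmonics or a preliminary PCA).
#'
#' @inheritParams pca
#' @return an `ordination` (method `"CVA"`); `percent_variance` is each
#'   discriminant root (eigenvalue of B W^-1) over their sum, i.e. the share
#'   of among-group variance per canonical axis.
#' @export
cva <- function(data, n_axes = 4L) {
  stopifnot(inherits(data, "grouped_dataset"))
  g <- nlevels(data$groups)
  p <- ncol(data$values)
  n <- nrow(data$values)
  if (g < 2L) stop("CVA needs at least 2 groups", call. = FALSE)
  if (n - g < p)
    stop("CVA requires n - g >= p (here n - g = ", n - g, ", p = ", p,
         "); reduce the dimensionality of the data first", call. = FALSE)
  Wp <- .pooled_within(data)
  ew <- eigen(Wp, symmetric = TRUE)
  if (min(ew$values) / max(ew$values) < 1e-10)
    stop("within-group matrix is rank-deficient; ",
         "reduce the dimensionality of the data first", call. = FALSE)
  Wi <- ew$vectors %*% (t(ew$vectors) / sqrt(ew$values))   # W_p^{-1/2}
  vd <- variance_decomposition(data)
  Bw <- t(Wi) %*% vd$B %*% Wi
  Bw <- (Bw + t(Bw)) / 2
  ee <- eigen(Bw, symmetric = TRUE)
  r <- min(g - 1L, p)
  ev <- pmax(ee$values[seq_len(r)], 0)
  A <- Wi %*% ee$vectors[, seq_len(r), drop = FALSE]        # raw-space axes
  Xc <- sweep(data$values, 2L, colMeans(data$values))
  scores <- Xc %*% A
  sw <- .fix_signs(A, scores)
  A <- sw[[1L]]; scores <- sw[[2L]]
  ax <- paste0("CV", seq_len(r))
  dimnames(A) <- list(colnames(data$values), ax)
  dimnames(scores) <- list(rownames(data$values), ax)
  gm <- rowsum(scores, data$groups) / as.vector(table(data$groups))
  gm <- gm[levels(data$groups), , drop = FALSE]
  if (n_axes > r) {
    warning("CVA: only ", r, " canonical axes available; n_axes clipped",
            call. = FALSE)
    n_axes <- r
  }
  .new_ordination("CVA", ev, 100 * ev / sum(ev), A, scores, gm, n_axes)
}

#' Principal coordinate analysis of a distance matrix
#'
#' Metric embedding of a symmetric distance matrix (Gower double-centering
#' of -d^2/2 followed by eigen-decomposition, via [stats::cmdscale()]);
#' coordinates are scaled by the square roots of the eigenvalues so
#' Euclidean distances between them reproduce the input when it is
#' Euclidean-embeddable. Axes with non-positive eigenvalues are dropped with
#' a warning reporting the negative-eigenvalue mass; no Cailliez/Lingoes
#' correction is applied.
#'
#' @param d square symmetric non-negative distance matrix with zero
#'   diagonal; rownames are the configuration labels. A `dist` object is
#'   also accepted.
#' @param n_axes axes to retain (default 4).
#' @return an `ordination` (method `"PCoA"`); `loadings` is `NULL`, and
#'   `group_means` equals the coordinates (one row per label).
#' @export
pcoa <- function(d, n_axes = 4L) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("`d` must be square", call. = FALSE)
  if (any(d < 0)) stop("`d` has negative entries", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-12 * max(1, max(d)))
    stop("`d` is not symmetric", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12)) stop("`d` has a non-zero diagonal", call. = FALSE)
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("g", seq_len(nrow(d)))
  k <- min(n_axes, nrow(d) - 1L)
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = nrow(d) - 1L, eig = TRUE))
  ev <- fit$eig
  pos <- ev > max(abs(ev)) * 1e-10
  neg_mass <- sum(abs(ev[ev < 0]))
  if (neg_mass > max(abs(ev)) * 1e-8)
    warning("distance matrix is not Euclidean-embeddable: dropping axes with ",
            "negative eigenvalues (total negative mass ",
            format(neg_mass, digits = 4), ")", call. = FALSE)
  coords <- fit$points[, seq_len(min(sum(pos), ncol(fit$points))),
                       drop = FALSE]
  coords <- .fix_signs(coords)[[1L]]
  dimnames(coords) <- list(labs, paste0("PCo", seq_len(ncol(coords))))
  evp <- ev[pos]
  if (k > ncol(coords)) k <- ncol(coords)
  .new_ordination("PCoA", evp, 100 * evp / sum(evp), NULL, coords, coords, k)
}

#' Read a labeled square distance matrix from delimited text
#'
#' @param path file with a header of labels and one labeled row per line
#'   (whitespace- or tab-delimited).
#' @return a labeled square matrix suitable for [pcoa()].
#' @export
read_distance_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1L,
                                   check.names = FALSE, comment.char = "#"))
  storage.mode(m) <- "double"
  m
}
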