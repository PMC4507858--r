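#' Construct a grouped dataset
#'
#' The unit passed to every ordination: an n x p matrix of shape variables
#' (14 size-standardized Fourier coefficients in the molar study) with one
#' group label per specimen (locality of trapping).
#'
#' @param values numeric matrix or data frame, one row per specimen.
#' @param groups group label per row (coerced to factor; empty levels
#'   dropped).
#' @return an object of class `grouped_dataset`: list with `values`
#'   (numeric matrix), `groups` (factor).
#' @export
grouped_dataset <- function(values, groups) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("`values` contains NA", call. = FALSE)
  if (nrow(values) < 2L) stop("need at least 2 specimens", call. = FALSE)
  if (ncol(values) < 1L) stop("need at least 1 variable", call. = FALSE)
  groups <- droplevels(as.factor(groups))
  if (length(groups) != nrow(values))
    stop("`groups` must have one label per row of `values`", call. = FALSE)
  if (anyNA(groups)) stop("`groups` contains NA", call. = FALSE)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("V", seq_len(ncol(values)))
  structure(list(values = values, groups = groups),
            class = "grouped_dataset")
}

#' @export
print.grouped_dataset <- function(x, ...) {
  cat("Grouped dataset:", nrow(x$values), "specimens x", ncol(x$values),
      "variables,", nlevels(x$groups), "groups\n")
  print(table(x$groups))
  invisible(x)
}

#' Group means of a grouped dataset
#'
#' @param data a [grouped_dataset()].
#' @return g x p matrix of group means, rownames = group labels.
#' @export
group_means <- function(data) {
  stopifnot(inherits(data, "grouped_dataset"))
  m <- rowsum(data$values, data$groups) / as.vector(table(data$groups))
  m[levels(data$groups), , drop = FALSE]
}

#' Decompose total variance into between- and within-group parts
#'
#' With grand (specimen-weighted) mean m and group means m_i, computes the
#' total variance-covariance matrix
#' \eqn{T = (1/n) \sum (x - m)(x - m)'}, the between-group matrix
#' \eqn{B = (1/n) \sum_i n_i (m_i - m)(m_i - m)'} (group means weighted by
#' sample size) and the within-group matrix \eqn{W = T - B} (the pooled
#' within-group scatter over n). The divisor-n convention makes the identity
#' T = B + W exact; every percent-of-variance the ordinations report is
#' invariant to that choice.
#'
#' @param data a [grouped_dataset()].
#' @return an object of class `variance_decomposition`: list with `T`, `B`,
#'   `W` (p x p symmetric matrices), `divisor = "n"`, `n`, `group_sizes`.
#' @export
variance_decomposition <- function(data) {
  stopifnot(inherits(data, "grouped_dataset"))
  X <- data$values
  n <- nrow(X)
  m <- colMeans(X)
  Xc <- sweep(X, 2L, m)
  Tm <- crossprod(Xc) / n
  gm <- group_means(data)
  ni <- as.vector(table(data$groups)[rownames(gm)])
  Gc <- sweep(gm, 2L, m)
  Bm <- crossprod(Gc * sqrt(ni)) / n
  Wm <- Tm - Bm
  # enforce exact symmetry against floating-point drift
  Tm <- (Tm + t(Tm)) / 2; Bm <- (Bm + t(Bm)) / 2; Wm <- (Wm + t(Wm)) / 2
  structure(list(T = Tm, B = Bm, W = Wm, divisor = "n", n = n,
                 group_sizes = stats::setNames(ni, rownames(gm))),
            class = "variance_decomposition")
}

# Pooled within-group covariance with divisor n - g (the CVA convention).
.pooled_within <- function(data) {
  X <- data$values
  g <- nlevels(data$groups)
  gm <- group_means(data)
  Xc <- X - gm[as.character(data$groups), , drop = FALSE]
  crossprod(Xc) / (nrow(X) - g)
}
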