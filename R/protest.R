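# Protest: Procrustes comparison of two group-mean configurations.
# Both configurations are centered and scaled to unit total sum of squares,
# then superimposed by the optimal orthogonal map (rotations and
# reflections). The residual sum of squares d (= 1 - (sum of singular
# values)^2) measures how different the two pictures of among-group
# differentiation are; r = sqrt(1 - d) is the associated correlation.
# Significance comes from permuting the rows of one configuration.

# align y's rows to x's labels; validate
.match_configs <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  lx <- rownames(x); ly <- rownames(y)
  if (is.null(lx) || is.null(ly))
    stop("configurations must have rownames (group labels)", call. = FALSE)
  if (anyDuplicated(lx) || anyDuplicated(ly))
    stop("configuration labels must be unique", call. = FALSE)
  if (nrow(x) < 3L)
    stop("Procrustes comparison needs at least 3 points", call. = FALSE)
  if (!setequal(lx, ly))
    stop("configurations have different label sets", call. = FALSE)
  y <- y[lx, , drop = FALSE]
  if (ncol(x) != ncol(y)) {
    warning("configurations have different numbers of axes; ",
            "padding the narrower with zero columns", call. = FALSE)
    k <- max(ncol(x), ncol(y))
    if (ncol(x) < k) x <- cbind(x, matrix(0, nrow(x), k - ncol(x)))
    if (ncol(y) < k) y <- cbind(y, matrix(0, nrow(y), k - ncol(y)))
  }
  list(x = x, y = y)
}

.unit_center <- function(m) {
  m <- sweep(m, 2L, colMeans(m))
  ss <- sum(m^2)
  if (ss == 0) stop("degenerate configuration: all points identical",
                    call. = FALSE)
  m / sqrt(ss)
}

# d for two already centered/unit-scaled matrices
.proc_d <- function(xs, ys) {
  s <- svd(crossprod(xs, ys))$d
  max(0, 1 - sum(s)^2)
}

#' Procrustes distance and correlation between two configurations
#'
#' @param x,y g x k matrices of group scores with group labels as rownames;
#'   rows are matched by label, not by order. If the two differ in axis
#'   count, the narrower is zero-padded (with a warning).
#' @return list with `d` (Procrustes distance statistic, residual sum of
#'   squares after symmetric superimposition, in \[0, 1\]) and
#'   `r = sqrt(1 - d)`.
#' @export
procrustes_statistic <- function(x, y) {
  m <- .match_configs(x, y)
  d <- .proc_d(.unit_center(m$x), .unit_center(m$y))
  list(d = d, r = sqrt(1 - d))
}

#' Protest: Procrustes comparison with a permutation test
#'
#' Computes the Procrustes distance between two configurations and assesses
#' whether they are more related than random by permuting the row order of
#' `y` `n_perm` times; the p-value is
#' `(#permuted d <= observed d + 1) / (n_perm + 1)`, so its smallest
#' attainable value is `1 / (n_perm + 1)`.
#'
#' @inheritParams procrustes_statistic
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed, recorded in the result.
#' @return an object of class `protest_result`: list with `d`, `r`,
#'   `p_value`, `n_perm`, `seed`, `permutation_d`.
#' @export
protest <- function(x, y, n_perm = 999L, seed = 1L) {
  if (n_perm < 1L) stop("`n_perm` must be at least 1", call. = FALSE)
  m <- .match_configs(x, y)
  xs <- .unit_center(m$x)
  ys <- .unit_center(m$y)
  d <- .proc_d(xs, ys)
  g <- nrow(xs)
  set.seed(seed)
  dp <- vapply(seq_len(n_perm), function(i) {
    .proc_d(xs, ys[sample.int(g), , drop = FALSE])
  }, numeric(1L))
  p <- (sum(dp <= d) + 1) / (n_perm + 1)
  structure(list(d = d, r = sqrt(1 - d), p_value = p,
                 n_perm = n_perm, seed = seed, permutation_d = dp),
            class = "protest_result")
}

#' @export
print.protest_result <- function(x, ...) {
  cat("Protest: D =", format(x$d, digits = 4),
      ", R =", format(x$r, digits = 4),
      ", P =", format(x$p_value, digits = 4),
      "(", x$n_perm, "permutations )\n")
  invisible(x)
}
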