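# Pmax: the first eigenvector of a group's phenotypic variance-covariance
# matrix P, i.e. the direction of maximal within-group variance — the
# candidate "line of least resistance" to evolution. The bootstrap procedure
# asks whether two groups' Pmax can be told apart given estimation noise.

#' Estimate a group's direction of maximal variance (Pmax)
#'
#' First eigenvector of the group's covariance matrix, unit norm, with the
#' per-axis sign convention (largest-magnitude loading positive). Estimation
#' is noisy in small samples: a warning is emitted below `min_n` specimens
#' (30 by default — groups below that are conventionally considered too
#' small for a stable Pmax).
#'
#' @param group_values numeric matrix, specimens x variables, for one group.
#' @param group_id optional label stored in the result.
#' @param min_n small-sample warning threshold (default 30).
#' @return an object of class `pmax_estimate`: list with `group_id`,
#'   `loading_vector` (unit p-vector), `percent_first_eigenvalue`,
#'   `n_specimens`, and (after [bootstrap_pmax()]) `bootstrap_r`, `r95`,
#'   `seed`.
#' @export
estimate_pmax <- function(group_values, group_id = NULL, min_n = 30L) {
  X <- as.matrix(group_values)
  storage.mode(X) <- "double"
  if (nrow(X) < 3L)
    stop("Pmax estimation needs at least 3 specimens", call. = FALSE)
  if (nrow(X) < min_n)
    warning("Pmax estimated on only ", nrow(X), " specimens (fewer than ",
            min_n, "): estimate may be unstable", call. = FALSE)
  ee <- eigen(stats::cov(X), symmetric = TRUE)
  v <- ee$vectors[, 1L]
  s <- sign(v[which.max(abs(v))]); if (s == 0) s <- 1
  v <- v * s / sqrt(sum(v^2))
  names(v) <- colnames(X)
  structure(list(group_id = group_id,
                 loading_vector = v,
                 percent_first_eigenvalue = 100 * ee$values[1L] / sum(ee$values),
                 n_specimens = nrow(X),
                 bootstrap_r = NULL, r95 = NULL, seed = NULL),
            class = "pmax_estimate")
}

#' @export
print.pmax_estimate <- function(x, ...) {
  cat("Pmax", if (!is.null(x$group_id)) paste0("[", x$group_id, "]"),
      ": n =", x$n_specimens,
      ", % variance on Pmax =",
      format(x$percent_first_eigenvalue, digits = 4))
  if (!is.null(x$r95)) cat(", bootstrap r95 =", format(x$r95, digits = 4))
  cat("\n")
  invisible(x)
}

#' Correlation between two loading vectors
#'
#' Default is the absolute Pearson correlation of the two coefficient
#' sequences; `method = "cosine"` gives the absolute cosine (vector
#' correlation sensu the angle between eigenvectors). Both are symmetric and
#' invariant to negating either vector, as required for eigenvectors whose
#' sign is arbitrary. The two measures differ unless the loadings are
#' centered.
#'
#' @param u,v numeric vectors of equal length >= 2; neither constant.
#' @param method `"pearson"` (default) or `"cosine"`.
#' @return a correlation in \[0, 1\].
#' @export
vector_correlation <- function(u, v, method = c("pearson", "cosine")) {
  method <- match.arg(method)
  u <- as.numeric(u); v <- as.numeric(v)
  if (length(u) != length(v) || length(u) < 2L)
    stop("`u` and `v` must have equal length >= 2", call. = FALSE)
  if (method == "pearson") {
    if (stats::sd(u) == 0 || stats::sd(v) == 0)
      stop("constant vector: Pearson correlation undefined", call. = FALSE)
    abs(stats::cor(u, v))
  } else {
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0)
      stop("zero vector: cosine undefined", call. = FALSE)
    abs(sum(u * v)) / (nu * nv)
  }
}

#' Bootstrap stability of a group's Pmax
#'
#' Resamples the group's specimens with replacement `n_boot` times
#' (100 in the molar study), re-estimates Pmax on each resample, and records
#' the correlation of each bootstrap Pmax with the original estimate. The
#' 5th percentile of that distribution, `r95`, is the lower bound of the
#' 95% bootstrap distribution: an observed between-group correlation above
#' it is indistinguishable from estimation noise. The bound is one-sided
#' because only low correlations indicate disagreement.
#'
#' @inheritParams estimate_pmax
#' @param n_boot bootstrap replicates (default 100; < 20 warns).
#' @param seed RNG seed, recorded in the result.
#' @param method correlation flavor, see [vector_correlation()].
#' @return a `pmax_estimate` with `bootstrap_r` (length `n_boot`), `r95`
#'   and `seed` filled.
#' @export
bootstrap_pmax <- function(group_values, n_boot = 100L, seed = 1L,
                           group_id = NULL, min_n = 30L,
                           method = c("pearson", "cosine")) {
  method <- match.arg(method)
  est <- estimate_pmax(group_values, group_id = group_id, min_n = min_n)
  if (n_boot < 20L)
    warning("fewer than 20 bootstrap replicates: interval unstable",
            call. = FALSE)
  X <- as.matrix(group_values)
  n <- nrow(X)
  set.seed(seed)
  r <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    eb <- suppressWarnings(estimate_pmax(X[idx, , drop = FALSE], min_n = 3L))
    vector_correlation(est$loading_vector, eb$loading_vector, method)
  }, numeric(1L))
  est$bootstrap_r <- r
  est$r95 <- unname(stats::quantile(r, 0.05))
  est$seed <- seed
  est
}

#' Compare the Pmax of two groups
#'
#' The between-group correlation of the two loading vectors is compared to
#' the looser (smaller) of the two bootstrap bounds: the less robustly
#' estimated group governs the decision. The groups' main variance
#' directions are declared distinguishable only when the observed
#' correlation falls below that bound.
#'
#' @param est_a,est_b `pmax_estimate` objects carrying `r95`
#'   (see [bootstrap_pmax()]).
#' @param method correlation flavor, see [vector_correlation()].
#' @return an object of class `pmax_comparison`: list with `group_a`,
#'   `group_b`, `r_between`, `threshold`, `distinguishable`.
#' @export
compare_pmax <- function(est_a, est_b, method = c("pearson", "cosine")) {
  method <- match.arg(method)
  stopifnot(inherits(est_a, "pmax_estimate"), inherits(est_b, "pmax_estimate"))
  if (is.null(est_a$r95) || is.null(est_b$r95))
    stop("both estimates need bootstrap information (run bootstrap_pmax first)",
         call. = FALSE)
  r <- vector_correlation(est_a$loading_vector, est_b$loading_vector, method)
  thr <- min(est_a$r95, est_b$r95)
  structure(list(group_a = est_a$group_id, group_b = est_b$group_id,
                 r_between = r, threshold = thr,
                 distinguishable = r < thr),
            class = "pmax_comparison")
}

#' @export
print.pmax_comparison <- function(x, ...) {
  cat("Pmax comparison", x$group_a, "/", x$group_b,
      ": R =", format(x$r_between, digits = 4),
      "vs threshold", format(x$threshold, digits = 4),
      "->", if (x$distinguishable) "distinguishable" else "not distinguishable",
      "\n")
  invisible(x)
}
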