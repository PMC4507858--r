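# Homogenized-variance simulation study: rebuild the dataset with isotropic
# within-group variance (keeping the observed group means and sizes), re-run
# PCA / bgPCA / CVA, and compare the three pairwise Protest distances to the
# ones observed on the real data. If the real within-group variance is
# strongly oriented along a direction shared among groups, the observed
# bgPCA-CVA distance should sit far in the upper tail of its simulated null.

#' Common homogenized within-group variance of a dataset
#'
#' Per group, the geometric mean of the p per-variable sample variances
#' (divisor n_i - 1); the common variance is the arithmetic mean of these
#' group-wise geometric means. This is the single isotropic variance the
#' simulated groups receive.
#'
#' @param data a [grouped_dataset()].
#' @return a positive scalar.
#' @export
homogenized_variance <- function(data) {
  stopifnot(inherits(data, "grouped_dataset"))
  lv <- levels(data$groups)
  gvar <- vapply(lv, function(g) {
    v <- apply(data$values[data$groups == g, , drop = FALSE], 2L, stats::var)
    if (any(v <= 0)) {
      bad <- colnames(data$values)[which(v <= 0)[1L]]
      stop("group '", g, "', variable '", bad,
           "' has zero variance: geometric mean undefined", call. = FALSE)
    }
    exp(mean(log(v)))
  }, numeric(1L))
  mean(gvar)
}

#' Specification of a homogenized-variance simulation
#'
#' @param group_means g x p matrix of observed group means (rownames =
#'   labels).
#' @param group_sizes g specimen counts.
#' @param sigma2 common per-variable variance (> 0).
#' @param n_sim number of simulated datasets (default 999).
#' @param n_axes ordination axes per configuration (default 4).
#' @param seed root RNG seed.
#' @return an object of class `homogenized_spec`.
#' @export
homogenized_spec <- function(group_means, group_sizes, sigma2,
                             n_sim = 999L, n_axes = 4L, seed = 1L) {
  group_means <- as.matrix(group_means)
  if (is.null(rownames(group_means)))
    rownames(group_means) <- paste0("g", seq_len(nrow(group_means)))
  if (length(group_sizes) != nrow(group_means))
    stop("`group_sizes` must have one entry per group", call. = FALSE)
  if (any(group_sizes < 1L)) stop("group sizes must be >= 1", call. = FALSE)
  if (!is.finite(sigma2) || sigma2 <= 0)
    stop("`sigma2` must be positive", call. = FALSE)
  if (n_sim < 1L) stop("`n_sim` must be >= 1", call. = FALSE)
  structure(list(group_means = group_means,
                 group_sizes = as.integer(group_sizes),
                 sigma2 = sigma2, n_sim = as.integer(n_sim),
                 n_axes = as.integer(n_axes), seed = as.integer(seed)),
            class = "homogenized_spec")
}

# sub-stream seed for replicate r of a root seed; kept below 2^31
.derive_seed <- function(seed, r) {
  as.integer((as.numeric(seed) + 48271 * as.numeric(r)) %% 2147483647)
}

#' Draw one homogenized-variance dataset
#'
#' Each group i receives n_i independent multinormal draws with mean equal
#' to the observed group-i mean and covariance `sigma2 * I` (exactly
#' isotropic — no direction of main variance survives); groups are drawn
#' independently. The draw is fully determined by `(spec$seed,
#' replicate_index)` via a derived sub-stream, so single replicates are
#' reproducible in isolation.
#'
#' @param spec a [homogenized_spec()].
#' @param replicate_index replicate number (1-based).
#' @return a [grouped_dataset()].
#' @export
simulate_homogenized_dataset <- function(spec, replicate_index = 1L) {
  stopifnot(inherits(spec, "homogenized_spec"))
  set.seed(.derive_seed(spec$seed, replicate_index))
  p <- ncol(spec$group_means)
  g <- nrow(spec$group_means)
  sd0 <- sqrt(spec$sigma2)
  vals <- vector("list", g)
  for (i in seq_len(g)) {
    ni <- spec$group_sizes[i]
    vals[[i]] <- matrix(stats::rnorm(ni * p, sd = sd0), ni, p,
                        byrow = FALSE) +
      matrix(spec$group_means[i, ], ni, p, byrow = TRUE)
  }
  values <- do.call(rbind, vals)
  colnames(values) <- colnames(spec$group_means)
  grouped_dataset(values,
                  rep(rownames(spec$group_means), spec$group_sizes))
}

# the three ordination configurations of a dataset on n_axes axes
.three_configs <- function(data, n_axes) {
  list(PCA = group_config(pca(data, n_axes), n_axes),
       bgPCA = group_config(bgpca(data, n_axes), n_axes),
       CVA = group_config(cva(data, n_axes), n_axes))
}

.sim_pairs <- matrix(c("PCA", "bgPCA", "PCA", "CVA", "bgPCA", "CVA"),
                     ncol = 2L, byrow = TRUE,
                     dimnames = list(c("PCA-bgPCA", "PCA-CVA", "bgPCA-CVA"),
                                     NULL))

#' Homogenized-variance simulation study
#'
#' Runs the full design: observed Procrustes distances between the PCA,
#' bgPCA and CVA group-mean configurations of `data` (first `n_axes` axes),
#' then `n_sim` simulated datasets with the same group means and sizes but
#' isotropic within-group variance ([homogenized_variance()]), each re-run
#' through the three ordinations and the three pairwise Procrustes
#' distances. The position of each observed distance within its simulated
#' distribution (`observed_quantile` = fraction of simulated distances <=
#' observed) measures how much the real within-group variance structure
#' shapes each pair of pictures.
#'
#' @param data a [grouped_dataset()]; must satisfy the CVA preconditions.
#' @param n_sim simulated datasets (default 999).
#' @param n_axes axes per configuration (default 4).
#' @param seed root RNG seed.
#' @param groups optional character vector: restrict the study to these
#'   groups (default: all groups in `data`).
#' @return an object of class `variance_simulation`: list with
#'   `observed_d` (named length-3), `simulated_d` (n_sim x 3 matrix),
#'   `observed_quantile`, `sigma2`, `n_sim`, `n_axes`, `seed`.
#' @export
simulation_study <- function(data, n_sim = 999L, n_axes = 4L, seed = 1L,
                             groups = NULL) {
  stopifnot(inherits(data, "grouped_dataset"))
  if (!is.null(groups)) {
    keep <- data$groups %in% groups
    data <- grouped_dataset(data$values[keep, , drop = FALSE],
                            data$groups[keep])
  }
  obs_cfg <- .three_configs(data, n_axes)
  observed_d <- vapply(rownames(.sim_pairs), function(pr) {
    procrustes_statistic(obs_cfg[[.sim_pairs[pr, 1L]]],
                         obs_cfg[[.sim_pairs[pr, 2L]]])$d
  }, numeric(1L))
  sigma2 <- homogenized_variance(data)
  spec <- homogenized_spec(group_means(data),
                           as.vector(table(data$groups)[levels(data$groups)]),
                           sigma2, n_sim = n_sim, n_axes = n_axes,
                           seed = seed)
  sim_d <- matrix(NA_real_, n_sim, 3L,
                  dimnames = list(NULL, rownames(.sim_pairs)))
  for (r in seq_len(n_sim)) {
    simdat <- simulate_homogenized_dataset(spec, r)
    cfg <- tryCatch(.three_configs(simdat, n_axes),
                    error = function(e) stop("replicate ", r, ": ",
                                             conditionMessage(e),
                                             call. = FALSE))
    sim_d[r, ] <- vapply(rownames(.sim_pairs), function(pr) {
      .proc_d(.unit_center(cfg[[.sim_pairs[pr, 1L]]]),
              .unit_center(cfg[[.sim_pairs[pr, 2L]]]))
    }, numeric(1L))
  }
  oq <- vapply(rownames(.sim_pairs),
               function(pr) mean(sim_d[, pr] <= observed_d[pr]),
               numeric(1L))
  structure(list(observed_d = observed_d, simulated_d = sim_d,
                 observed_quantile = oq, sigma2 = sigma2,
                 n_sim = n_sim, n_axes = n_axes, seed = seed),
            class = "variance_simulation")
}

#' @export
print.variance_simulation <- function(x, ...) {
  cat("Homogenized-variance simulation (", x$n_sim, "datasets, sigma2 =",
      format(x$sigma2, digits = 4), ")\n")
  out <- data.frame(observed_d = x$observed_d,
                    sim_mean_d = colMeans(x$simulated_d),
                    sim_q975 = apply(x$simulated_d, 2L, stats::quantile, 0.975),
                    observed_quantile = x$observed_quantile)
  print(out, digits = 4)
  invisible(x)
}

#' Histogram panel of a simulation study (one panel per method pair)
#'
#' Grey histograms: simulated Procrustes distances under homogenized
#' within-group variance; red line: the observed distance.
#'
#' @param x a `variance_simulation`.
#' @param ... passed to [graphics::hist()].
#' @export
plot.variance_simulation <- function(x, ...) {
  op <- graphics::par(mfrow = c(1L, 3L))
  on.exit(graphics::par(op))
  for (pr in colnames(x$simulated_d)) {
    rng <- range(c(x$simulated_d[, pr], x$observed_d[pr]))
    graphics::hist(x$simulated_d[, pr], col = "grey", border = "white",
                   main = pr, xlab = "Procrustes distance", xlim = rng, ...)
    graphics::abline(v = x$observed_d[pr], col = "red", lwd = 2)
  }
  invisible(x)
}
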