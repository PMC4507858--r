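# Synthetic grouped shape data with the variance structure the analysis is
# about: all groups share one dominant within-group variance direction
# (Pmax) of configurable anisotropy, and group means are displaced partly
# along that direction ("island"-style divergence down the line of least
# resistance) and partly orthogonal to it ("clade"-style divergence).

#' Configuration for the synthetic grouped-shape generator
#'
#' Group i is drawn from a multinormal with mean
#' `center + along_pmax_displacements[i] * pmax_direction +
#' orthogonal_displacements[i, ]` and covariance `V diag(lambda) V'`, where
#' the first column of the orthonormal `V` is `pmax_direction` and
#' `lambda = (anisotropy * lambda2, lambda2, residual decay...)`. The
#' default residual spectrum decays geometrically (ratio 0.7) from
#' `lambda2 = 1`.
#'
#' @param n_groups number of groups; default 7, mirroring the seven
#'   continental localities of the molar study.
#' @param n_per_group per-group specimen counts (recycled); default the
#'   study's continental sample sizes.
#' @param p number of variables (default 14, the 2 x 7 radial FCs).
#' @param pmax_direction unit p-vector shared by all groups (default: a
#'   fixed deterministic direction).
#' @param anisotropy lambda1 / lambda2 ratio >= 1 (default 10).
#' @param residual_eigenvalues optional length p-1 spectrum
#'   `(lambda2..lambdap)`; default `0.7^(0:(p-2))`.
#' @param along_pmax_displacements per-group scalar offsets of the means
#'   along `pmax_direction` (default 0).
#' @param orthogonal_displacements g x p matrix of per-group offsets
#'   orthogonal to `pmax_direction` (default 0).
#' @param seed RNG seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_groups = 7L,
                             n_per_group = c(68L, 13L, 15L, 7L, 18L, 14L, 14L),
                             p = 14L,
                             pmax_direction = NULL,
                             anisotropy = 10,
                             residual_eigenvalues = NULL,
                             along_pmax_displacements = 0,
                             orthogonal_displacements = NULL,
                             seed = 1L) {
  n_groups <- as.integer(n_groups)
  p <- as.integer(p)
  if (n_groups < 1L || p < 2L) stop("need n_groups >= 1 and p >= 2",
                                    call. = FALSE)
  n_per_group <- rep_len(as.integer(n_per_group), n_groups)
  if (any(n_per_group < 1L)) stop("group sizes must be >= 1", call. = FALSE)
  if (is.null(pmax_direction)) {
    # fixed smooth direction: heavier weight on low harmonics
    pmax_direction <- exp(-0.25 * (seq_len(p) - 1L))
  }
  if (length(pmax_direction) != p)
    stop("`pmax_direction` must have length p", call. = FALSE)
  pmax_direction <- pmax_direction / sqrt(sum(pmax_direction^2))
  if (anisotropy < 1) stop("`anisotropy` must be >= 1", call. = FALSE)
  if (is.null(residual_eigenvalues)) residual_eigenvalues <- 0.7^(0:(p - 2L))
  if (length(residual_eigenvalues) != p - 1L || any(residual_eigenvalues <= 0))
    stop("`residual_eigenvalues` must be p - 1 positive values", call. = FALSE)
  along <- rep_len(as.numeric(along_pmax_displacements), n_groups)
  if (is.null(orthogonal_displacements))
    orthogonal_displacements <- matrix(0, n_groups, p)
  orthogonal_displacements <- as.matrix(orthogonal_displacements)
  if (!all(dim(orthogonal_displacements) == c(n_groups, p)))
    stop("`orthogonal_displacements` must be an n_groups x p matrix",
         call. = FALSE)
  if (max(abs(orthogonal_displacements %*% pmax_direction)) > 1e-10)
    stop("`orthogonal_displacements` must be orthogonal to `pmax_direction`",
         call. = FALSE)
  structure(list(n_groups = n_groups, n_per_group = n_per_group, p = p,
                 pmax_direction = pmax_direction, anisotropy = anisotropy,
                 residual_eigenvalues = residual_eigenvalues,
                 along_pmax_displacements = along,
                 orthogonal_displacements = orthogonal_displacements,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# orthonormal basis whose first column is v (deterministic completion)
.basis_from <- function(v) {
  p <- length(v)
  Q <- qr.Q(qr(cbind(v, diag(p))))[, seq_len(p), drop = FALSE]
  if (sum(Q[, 1L] * v) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

#' Generate a grouped shape dataset from a synthetic configuration
#'
#' @param cfg a [synthetic_config()].
#' @return a [grouped_dataset()] with groups `G1..Gg` and variables named
#'   like the 14-FC tables (`UM1A1..` when p = 14, else `V1..Vp`);
#'   deterministic under `cfg$seed`.
#' @export
generate_grouped_shapes <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  p <- cfg$p
  V <- .basis_from(cfg$pmax_direction)
  lambda <- c(cfg$anisotropy * cfg$residual_eigenvalues[1L],
              cfg$residual_eigenvalues)
  set.seed(cfg$seed)
  vals <- vector("list", cfg$n_groups)
  for (i in seq_len(cfg$n_groups)) {
    ni <- cfg$n_per_group[i]
    mu <- cfg$along_pmax_displacements[i] * cfg$pmax_direction +
      cfg$orthogonal_displacements[i, ]
    Z <- matrix(stats::rnorm(ni * p), ni, p)
    vals[[i]] <- sweep(Z, 2L, sqrt(lambda), `*`) %*% t(V) +
      matrix(mu, ni, p, byrow = TRUE)
  }
  values <- do.call(rbind, vals)
  colnames(values) <- if (p == 14L) {
    c(paste0("UM1A", 1:7), paste0("UM1B", 1:7))
  } else paste0("V", seq_len(p))
  grouped_dataset(values, rep(paste0("G", seq_len(cfg$n_groups)),
                              cfg$n_per_group))
}

#' Island-style synthetic configuration
#'
#' Group means displaced along the shared Pmax only (divergence down the
#' line of least resistance), evenly spread over +/- 1.5 within-group
#' standard deviations along Pmax so between- and within-group variance
#' along that line are comparable.
#'
#' @param n_groups,n_per_group,p,anisotropy,seed see [synthetic_config()].
#' @return a `synthetic_config`.
#' @export
island_config <- function(n_groups = 7L, n_per_group = 40L, p = 14L,
                          anisotropy = 10, seed = 1L) {
  sd1 <- sqrt(anisotropy)          # lambda2 defaults to 1
  synthetic_config(n_groups = n_groups, n_per_group = n_per_group, p = p,
                   anisotropy = anisotropy,
                   along_pmax_displacements =
                     seq(-1.5, 1.5, length.out = n_groups) * sd1,
                   seed = seed)
}

#' Clade-style synthetic configuration
#'
#' Group means displaced only orthogonally to the shared Pmax, along one
#' fixed "clade" axis, with a spread small in absolute terms (so the total
#' variance stays dominated by Pmax) but large relative to the within-group
#' variance in that direction.
#'
#' @inheritParams island_config
#' @return a `synthetic_config`; the clade axis is stored in
#'   `attr(, "clade_axis")`.
#' @export
clade_config <- function(n_groups = 7L, n_per_group = 40L, p = 14L,
                         anisotropy = 10, seed = 1L) {
  base <- synthetic_config(n_groups = n_groups, n_per_group = n_per_group,
                           p = p, anisotropy = anisotropy, seed = seed)
  u <- .basis_from(base$pmax_direction)[, 2L]   # within-group sd 1 here
  disp <- outer(seq(-1.5, 1.5, length.out = n_groups) * 1.6, u)
  cfg <- synthetic_config(n_groups = n_groups, n_per_group = n_per_group,
                          p = p, anisotropy = anisotropy,
                          orthogonal_displacements = disp, seed = seed)
  attr(cfg, "clade_axis") <- u
  cfg
}

#' Read a Fourier-coefficient table
#'
#' Reads the study's data format: a delimited text table whose header
#' contains a group column `Loc` and the 14 coefficient columns
#' `UM1A1..UM1A7`, `UM1B1..UM1B7` (any column order; tab or whitespace
#' delimited; `#` comment lines allowed; decimal point only). Extra columns
#' are ignored with a warning.
#'
#' @param path file path.
#' @return a [grouped_dataset()] with columns ordered `UM1A1..A7, UM1B1..B7`
#'   and group labels from `Loc`.
#' @export
read_fc_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#",
                          colClasses = "character", check.names = FALSE)
  wanted <- c(paste0("UM1A", 1:7), paste0("UM1B", 1:7))
  for (cn in c("Loc", wanted)) {
    hits <- sum(colnames(df) == cn)
    if (hits == 0L) stop("missing column '", cn, "'", call. = FALSE)
    if (hits > 1L) stop("duplicate column '", cn, "'", call. = FALSE)
  }
  extra <- setdiff(colnames(df), c("Loc", wanted))
  if (length(extra))
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  vals <- matrix(NA_real_, nrow(df), length(wanted),
                 dimnames = list(NULL, wanted))
  for (cn in wanted) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop("non-numeric value in column '", cn, "', row ", bad,
           " ('", df[[cn]][bad], "')", call. = FALSE)
    }
    vals[, cn] <- v
  }
  grouped_dataset(vals, df$Loc)
}

#' Write a grouped dataset as a Fourier-coefficient table
#'
#' Tab-delimited, full precision, header `Loc` + variable names; readable by
#' [read_fc_table()] when p = 14 (otherwise columns are named `V1..Vp` with
#' a warning). Group labels containing whitespace are rejected, since the
#' format is plain delimited text.
#'
#' @param data a [grouped_dataset()].
#' @param path output file path.
#' @export
write_fc_table <- function(data, path) {
  stopifnot(inherits(data, "grouped_dataset"))
  labs <- as.character(data$groups)
  if (any(grepl("[[:space:]]", labs)))
    stop("group labels must not contain whitespace", call. = FALSE)
  vals <- data$values
  if (ncol(vals) == 14L) {
    colnames(vals) <- c(paste0("UM1A", 1:7), paste0("UM1B", 1:7))
  } else {
    warning("dataset does not have 14 variables: writing generic V1..Vp ",
            "column names", call. = FALSE)
    colnames(vals) <- paste0("V", seq_len(ncol(vals)))
  }
  df <- data.frame(Loc = labs, vals, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
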