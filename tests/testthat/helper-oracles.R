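# Independent oracles and fixture builders used across the suite.

# rotate a 2-column point set by angle a (counterclockwise)
rotate_pts <- function(pts, a) {
  pts %*% t(matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L))
}

# equal-angle samples of an ellipse with semi-axes ax, ay
ellipse_pts <- function(ax, ay, n = 128L, phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1L) / n
  cbind(ax * cos(th), ay * sin(th))
}

# dense numerical-integration oracle for the elliptic Fourier coefficients:
# resample the closed polygon very finely at equal arc length and integrate
# x(t) cos/sin(2 pi h t / T) by the trapezoid rule. Independent of the
# closed-form implementation path.
efa_oracle <- function(pts, n_harmonics, n_dense = 20000L) {
  dense <- unclass(shapevar::resample_equal_arclength(pts, n_dense))
  T_ <- shapevar::outline_perimeter(dense)
  tt <- T_ * (seq_len(n_dense) - 1L) / n_dense
  out <- matrix(0, n_harmonics, 4L,
                dimnames = list(NULL, c("a", "b", "c", "d")))
  for (h in seq_len(n_harmonics)) {
    ch <- cos(2 * pi * h * tt / T_)
    sh <- sin(2 * pi * h * tt / T_)
    out[h, ] <- (2 / n_dense) * c(sum(dense[, 1L] * ch),
                                  sum(dense[, 1L] * sh),
                                  sum(dense[, 2L] * ch),
                                  sum(dense[, 2L] * sh))
  }
  out
}

# brute-force discrete radial Fourier sums (plain loops, raw coefficients)
radial_oracle <- function(pts, n_harmonics) {
  ctr <- colMeans(pts)
  r <- sqrt((pts[, 1L] - ctr[1L])^2 + (pts[, 2L] - ctr[2L])^2)
  N <- length(r)
  A <- B <- numeric(n_harmonics)
  for (h in seq_len(n_harmonics)) {
    sa <- sb <- 0
    for (j in 0:(N - 1L)) {
      sa <- sa + r[j + 1L] * cos(2 * pi * h * j / N)
      sb <- sb + r[j + 1L] * sin(2 * pi * h * j / N)
    }
    A[h] <- 2 * sa / N
    B[h] <- 2 * sb / N
  }
  list(a0 = mean(r), A = A, B = B, r = r)
}

# smooth radial blob at equal angular steps, harmonic content limited to
# `harmonics`; points centered so the polygon centroid is exactly at the mean
radial_blob <- function(n = 64L, harmonics = 2:7, amp = 0.05, seed = 42L) {
  set.seed(seed)
  j <- 0:(n - 1L)
  r <- rep(1, n)
  for (h in harmonics) {
    r <- r + amp * stats::runif(1L, -1, 1) * cos(2 * pi * h * j / n) +
      amp * stats::runif(1L, -1, 1) * sin(2 * pi * h * j / n)
  }
  ang <- 2 * pi * j / n
  pts <- cbind(r * cos(ang), r * sin(ang))
  sweep(pts, 2L, colMeans(pts))
}

# irregular star-shaped 10-gon (no symmetry)
irregular_polygon <- function(seed = 7L, n = 10L) {
  set.seed(seed)
  ang <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, 0.5, 2)
  cbind(r * cos(ang), r * sin(ang))
}

# multinormal draws with given mean and covariance factorization V, lambda
draw_group <- function(n, mu, V, lambda) {
  p <- length(mu)
  Z <- matrix(stats::rnorm(n * p), n, p)
  sweep(Z, 2L, sqrt(lambda), `*`) %*% t(V) + matrix(mu, n, p, byrow = TRUE)
}

# orthonormal basis with first column along v
basis_with <- function(v) {
  p <- length(v)
  Q <- qr.Q(qr(cbind(v, diag(p))))[, seq_len(p), drop = FALSE]
  if (sum(Q[, 1L] * v) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

# grouped dataset whose pooled within-group covariance is EXACTLY sigma2 * I:
# residuals are group-centered then whitened by the empirical pooled factor
isotropic_within_dataset <- function(group_mu, n_per_group, sigma2 = 1,
                                     seed = 11L) {
  set.seed(seed)
  g <- nrow(group_mu)
  p <- ncol(group_mu)
  groups <- factor(rep(seq_len(g), each = n_per_group))
  E <- matrix(stats::rnorm(g * n_per_group * p), ncol = p)
  gm <- rowsum(E, groups) / n_per_group
  Ec <- E - gm[as.integer(groups), , drop = FALSE]
  S <- crossprod(Ec) / (nrow(Ec) - g)
  es <- eigen(S, symmetric = TRUE)
  W <- Ec %*% es$vectors %*% (t(es$vectors) / sqrt(es$values)) * sqrt(sigma2)
  X <- W + group_mu[as.integer(groups), , drop = FALSE]
  shapevar::grouped_dataset(X, paste0("G", groups))
}
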