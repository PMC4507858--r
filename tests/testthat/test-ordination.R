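test_that("variance decomposition matches the hand-worked example", {
  d <- grouped_dataset(matrix(c(0, 2, 4, 6), 4L, 1L), c("a", "a", "b", "b"))
  vd <- variance_decomposition(d)
  expect_equal(as.numeric(vd$T), 5)
  expect_equal(as.numeric(vd$B), 4)
  expect_equal(as.numeric(vd$W), 1)
})

test_that("degenerate groupings give the expected B and W", {
  X <- matrix(rnorm(30), 10L, 3L)
  one <- variance_decomposition(grouped_dataset(X, rep("a", 10L)))
  expect_equal(one$B, matrix(0, 3L, 3L), ignore_attr = TRUE)
  expect_equal(one$W, one$T)
  each <- variance_decomposition(grouped_dataset(X, paste0("s", 1:10)))
  expect_lt(max(abs(each$W)), 1e-14)
  expect_equal(each$B, each$T, tolerance = 1e-12)
})

test_that("T = B + W holds on random grouped datasets", {
  set.seed(20)
  for (i in 1:10) {
    g <- sample(3:6, 1L)
    p <- sample(2:8, 1L)
    n <- sample(20:60, 1L)
    d <- grouped_dataset(matrix(rnorm(n * p), n, p),
                         sample(letters[seq_len(g)], n, replace = TRUE))
    vd <- variance_decomposition(d)
    expect_lt(max(abs(vd$T - vd$B - vd$W)) / max(abs(vd$T)), 1e-10)
    expect_gte(min(eigen(vd$B, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("PCA recovers closed-form eigenvalues of a known covariance", {
  # empirical covariance fixed exactly at [[2,1],[1,2]] (divisor n here)
  X <- matrix(rnorm(400), 200L, 2L)
  X <- sweep(X, 2L, colMeans(X))
  S <- crossprod(X) / 200
  X <- X %*% solve(chol(S)) %*% chol(matrix(c(2, 1, 1, 2), 2L))
  d <- grouped_dataset(X, rep(c("a", "b"), 100L))
  suppressWarnings(p <- pca(d, 2L))
  expect_equal(p$eigenvalues, c(3, 1), tolerance = 1e-9)
  expect_equal(p$percent_variance, c(75, 25), tolerance = 1e-9)
  expect_equal(sum(p$percent_variance), 100, tolerance = 1e-9)
})

test_that("trace identities link eigenvalues to T and B", {
  d <- generate_grouped_shapes(island_config(seed = 8L))
  vd <- variance_decomposition(d)
  expect_equal(sum(pca(d)$eigenvalues), sum(diag(vd$T)), tolerance = 1e-10)
  expect_equal(sum(bgpca(d)$eigenvalues), sum(diag(vd$B)), tolerance = 1e-8)
})

test_that("two groups give one between-group axis carrying 100%", {
  d <- grouped_dataset(matrix(rnorm(80), 40L, 2L), rep(c("a", "b"), 20L))
  suppressWarnings(b <- bgpca(d, 1L))
  expect_length(b$eigenvalues, 1L)
  expect_equal(b$percent_variance, 100)
})

test_that("bgPCA axis 1 recovers a known direction of group means", {
  set.seed(4)
  v <- c(3, 1, -2, 0.5); v <- v / sqrt(sum(v^2))
  mu <- outer(seq(-2, 2, length.out = 5L), v)
  X <- do.call(rbind, lapply(1:5, function(i)
    matrix(rnorm(30 * 4, sd = 0.1), 30L, 4L) +
      matrix(mu[i, ], 30L, 4L, byrow = TRUE)))
  b <- bgpca(grouped_dataset(X, rep(1:5, each = 30L)), 4L)
  expect_gt(vector_correlation(b$loadings[, 1L], v, "cosine"), 0.99)
})

test_that("bgPCA and CVA agree with ade4 on eigen-structure", {
  skip_if_not_installed("ade4")
  d <- generate_grouped_shapes(island_config(seed = 3L))
  # ade4 re-evaluates the dudi call lazily, so the data frame must live
  # somewhere its eval.parent() chain can see
  assign(".sv_ade4_df", as.data.frame(d$values), envir = globalenv())
  withr::defer(rm(".sv_ade4_df", envir = globalenv()))
  dudi <- ade4::dudi.pca(get(".sv_ade4_df", envir = globalenv()),
                         scannf = FALSE, nf = 14L, scale = FALSE)
  bca <- ade4::bca(dudi, d$groups, scannf = FALSE, nf = 6L)
  b <- bgpca(d)
  expect_equal(b$percent_variance[1:6], 100 * bca$eig[1:6] / sum(bca$eig),
               tolerance = 1e-8)
  # ade4::discrimin reports eigenvalues of B against T; convert BW^-1 roots
  n <- nrow(d$values); g <- nlevels(d$groups)
  dis <- ade4::discrimin(dudi, d$groups, scannf = FALSE, nf = 6L)
  mu <- cva(d)$eigenvalues * n / (n - g)
  expect_equal(mu / (1 + mu), dis$eig[1:6], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("CVA eigenvalues equal a brute-force B W^-1 product", {
  set.seed(12)
  for (i in 1:5) {
    d <- grouped_dataset(matrix(rnorm(60 * 4), 60L, 4L),
                         sample(letters[1:5], 60L, replace = TRUE))
    vd <- variance_decomposition(d)
    n <- nrow(d$values); g <- nlevels(d$groups)
    Wp <- vd$W * n / (n - g)
    bf <- sort(Re(eigen(vd$B %*% solve(Wp))$values), decreasing = TRUE)
    expect_equal(cva(d)$eigenvalues, bf[seq_len(g - 1L)], tolerance = 1e-9)
  }
})

test_that("canonical scores have unit pooled within-group variance", {
  d <- generate_grouped_shapes(island_config(seed = 5L))
  cv <- cva(d)
  gm <- rowsum(cv$scores, d$groups) / as.vector(table(d$groups))
  resid <- cv$scores - gm[as.character(d$groups), , drop = FALSE]
  wvar <- diag(crossprod(resid)) / (nrow(resid) - nlevels(d$groups))
  expect_equal(unname(wvar), rep(1, ncol(cv$scores)), tolerance = 1e-9)
})

test_that("CVA is invariant under invertible linear maps of the variables", {
  set.seed(33)
  d <- generate_grouped_shapes(island_config(n_groups = 5L, p = 6L,
                                             seed = 21L))
  cv0 <- cva(d)
  for (i in 1:3) {
    Q <- matrix(rnorm(36), 6L, 6L) + diag(6L)
    d2 <- grouped_dataset(d$values %*% Q, d$groups)
    cv1 <- cva(d2)
    flip <- sign(colSums(cv0$scores * cv1$scores))
    expect_lt(max(abs(sweep(cv1$scores, 2L, flip, `*`) - cv0$scores)), 1e-8)
    expect_equal(cv1$eigenvalues, cv0$eigenvalues, tolerance = 1e-9)
  }
})

test_that("CVA directions coincide with bgPCA under exactly isotropic W", {
  set.seed(14)
  mu <- matrix(rnorm(6 * 5), 6L, 5L)
  d <- isotropic_within_dataset(mu, n_per_group = 20L, sigma2 = 0.5)
  pr <- procrustes_statistic(group_config(bgpca(d, 4L), 4L),
                             group_config(cva(d, 4L), 4L))
  expect_lt(pr$d, 1e-8)
})

test_that("CVA preconditions are enforced", {
  d <- grouped_dataset(matrix(rnorm(10 * 12), 10L, 12L), rep(c("a", "b"), 5L))
  expect_error(cva(d), "n - g >= p")
  X <- matrix(rnorm(40 * 3), 40L, 3L)
  X <- cbind(X, X[, 1L] + X[, 2L])          # exactly collinear variables
  expect_error(cva(grouped_dataset(X, rep(letters[1:4], 10L))),
               "rank-deficient")
})

test_that("PCoA embeds Euclidean distances exactly", {
  set.seed(6)
  P <- matrix(rnorm(24), 8L, 3L,
              dimnames = list(paste0("g", 1:8), NULL))
  d <- as.matrix(dist(P))
  ord <- pcoa(d, n_axes = 7L)
  rec <- as.matrix(dist(ord$scores))
  expect_lt(max(abs(rec - d)), 1e-9)
})

test_that("PCoA of an equilateral triangle has two equal positive eigenvalues", {
  d <- matrix(1, 3L, 3L) - diag(3L)
  rownames(d) <- colnames(d) <- c("a", "b", "c")
  ord <- suppressWarnings(pcoa(d, 2L))
  expect_length(ord$eigenvalues, 2L)
  expect_lt(abs(ord$eigenvalues[1L] - ord$eigenvalues[2L]), 1e-12)
})

test_that("non-Euclidean distances trigger a negative-eigenvalue warning", {
  d <- matrix(2, 4L, 4L) - 2 * diag(4L)
  d[1L, -1L] <- d[-1L, 1L] <- 1          # center closer than circumradius
  rownames(d) <- colnames(d) <- paste0("g", 1:4)
  expect_warning(pcoa(d, 3L), "negative eigenvalues")
})

test_that("PCoA validates its input", {
  m <- matrix(c(0, 1, 2, 0), 2L, 2L)
  expect_error(pcoa(m), "symmetric")
  expect_error(pcoa(matrix(-1, 3L, 3L)), "negative entries")
})
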