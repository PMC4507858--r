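test_that("homogenized variance matches hand and brute-force oracles", {
  # all per-variable variances equal v -> sigma2 = v
  X <- rbind(diag(c(2, 2)), -diag(c(2, 2)), matrix(0, 2L, 2L))
  d <- grouped_dataset(rbind(X, X), rep(c("a", "b"), each = 6L))
  v <- var(X[, 1L])
  expect_equal(homogenized_variance(d), v)

  # two groups, p = 2, variances {1, 4} and {1, 1} -> mean(gm) = 1.5
  g1 <- cbind(scale(1:5)[, 1L], 2 * scale(1:5)[, 1L])   # variances 1, 4
  g2 <- cbind(scale(1:5)[, 1L], scale(1:5)[, 1L] * 1)   # variances 1, 1
  d2 <- grouped_dataset(rbind(g1, g2), rep(c("a", "b"), each = 5L))
  expect_equal(homogenized_variance(d2), 1.5)

  # random dataset vs an independently coded log-mean-exp oracle
  set.seed(1)
  d3 <- generate_grouped_shapes(island_config(seed = 2L))
  oracle <- mean(vapply(levels(d3$groups), function(g) {
    vv <- diag(stats::cov(d3$values[d3$groups == g, ]))
    exp(sum(log(vv)) / length(vv))
  }, numeric(1L)))
  expect_equal(homogenized_variance(d3), oracle, tolerance = 1e-12)

  # zero variance names the group and variable
  bad <- grouped_dataset(cbind(rnorm(6), rep(1, 6L)),
                         rep(c("a", "b"), each = 3L))
  expect_error(homogenized_variance(bad), "group 'a'.*zero variance")
})

test_that("simulated groups match their specification within sampling error", {
  mu <- matrix(seq(-3, 3, length.out = 14L), 1L, 14L,
               dimnames = list("g1", NULL))
  spec <- homogenized_spec(mu, 2000L, sigma2 = 0.4, seed = 9L)
  d <- simulate_homogenized_dataset(spec, 1L)
  S <- stats::cov(d$values)
  expect_true(all(abs(diag(S) - 0.4) < 0.15 * 0.4))
  off <- S[upper.tri(S)]
  expect_lt(max(abs(off)), 4 * 0.4 / sqrt(2000))
  expect_lt(max(abs(colMeans(d$values) - mu[1L, ])),
            4 * sqrt(0.4 / 2000))
})

test_that("replicates are deterministic and independent of each other", {
  mu <- matrix(rnorm(10), 2L, 5L, dimnames = list(c("a", "b"), NULL))
  spec <- homogenized_spec(mu, c(8L, 12L), sigma2 = 1, seed = 3L)
  expect_identical(simulate_homogenized_dataset(spec, 4L),
                   simulate_homogenized_dataset(spec, 4L))
  expect_false(identical(simulate_homogenized_dataset(spec, 4L)$values,
                         simulate_homogenized_dataset(spec, 5L)$values))
})

test_that("spec validation catches bad inputs", {
  mu <- matrix(0, 2L, 3L)
  expect_error(homogenized_spec(mu, 5L, 1), "one entry per group")
  expect_error(homogenized_spec(mu, c(5L, 0L), 1), ">= 1")
  expect_error(homogenized_spec(mu, c(5L, 5L), -1), "positive")
})

test_that("isotropic input data sit inside their own homogenized null", {
  set.seed(21)
  mu <- matrix(rnorm(5 * 6, sd = 1.2), 5L, 6L,
               dimnames = list(paste0("g", 1:5), NULL))
  d <- simulate_homogenized_dataset(
    homogenized_spec(mu, rep(30L, 5L), sigma2 = 1, seed = 17L), 1L)
  sim <- simulation_study(d, n_sim = 199L, n_axes = 4L, seed = 2L)
  for (pr in names(sim$observed_quantile)) {
    expect_gte(sim$observed_quantile[[pr]], 0.025)
    expect_lte(sim$observed_quantile[[pr]], 0.975)
  }
  # with isotropic within-group noise PCA and bgPCA configurations align
  expect_true(all(sim$simulated_d[, "PCA-bgPCA"] < 0.2))
})

test_that("island-style anisotropy pushes bgPCA-CVA into the upper tail", {
  d <- generate_grouped_shapes(island_config(seed = 31L))
  sim <- simulation_study(d, n_sim = 199L, n_axes = 4L, seed = 3L)
  expect_gt(sim$observed_d[["bgPCA-CVA"]],
            stats::quantile(sim$simulated_d[, "bgPCA-CVA"], 0.975))
  expect_equal(unname(sim$observed_quantile[["bgPCA-CVA"]]), 1,
               tolerance = 0.03)
})

test_that("identical seeds give identical simulation results", {
  d <- generate_grouped_shapes(island_config(n_groups = 5L,
                                             n_per_group = 25L, p = 6L,
                                             seed = 1L))
  s1 <- simulation_study(d, n_sim = 20L, seed = 5L)
  s2 <- simulation_study(d, n_sim = 20L, seed = 5L)
  expect_identical(s1$simulated_d, s2$simulated_d)
  expect_identical(s1$observed_d, s2$observed_d)
})

test_that("PCA-bgPCA is the closest pair under the homogenized null", {
  set.seed(22)
  mu <- matrix(rnorm(6 * 8, sd = 1.5), 6L, 8L,
               dimnames = list(paste0("g", 1:6), NULL))
  d <- simulate_homogenized_dataset(
    homogenized_spec(mu, rep(25L, 6L), sigma2 = 1, seed = 23L), 1L)
  sim <- simulation_study(d, n_sim = 99L, seed = 7L)
  mns <- colMeans(sim$simulated_d)
  expect_lt(mns[["PCA-bgPCA"]], mns[["PCA-CVA"]])
  expect_lt(mns[["PCA-bgPCA"]], mns[["bgPCA-CVA"]])
})

test_that("bgPCA-CVA observed quantile grows with input anisotropy", {
  q <- vapply(c(1, 5, 20), function(a) {
    d <- generate_grouped_shapes(island_config(n_groups = 6L,
                                               n_per_group = 30L, p = 8L,
                                               anisotropy = a, seed = 41L))
    simulation_study(d, n_sim = 99L, seed = 4L)$observed_quantile[["bgPCA-CVA"]]
  }, numeric(1L))
  expect_true(all(diff(q) >= 0))
})
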