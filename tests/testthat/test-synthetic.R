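test_that("generated groups recover the configured Pmax direction", {
  cfg <- synthetic_config(n_groups = 4L, n_per_group = 100L, p = 14L,
                          anisotropy = 10, seed = 2L)
  d <- generate_grouped_shapes(cfg)
  hits <- sum(vapply(levels(d$groups), function(g) {
    est <- estimate_pmax(d$values[d$groups == g, , drop = FALSE])
    vector_correlation(est$loading_vector, cfg$pmax_direction) > 0.9
  }, logical(1L)))
  expect_gte(hits, 3L)
})

test_that("island-style data align PCA and bgPCA axis 1 with Pmax", {
  cfg <- island_config(seed = 3L)
  d <- generate_grouped_shapes(cfg)
  expect_gt(vector_correlation(pca(d)$loadings[, 1L], cfg$pmax_direction), 0.9)
  expect_gt(vector_correlation(bgpca(d)$loadings[, 1L], cfg$pmax_direction),
            0.9)
})

test_that("clade-style data put the clade axis on CVA rather than PCA", {
  cfg <- clade_config(seed = 4L)
  u <- attr(cfg, "clade_axis")
  d <- generate_grouped_shapes(cfg)
  r_cva <- vector_correlation(cva(d)$loadings[, 1L], u, "cosine")
  r_pca <- vector_correlation(pca(d)$loadings[, 1L], u, "cosine")
  expect_gt(r_cva, r_pca)
})

test_that("per-group sample covariance converges to the specified one", {
  cfg <- synthetic_config(n_groups = 1L, n_per_group = 50L, p = 6L,
                          anisotropy = 8, seed = 5L)
  V <- basis_with(cfg$pmax_direction)
  lam <- c(8 * cfg$residual_eigenvalues[1L], cfg$residual_eigenvalues)
  Sigma <- V %*% diag(lam) %*% t(V)
  frob <- vapply(c(50L, 500L, 5000L), function(n) {
    cfg_n <- synthetic_config(n_groups = 1L, n_per_group = n, p = 6L,
                              anisotropy = 8, seed = 5L)
    d <- generate_grouped_shapes(cfg_n)
    sqrt(sum((stats::cov(d$values) - Sigma)^2))
  }, numeric(1L))
  expect_true(all(diff(frob) < 0))
})

test_that("configuration invariants are validated", {
  expect_error(synthetic_config(anisotropy = 0.5), "anisotropy")
  expect_error(synthetic_config(pmax_direction = rep(1, 3L), p = 14L),
               "length p")
  bad_orth <- matrix(1, 7L, 14L)
  expect_error(synthetic_config(orthogonal_displacements = bad_orth),
               "orthogonal")
  cfg <- synthetic_config(seed = 1L)
  expect_equal(sum(cfg$pmax_direction^2), 1, tolerance = 1e-12)
})

test_that("generation is deterministic under the seed", {
  cfg <- island_config(n_groups = 3L, n_per_group = 10L, p = 5L, seed = 9L)
  expect_identical(generate_grouped_shapes(cfg)$values,
                   generate_grouped_shapes(cfg)$values)
})

test_that("FC tables round-trip through the study text format", {
  d <- generate_grouped_shapes(island_config(n_groups = 3L,
                                             n_per_group = 5L, seed = 6L))
  f <- withr::local_tempfile(fileext = ".txt")
  write_fc_table(d, f)
  d2 <- read_fc_table(f)
  expect_equal(d2$values, d$values, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(as.character(d2$groups), as.character(d$groups))
})

test_that("the reader enforces and tolerates columns as documented", {
  d <- generate_grouped_shapes(island_config(n_groups = 3L,
                                             n_per_group = 5L, seed = 7L))
  f <- withr::local_tempfile(fileext = ".txt")
  write_fc_table(d, f)

  tab <- utils::read.table(f, header = TRUE, check.names = FALSE)
  f2 <- withr::local_tempfile(fileext = ".txt")
  utils::write.table(tab[, -2L], f2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_fc_table(f2), "missing column 'UM1A1'")

  tab$UM1A8 <- 0
  utils::write.table(tab, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(d3 <- read_fc_table(f2), "UM1A8")
  expect_equal(ncol(d3$values), 14L)

  tab$UM1A8 <- NULL
  tab$UM1A1[3L] <- "oops"
  utils::write.table(tab, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_fc_table(f2), "non-numeric value in column 'UM1A1', row 3")
})

test_that("comment lines are accepted and whitespace labels rejected", {
  d <- generate_grouped_shapes(island_config(n_groups = 3L,
                                             n_per_group = 4L, seed = 8L))
  f <- withr::local_tempfile(fileext = ".txt")
  write_fc_table(d, f)
  txt <- c("# provenance comment", readLines(f))
  writeLines(txt, f)
  expect_silent(read_fc_table(f))

  bad <- grouped_dataset(d$values, sub("G1", "G 1", as.character(d$groups)))
  expect_error(write_fc_table(bad, f), "whitespace")
})

test_that("non-14-variable datasets write generic columns with a warning", {
  d <- grouped_dataset(matrix(rnorm(20), 10L, 2L), rep(c("a", "b"), 5L))
  f <- withr::local_tempfile(fileext = ".txt")
  expect_warning(write_fc_table(d, f), "V1..Vp")
  expect_match(readLines(f, n = 1L), "Loc\tV1\tV2")
})
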