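test_that("covariance entries follow the four-level rule", {
  ## two genes with two omics each in one cluster, plus a second cluster,
  ## reproduces the textbook block pattern
  st <- omics_structure(c(1, 1, 2, 2), n0 = 2)
  S <- as.matrix(build_covariance(st, c(0.8, 0.6, 0.5, 0.1)))
  block <- rbind(c(1.0, 0.8, 0.6, 0.5),
                 c(0.8, 1.0, 0.5, 0.6),
                 c(0.6, 0.5, 1.0, 0.8),
                 c(0.5, 0.6, 0.8, 1.0))
  expect_equal(S[1:4, 1:4], block)
  expect_true(all(S[1:4, 5:8] == 0.1))
  expect_equal(S, t(S))
})

test_that("zero correlations give the identity", {
  st <- toy_structure(c(2, 2), n0 = 2)
  expect_equal(as.matrix(build_covariance(st, c(0, 0, 0, 0))), diag(8))
})

test_that("scenario-1 covariance is positive definite at full scale", {
  st <- build_structure(c(10, 5, 4, 3), n0 = 3)
  S <- as.matrix(build_covariance(st, c(0.8, 0.6, 0.6, 0.1)))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("non-positive-definite configurations are rejected with the smallest eigenvalue", {
  st <- toy_structure(c(2, 2), n0 = 2)
  expect_error(build_covariance(st, c(0.1, 0.2, 0.2, 0.9)),
               "not positive definite.*-2.1")
})

test_that("factored representation matches the dense matrix", {
  st <- omics_structure(c(1, 1, 1, 2, 2, 3), n0 = 2)   # p = 12
  for (pis in list(c(0.8, 0.6, 0.6, 0.1), c(0.6, 0.8, 0.6, 0.1),
                   c(0.5, 0.4, 0.3, 0.2))) {
    cov <- build_covariance(st, pis)
    expect_equal(cov$type, "factored")
    ## rebuild Sigma explicitly from the factor loadings (independent of the
    ## entry-rule construction used by as.matrix)
    L <- cbind(cov$load_global,
               cov$load_cluster * outer(st$cluster_of_col, 1:st$C, "=="),
               cov$load_cluster_type *
                 outer((st$cluster_of_col - 1) * st$n0 + st$type_of_col,
                       1:(st$C * st$n0), "=="),
               cov$load_gene * outer(st$gene_of_col, 1:st$G, "=="))
    S_fac <- L %*% t(L) + diag(cov$sd_resid^2, st$p)
    expect_equal(S_fac, as.matrix(cov), tolerance = 1e-12)
    ## eigenvalues agree with the brute-force dense route
    expect_equal(eigen(S_fac, symmetric = TRUE, only.values = TRUE)$values,
                 eigen(as.matrix(cov), symmetric = TRUE, only.values = TRUE)$values,
                 tolerance = 1e-10)
  }
})

test_that("sample covariance converges to the target at all four levels", {
  sc <- simulation_scenario(5000, pis = c(0.7, 0.5, 0.4, 0.1),
                            dims = c(2, 0, 0, 0), n0 = 3, seed = 42)
  d <- simulate_dataset(sc)
  emp <- cor(d$X)
  expect_lt(max(abs(emp - as.matrix(sc$covariance))), 0.05)
})

test_that("simulated data carry the stated correlation and balanced outcome", {
  sc <- simulation_scenario(200, seed = 3)
  d <- simulate_dataset(sc)
  ## omics of the same gene correlate at pi1 = 0.8
  expect_lt(abs(cor(d$X[, 1], d$X[, 2]) - 0.8), 3 / sqrt(200))
  ## the five signal genes carry the stated coefficient vectors
  expect_equal(d$beta[d$structure$columns_of_gene[[d$true_nonzero_genes[1]]]],
               c(1.5, 1.5, 1.5))
  expect_equal(sort(unique(d$beta[d$beta != 0])),
               sort(unique(c(1.5, 3, -1.2, -1.4, -1.3, -2, -2.8))))
  expect_length(d$true_nonzero_genes, 5)
  ## a null model with zero intercept gives balanced outcomes
  sc0 <- simulation_scenario(400, dims = c(2, 0, 0, 0), n0 = 3,
                             beta_spec = list(), seed = 5)
  d0 <- simulate_dataset(sc0)
  expect_lt(abs(mean(d0$y) - 0.5), 3 / (2 * sqrt(400)))
})

test_that("simulation is reproducible under a fixed seed", {
  sc <- simulation_scenario(50, dims = c(1, 0, 0, 0), seed = 9)
  d1 <- simulate_dataset(sc)
  d2 <- simulate_dataset(sc)
  expect_identical(d1$X, d2$X)
  expect_identical(d1$y, d2$y)
  d3 <- simulate_dataset(sc, seed = 10)
  expect_false(identical(d1$X, d3$X))
})

test_that("label perturbation moves the stated fraction of genes", {
  labels <- rep(1:4, each = 10)
  expect_identical(permute_cluster_labels(labels, 0, seed = 1), as.integer(labels))
  ## reassignment moves exactly round(fraction * G) genes
  pert <- permute_cluster_labels(labels, 0.25, seed = 2, mode = "reassign")
  expect_equal(sum(pert != labels), 10)
  ## full reassignment on two clusters sends every gene to the other cluster
  two <- c(1L, 1L, 2L, 2L)
  expect_identical(permute_cluster_labels(two, 1, seed = 3, mode = "reassign"),
                   c(2L, 2L, 1L, 1L))
  ## shuffling never increases the number of labels and touches <= m genes
  sh <- permute_cluster_labels(labels, 0.5, seed = 4)
  expect_lte(sum(sh != labels), 20)
  expect_true(all(sh %in% 1:4))
})

test_that("16% perturbation realises an ARI near 0.72 on the n=200 design", {
  st <- build_structure(c(10, 5, 4, 3), n0 = 3)
  set.seed(11)
  aris <- replicate(30, adjusted_rand_index(
    permute_cluster_labels(st$cluster_of_gene, 0.16), st$cluster_of_gene))
  expect_lt(abs(mean(aris) - 0.719), 0.03)
})

test_that("datasets round-trip through the TSV writers", {
  sc <- simulation_scenario(12, dims = c(1, 0, 0, 0), seed = 2)
  d <- simulate_dataset(sc)
  prefix <- file.path(tempdir(), "toy")
  write_dataset(d, prefix)
  back <- read_dataset(prefix)
  expect_equal(unname(back$X), unname(d$X), tolerance = 1e-12)
  expect_equal(back$y, d$y)
  expect_equal(back$structure$cluster_of_gene, d$structure$cluster_of_gene)
  expect_equal(colnames(back$X)[1], "cluster1_gene1_omics1")
})
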