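test_that("weight blocks at beta = 0 equal the scaled quarter cross-products", {
  set.seed(1)
  st <- toy_structure(c(2, 2), n0 = 2)
  X <- matrix(rnorm(30 * st$p), 30, st$p)
  y <- rep(c(0, 1), 15)                       # ybar = 0.5 so beta0 = 0
  q2 <- c(1L, 2L)
  W <- build_block_W(X, y, numeric(st$p), 0, st, q2)
  for (g in 1:st$G) {
    cols <- st$columns_of_gene[[g]]
    expect_equal(W$blocks[[g]] * W$scale[g],
                 q2[st$cluster_of_gene[g]] * st$n0 *
                   crossprod(X[, cols]) / 4, tolerance = 1e-12)
    expect_gte(min(eigen(W$blocks[[g]], symmetric = TRUE,
                         only.values = TRUE)$values), 0)
  }
})

test_that("assembled block weights equal the masked scaled dense Hessian", {
  set.seed(2)
  st <- toy_structure(c(2, 1), n0 = 2)        # p = 6, two clusters
  X <- matrix(rnorm(40 * st$p), 40, st$p)
  y <- rbinom(40, 1, 0.5)
  beta <- rnorm(st$p, 0, 0.3); b0 <- -0.2
  q2 <- c(2L, 1L)
  W <- build_block_W(X, y, beta, b0, st, q2)
  ## dense oracle: mask -l'' outside gene blocks, scale by q2c * n0
  Hd <- -hessian_block(X, y, beta, b0, columns = 1:st$p)
  dense <- matrix(0, st$p, st$p)
  for (g in 1:st$G) {
    cols <- st$columns_of_gene[[g]]
    dense[cols, cols] <- q2[st$cluster_of_gene[g]] * st$n0 * Hd[cols, cols]
  }
  assembled <- matrix(0, st$p, st$p)
  for (g in 1:st$G) {
    cols <- st$columns_of_gene[[g]]
    assembled[cols, cols] <- W$blocks[[g]] * W$scale[g]
  }
  expect_equal(assembled, dense, tolerance = 1e-10)
})

test_that("surrogate argmax is exact", {
  set.seed(3)
  st <- toy_structure(c(1, 1), n0 = 2)        # p = 4
  X <- matrix(rnorm(50 * st$p), 50, st$p)
  y <- rbinom(50, 1, 0.5)
  beta <- rnorm(st$p, 0, 0.2)
  W <- build_block_W(X, y, beta, 0, st, c(1L, 1L))
  grad <- gradient(X, y, beta, 0)
  u <- 50
  omega <- surrogate_argmax(beta, grad, W, u)
  ## zero gradient fixes omega at beta
  expect_equal(surrogate_argmax(beta, numeric(st$p), W, u), beta)
  ## doubling u halves the move
  omega2 <- surrogate_argmax(beta, grad, W, 2 * u)
  expect_equal(omega2 - beta, (omega - beta) / 2, tolerance = 1e-10)
  ## numerical maximisation of g agrees with the closed form
  opt <- optim(beta, function(w) -dense_surrogate(X, y, beta, 0, W, u, w),
               method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
  expect_equal(omega, opt$par, tolerance = 1e-5)
  expect_gte(dense_surrogate(X, y, beta, 0, W, u, omega),
             -opt$value - 1e-8)
})

test_that("screening scores are the stated quadratic forms", {
  set.seed(4)
  st <- toy_structure(c(2, 1), n0 = 3)
  X <- matrix(rnorm(60 * st$p), 60, st$p)
  y <- rbinom(60, 1, 0.5)
  q2 <- c(1L, 1L)
  W <- build_block_W(X, y, numeric(st$p), 0.1, st, q2)
  omega <- rnorm(st$p)
  r <- gene_scores(omega, W)
  Rc <- cluster_scores(omega, W)
  for (g in 1:st$G) {
    v <- omega[st$columns_of_gene[[g]]]
    expect_equal(r[g], as.numeric(t(v) %*% W$blocks[[g]] %*% v),
                 tolerance = 1e-12)
  }
  expect_equal(Rc, as.numeric(rowsum(r * W$scale, st$cluster_of_gene)),
               tolerance = 1e-12)
  expect_true(all(r >= 0))
  ## a zeroed gene block scores zero
  omega[st$columns_of_gene[[2]]] <- 0
  expect_equal(gene_scores(omega, W)[2], 0)
})

test_that("constrained selection respects and saturates the constraints", {
  set.seed(5)
  st <- toy_structure(c(3, 2), n0 = 2)
  X <- matrix(rnorm(80 * st$p), 80, st$p)
  y <- rbinom(80, 1, 0.5)
  W <- build_block_W(X, y, numeric(st$p), 0, st, st$Hc)
  omega <- rnorm(st$p)
  ## non-binding constraints zero nothing
  sel <- constrained_select(omega, W, q1 = st$C)
  expect_equal(sel$genes, 1:st$G)
  expect_equal(sel$omega, omega)
  ## binding constraints keep the per-cluster and cluster caps
  W2 <- build_block_W(X, y, numeric(st$p), 0, st, c(1L, 1L))
  sel2 <- constrained_select(omega, W2, q1 = 1)
  expect_length(sel2$clusters, 1)
  expect_length(sel2$genes, 1)
  expect_true(all(sel2$omega[-unlist(st$columns_of_gene[sel2$genes])] == 0))
  ## a gene with zero omega never beats a positive-score sibling
  omega3 <- omega
  omega3[st$columns_of_gene[[1]]] <- 0
  sel3 <- constrained_select(omega3, W2, q1 = 2)
  expect_false(1 %in% sel3$genes)
})

test_that("two-step selection attains the exhaustive surrogate maximum", {
  ## the masking step is exactly the constrained argmax of g over feasible
  ## supports on block-diagonal W; verify by enumeration on tiny designs
  for (seed in 1:50) {
    set.seed(seed)
    sizes <- sample(1:3, sample(2:3, 1), replace = TRUE)
    n0 <- sample(1:2, 1)
    st <- toy_structure(sizes, n0)
    n <- 40
    X <- matrix(rnorm(n * st$p), n, st$p)
    y <- rbinom(n, 1, 0.5)
    beta <- rnorm(st$p, 0, 0.4) * rbinom(st$p, 1, 0.6)
    q1 <- sample(seq_along(sizes), 1)
    q2 <- pmax(1L, sapply(st$Hc, function(h) sample(h, 1)) - 1L)
    u <- 10
    W <- build_block_W(X, y, beta, 0, st, q2)
    grad <- gradient(X, y, beta, 0)
    omega <- surrogate_argmax(beta, grad, W, u)
    sel <- constrained_select(omega, W, q1)
    g_sel <- dense_surrogate(X, y, beta, 0, W, u, sel$omega)
    ## enumerate every feasible support
    best <- -Inf
    all_sets <- expand.grid(rep(list(c(FALSE, TRUE)), st$G))
    for (i in seq_len(nrow(all_sets))) {
      keep <- unlist(all_sets[i, ])
      cl_used <- unique(st$cluster_of_gene[keep])
      if (length(cl_used) > q1) next
      per_cl <- table(factor(st$cluster_of_gene[keep], levels = 1:st$C))
      if (any(per_cl > q2)) next
      w <- omega
      w[!keep[st$gene_of_col]] <- 0
      best <- max(best, dense_surrogate(X, y, beta, 0, W, u, w))
    }
    expect_equal(g_sel, best, tolerance = 1e-9)
  }
})

test_that("non-binding screening reduces to the full maximum likelihood fit", {
  set.seed(6)
  st <- toy_structure(c(2, 2), n0 = 2)
  X <- matrix(rnorm(200 * st$p), 200, st$p)
  y <- rbinom(200, 1, plogis(X %*% rnorm(st$p, 0, 0.5)))
  f <- jsbd(X, y, st, q1 = st$C, q2 = st$Hc)
  expect_equal(sort(f$retained_genes), 1:st$G)
  ref <- glm(y ~ X, family = binomial())
  expect_equal(f$beta, unname(coef(ref)[-1]), tolerance = 1e-5)
  expect_equal(f$beta0, unname(coef(ref)[1]), tolerance = 1e-5)
  expect_true(f$converged)
})

test_that("log-likelihood trace ascends and u dominates the curvature ratio", {
  n_checked <- 0
  for (seed in 1:30) {
    inst <- rand_instance(seed)
    f <- jsbd(inst$X, inst$y, inst$structure, q1 = 2, u = 1e5,
              compute_tau = TRUE)
    expect_true(all(diff(f$loglik_trace) >= -1e-7))
    expect_true(all(f$tau_trace <= 1e5))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 30)
})

test_that("JSD coincides with JSBD when each gene has one omics", {
  set.seed(7)
  st <- toy_structure(c(3, 3), n0 = 1)
  X <- matrix(rnorm(100 * st$p), 100, st$p)
  y <- rbinom(100, 1, plogis(X %*% c(1, 0, 0, -1, 0, 0)))
  f1 <- jsbd(X, y, st, q1 = 2, q2 = c(1L, 1L))
  f2 <- jsbd(X, y, st, q1 = 2, q2 = c(1L, 1L), method = "jsd")
  expect_identical(f1$retained_genes, f2$retained_genes)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
})

test_that("orthonormal within-gene columns give identical JSBD/JSD rankings", {
  set.seed(8)
  st <- toy_structure(c(2, 2), n0 = 2)
  X <- matrix(rnorm(64 * st$p), 64, st$p)
  for (g in 1:st$G) {                          # orthonormalise each gene block
    cols <- st$columns_of_gene[[g]]
    X[, cols] <- qr.Q(qr(X[, cols]))
  }
  y <- rbinom(64, 1, 0.5)
  beta <- numeric(st$p)
  b0 <- qlogis(mean(y))                        # constant eta: exact diagonality
  q2 <- c(1L, 1L)
  grad <- gradient(X, y, beta, b0)
  Wb <- build_block_W(X, y, beta, b0, st, q2, diagonal = FALSE)
  Wd <- build_block_W(X, y, beta, b0, st, q2, diagonal = TRUE)
  rb <- gene_scores(surrogate_argmax(beta, grad, Wb, 1e5), Wb)
  rd <- gene_scores(surrogate_argmax(beta, grad, Wd, 1e5), Wd)
  expect_equal(order(-rb), order(-rd))
  expect_equal(rb, rd, tolerance = 1e-10)
})

test_that("per-cluster scale constants do not alter within-cluster rankings", {
  set.seed(9)
  st <- toy_structure(c(4, 3), n0 = 2)
  X <- matrix(rnorm(90 * st$p), 90, st$p)
  y <- rbinom(90, 1, 0.5)
  beta <- numeric(st$p); b0 <- qlogis(mean(y))
  grad <- gradient(X, y, beta, b0)
  r_scaled <- gene_scores(surrogate_argmax(beta, grad,
    build_block_W(X, y, beta, b0, st, c(2L, 1L), scale_wc = TRUE), 1e5),
    build_block_W(X, y, beta, b0, st, c(2L, 1L), scale_wc = TRUE))
  W1 <- build_block_W(X, y, beta, b0, st, c(2L, 1L), scale_wc = FALSE)
  r_flat <- gene_scores(surrogate_argmax(beta, grad, W1, 1e5), W1)
  for (c in 1:st$C) {
    genes <- st$genes_of_cluster[[c]]
    expect_equal(order(-r_scaled[genes]), order(-r_flat[genes]))
  }
})

test_that("jsbd object methods are coherent", {
  inst <- rand_instance(99, n = 120)
  f <- jsbd(inst$X, inst$y, inst$structure, q1 = 2)
  expect_s3_class(f, "jsbd")
  cf <- coef(f)
  expect_length(cf, inst$structure$p + 1)
  ## support of beta lies inside the retained genes' columns
  expect_true(all(which(cf[-1] != 0) %in% f$retained_columns))
  pr <- predict(f, inst$X, type = "response")
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(qlogis(pr), predict(f, inst$X), tolerance = 1e-10)
  expect_output(print(f), "Joint screening")
  expect_output(print(summary(f)), "Retained genes")
})
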