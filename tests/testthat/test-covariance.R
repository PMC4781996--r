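test_that("Ledoit-Wolf matches an independent reference implementation", {
  # fixture regenerated deterministically; expected values were computed
  # once with scikit-learn's LedoitWolf estimator on the identical matrix
  # and frozen here (agreement to 1e-9).
  set.seed(7)
  n <- 40; p <- 6
  Z <- matrix(rnorm(n * p), n, p)
  Z[, 2] <- Z[, 1] * 0.6 + Z[, 2] * 0.8
  X <- round(Z, 6)
  lw <- ledoit_wolf(X)
  expect_equal(lw$intensity, 0.4480632916, tolerance = 1e-9)
  expect_equal(lw$sigma[1, 1], 1.0143254439, tolerance = 1e-9)
  expect_equal(lw$sigma[1, 2], 0.4783721815, tolerance = 1e-9)
  expect_equal(lw$sigma[3, 6], -0.0971206563, tolerance = 1e-9)
})

test_that("shrinkage intensity is always within [0, 1]", {
  set.seed(20)
  for (dims in list(c(5, 30), c(30, 5), c(10, 10), c(3, 50))) {
    X <- matrix(rnorm(dims[1] * dims[2]), dims[1], dims[2])
    lw <- ledoit_wolf(X)
    expect_gte(lw$intensity, 0)
    expect_lte(lw$intensity, 1)
    # estimate is positive definite whenever some shrinkage is applied
    if (lw$intensity > 0) {
      expect_gt(min(eigen(lw$sigma, symmetric = TRUE,
                          only.values = TRUE)$values), 0)
    }
  }
})

test_that("degenerate zero-variance input warns and returns zero", {
  X <- matrix(5, 6, 4)
  expect_warning(lw <- ledoit_wolf(X), "zero variance")
  expect_equal(unname(lw$sigma), matrix(0, 4, 4))
  expect_equal(lw$intensity, 0)
  expect_error(partial_correlation(lw$sigma), "singular")
})

test_that("the estimator is consistent at large n", {
  set.seed(99)
  X <- matrix(rnorm(5000 * 10), 5000, 10)
  lw <- ledoit_wolf(X)
  expect_lt(max(abs(lw$sigma - diag(10))), 0.1)
})

test_that("partial correlations satisfy the analytic identities", {
  # diagonal covariance: no conditional association anywhere
  pc <- partial_correlation(diag(c(1, 2, 3)))
  expect_equal(unname(pc[upper.tri(pc)]), rep(0, 3))
  expect_equal(unname(diag(pc)), rep(1, 3))

  # P = 2: partial correlation reduces to the Pearson correlation
  S <- matrix(c(2, 0.8, 0.8, 1), 2)
  pc2 <- partial_correlation(S)
  expect_equal(pc2[1, 2], 0.8 / sqrt(2 * 1))

  # Gaussian chain 1-2-3: conditional independence of 1 and 3 given 2
  omega <- matrix(c(1, -0.4, 0, -0.4, 1, -0.4, 0, -0.4, 1), 3)
  sigma <- solve(omega)  # oracle round trip
  pc3 <- partial_correlation(sigma)
  expect_lt(abs(pc3[1, 3]), 1e-8)
  expect_equal(pc3[1, 2], 0.4, tolerance = 1e-10)
  expect_equal(pc3[2, 3], 0.4, tolerance = 1e-10)
})

test_that("partial correlation recovers a sparse precision pattern", {
  set.seed(4)
  p <- 8
  omega <- diag(p)
  omega[1, 2] <- omega[2, 1] <- -0.3
  omega[4, 7] <- omega[7, 4] <- 0.25
  sigma <- solve(omega)
  pc <- partial_correlation(sigma)
  expected_nonzero <- matrix(FALSE, p, p)
  expected_nonzero[1, 2] <- expected_nonzero[2, 1] <- TRUE
  expected_nonzero[4, 7] <- expected_nonzero[7, 4] <- TRUE
  off <- upper.tri(pc)
  expect_true(all(abs(pc[off & !expected_nonzero]) < 1e-8))
  expect_true(all(abs(pc[off & expected_nonzero]) > 0.1))
})

test_that("pipeline reduces to sample-covariance partial correlation as shrinkage vanishes", {
  set.seed(12)
  n <- 4000; p <- 6
  A <- matrix(rnorm(p * p), p)
  sigma_true <- crossprod(A) / p + diag(p)
  X <- matrix(rnorm(n * p), n, p) %*% chol(sigma_true)
  lw <- ledoit_wolf(X)
  expect_lt(lw$intensity, 0.02)
  S <- cov(X) * (n - 1) / n
  pc_plain <- partial_correlation(S)
  pc_lw <- partial_correlation(lw$sigma)
  expect_lt(max(abs(pc_plain - pc_lw)), 0.02)
})

test_that("shrinkage beats the sample covariance when n < P", {
  set.seed(31)
  sigma_true <- make_block_covariance(40, 4, 0.4, 0.05)
  ch <- chol(sigma_true)
  wins <- 0
  n_rep <- 30
  for (r in seq_len(n_rep)) {
    X <- matrix(rnorm(20 * 40), 20, 40) %*% ch
    lw <- ledoit_wolf(X)
    err_lw <- sqrt(sum((lw$sigma - sigma_true)^2))
    err_s <- sqrt(sum((lw$sample_cov - sigma_true)^2))
    if (err_lw < err_s) wins <- wins + 1
  }
  expect_gte(wins, 0.9 * n_rep)
})

test_that("binarization keeps exactly the strongest connections", {
  W <- diag(4)
  W[1, 2] <- W[2, 1] <- 0.9
  W[1, 3] <- W[3, 1] <- -0.8   # magnitude ranking keeps negatives
  W[1, 4] <- W[4, 1] <- 0.7
  W[2, 3] <- W[3, 2] <- 0.6
  W[2, 4] <- W[4, 2] <- 0.5
  W[3, 4] <- W[4, 3] <- 0.4
  g <- binarize_at_sparsity(W, 1 / 3)
  expect_equal(g$n_edges, 2)
  expect_equal(g$adjacency[1, 2], 1L)
  expect_equal(g$adjacency[1, 3], 1L)
  expect_equal(sum(g$adjacency), 4)

  # signed ranking drops the negative edge
  g_pos <- binarize_at_sparsity(W, 1 / 3, positive_only = TRUE)
  expect_equal(g_pos$adjacency[1, 3], 0L)
  expect_equal(g_pos$adjacency[1, 4], 1L)
})

test_that("edge budget uses floor and the 148-region convention holds", {
  set.seed(2)
  W <- matrix(rnorm(148^2), 148)
  W <- (W + t(W)) / 2
  diag(W) <- 1
  g <- binarize_at_sparsity(W, 0.05)
  expect_equal(g$n_edges, 543)      # floor(0.05 * 148*147/2)
  expect_equal(sum(graph_degree(g)), 2 * 543)  # handshake
  expect_error(binarize_at_sparsity(W[1:5, 1:5], 0.05), "0 edges")
})

test_that("ties at the cutoff break lexicographically and reproducibly", {
  W <- diag(4)
  W[upper.tri(W)] <- 0.5            # every pair tied
  W <- W + t(W) - diag(diag(W))
  g1 <- binarize_at_sparsity(W, 1 / 3)
  g2 <- binarize_at_sparsity(W, 1 / 3)
  expect_identical(g1$adjacency, g2$adjacency)
  # the two lexicographically smallest pairs are (1,2), (1,3)
  expect_equal(g1$adjacency[1, 2], 1L)
  expect_equal(g1$adjacency[1, 3], 1L)
  expect_equal(g1$n_edges, 2)
})

test_that("the default sweep yields 31 nested graphs", {
  set.seed(6)
  W <- matrix(rnorm(40^2), 40)
  W <- (W + t(W)) / 2
  diag(W) <- 1
  sweep_g <- sparsity_sweep(W)
  expect_length(sweep_g, 31)
  for (i in seq_len(30)) {
    a <- sweep_g[[i]]$adjacency
    b <- sweep_g[[i + 1]]$adjacency
    expect_true(all(b[a == 1L] == 1L))  # edge sets nested
  }
  expect_length(sparsity_sweep(W, 0.2, 0.2), 1)
})
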