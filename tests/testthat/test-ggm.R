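test_that("correlation input validates, repairs and flags degeneracy", {
  set.seed(1)
  X <- matrix(rnorm(1e5 * 3), ncol = 3)
  ci <- correlation_matrix(X)
  expect_lt(max(abs(ci$S[upper.tri(ci$S)])), 0.02)
  expect_equal(diag(ci$S), rep(1, 3), ignore_attr = TRUE)
  expect_false(ci$repaired)

  # a duplicated column makes the matrix singular; repair is flagged
  Xd <- cbind(X[1:50, ], X[1:50, 1])
  cid <- correlation_matrix(Xd)
  expect_true(cid$repaired)
  expect_gt(min_eig(cid$S), 0)

  expect_error(correlation_matrix(cbind(X[1:50, ], 1)),
               class = "estimation_error")
  expect_error(correlation_matrix(X[1:2, ]), class = "estimation_error")
})

test_that("glasso solves trivial cases exactly", {
  expect_equal(glasso_fit(diag(4), 0.3)$theta, diag(4), ignore_attr = TRUE)
  set.seed(2)
  S <- cor(matrix(rnorm(400), 100, 4))
  lam <- max(abs(S[upper.tri(S)]))
  th <- glasso_fit(S, lam + 1e-12)$theta
  expect_equal(th, diag(1 / diag(S)), ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("glasso matches the p = 2 closed-form solution", {
  S <- matrix(c(1, .6, .6, 1), 2)
  for (lam in c(0.05, 0.2, 0.5)) {
    W <- S
    W[1, 2] <- W[2, 1] <- sign(S[1, 2]) * max(abs(S[1, 2]) - lam, 0)
    expect_equal(glasso_fit(S, lam, tol = 1e-9)$theta, solve(W),
                 tolerance = 1e-7, ignore_attr = TRUE)
  }
})

test_that("glasso agrees with an independent ADMM solver across a sweep", {
  set.seed(42)
  worst <- 0
  for (p in 2:4) for (rep in 1:2) {
    S <- cor(matrix(rnorm(60 * p), 60, p))
    for (lam in c(0.01, 0.05, 0.1, 0.3, 0.6)) {
      d <- max(abs(glasso_fit(S, lam, tol = 1e-9)$theta -
                     admm_glasso(S, lam)))
      worst <- max(worst, d)
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("the penalty grid has the documented endpoints and ordering", {
  S <- diag(3); S[1, 2] <- S[2, 1] <- 0.5; S[1, 3] <- S[3, 1] <- 0.2
  g <- lambda_grid(S)
  expect_equal(length(g), 100)
  expect_equal(g[1], 0.5)
  expect_equal(g[100], 0.005)
  expect_equal(lambda_grid(S, n_lambda = 2, min_ratio = 0.1), c(0.5, 0.05))
  expect_true(all(diff(g) < 0))
  expect_warning(g0 <- lambda_grid(diag(3)), "zero")
  expect_equal(g0, 0)
})

test_that("EBIC evaluates its defining formula", {
  set.seed(3)
  S <- cor(matrix(rnorm(50 * 4), 50, 4))
  th <- glasso_fit(S, 0.1)$theta
  n <- 50; p <- 4
  E <- sum(th[upper.tri(th)] != 0)
  L <- (n / 2) * (determinant(th)$modulus[1] - sum(diag(S %*% th)))
  for (g in c(0, 0.25, 0.5)) {
    expected <- -2 * L + E * log(n) + 4 * E * g * log(p)
    expect_equal(ebic(th, S, n, gamma = g), as.numeric(expected),
                 tolerance = 1e-10)
  }
  # empty model on identity S: penalty term vanishes (E = 0), leaving -2L
  expect_equal(ebic(diag(4), diag(4), 100, gamma = 0.5),
               ebic(diag(4), diag(4), 100, gamma = 0))
  expect_equal(ebic(diag(4), diag(4), 100, gamma = 0.5), 100 * 4)
})

test_that("EBIC model selection recovers sparse truths", {
  # truly empty network: at most one spurious edge at n = 5000
  set.seed(4)
  X <- matrix(rnorm(5000 * 8), ncol = 8)
  net <- estimate_network(X)
  expect_lte(network_summary(net)$n_edges, 1)

  # planted 10-node network: sensitivity >= 0.9 at n = 5000
  truth <- random_pcor_net(10, 0.4, seed = 5)
  Xp <- gaussian_sample(truth, 5000, seed = 6)
  est <- estimate_network(Xp)
  tru <- truth$weights != 0
  eh <- est$weights != 0
  ut <- upper.tri(tru)
  expect_gte(sum(eh[ut] & tru[ut]) / sum(tru[ut]), 0.9)
  expect_equal(network_summary(est)$possible_edges, 45)
})

test_that("edge count is monotone along the penalty path", {
  set.seed(7)
  for (rep in 1:3) {
    X <- matrix(rnorm(300 * 6), ncol = 6)
    net <- estimate_network(X, n_lambda = 50)
    # grid is descending, so counts must be non-decreasing down the path
    expect_true(all(diff(net$path$n_edges) >= 0))
  }
})

test_that("the unpenalized limit recovers inverse-correlation pcors", {
  truth <- random_pcor_net(6, 0.5, seed = 8)
  X <- gaussian_sample(truth, 4000, seed = 9)
  S <- cor(X)
  th <- glasso_fit(S, 1e-6, tol = 1e-9)$theta
  expect_lt(max(abs(precision_to_pcor(th) - precision_to_pcor(solve(S)))),
            1e-3)
})

test_that("estimation is deterministic and ties break toward sparsity", {
  truth <- random_pcor_net(8, 0.4, seed = 10)
  X <- gaussian_sample(truth, 400, seed = 11)
  n1 <- estimate_network(X)
  n2 <- estimate_network(X)
  expect_identical(n1$weights, n2$weights)
  expect_identical(n1$lambda, n2$lambda)
  # selected lambda is the largest among EBIC minimizers
  mins <- which(n1$path$ebic == min(n1$path$ebic))
  expect_equal(n1$lambda, n1$path$lambda[mins[1]])
})

test_that("network summaries report the documented quantities", {
  W <- matrix(0, 10, 10)
  pairs <- which(upper.tri(W), arr.ind = TRUE)[1:39, ]
  for (k in 1:39) {
    W[pairs[k, 1], pairs[k, 2]] <- 0.1
    W[pairs[k, 2], pairs[k, 1]] <- 0.1
  }
  s <- network_summary(W)
  expect_equal(s$possible_edges, 45)
  expect_equal(s$n_edges, 39)
  expect_equal(s$pct_edges, 86.67, tolerance = 0.005 / 86.67)
  expect_equal(s$global_strength, 3.9)

  e <- network_summary(matrix(0, 4, 4))
  expect_true(is.na(e$mean_abs_weight))
  expect_equal(e$n_edges, 0)
})
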