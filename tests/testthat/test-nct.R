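test_that("global strength sums absolute weights over unordered pairs", {
  expect_equal(global_strength(matrix(0, 5, 5)), 0)
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.3
  W[1, 3] <- W[3, 1] <- -0.2
  W[2, 3] <- W[3, 2] <- 0.5
  expect_equal(global_strength(W), 1.0)
})

test_that("the strength statistic is the absolute global-strength gap", {
  # networks engineered to the published group strengths 4.58 and 4.33
  Wa <- matrix(0, 10, 10); Wb <- matrix(0, 10, 10)
  Wa[1, 2] <- Wa[2, 1] <- 0.58; Wb[1, 2] <- Wb[2, 1] <- 0.33
  for (k in 1:8) {
    Wa[k, k + 2] <- Wa[k + 2, k] <- 0.5
    Wb[k, k + 2] <- Wb[k + 2, k] <- 0.5
  }
  expect_equal(global_strength(Wa), 4.58)
  expect_equal(global_strength(Wb), 4.33)
  expect_equal(abs(global_strength(Wa) - global_strength(Wb)), 0.25)
})

test_that("classification of edge changes follows the taxonomy", {
  expect_equal(classify_edge_change(0.13, 0.28, TRUE), "strengthened")
  expect_equal(classify_edge_change(0.16, 0, TRUE), "lost")
  expect_equal(classify_edge_change(0, 0.11, TRUE), "new link")
  expect_equal(classify_edge_change(0.22, 0.09, TRUE), "weakened")
  expect_equal(classify_edge_change(0.9, 0.1, FALSE), "unchanged")
  expect_equal(classify_edge_change(0, 0, TRUE), "unchanged")
})

fabricated_nct <- function(wa, wb, perm_edge) {
  labels <- paste0("V", seq_len(nrow(wa)))
  ut <- upper.tri(wa)
  pairs <- which(ut, arr.ind = TRUE)
  structure(
    list(M = max(abs(wa - wb)[ut]), S = 0, p_M = 1, p_S = 1,
         global_strength = c(a = 0, b = 0),
         edge_diff = data.frame(from = labels[pairs[, 1]],
                                to = labels[pairs[, 2]],
                                weight_a = wa[ut], weight_b = wb[ut],
                                abs_diff = abs(wa - wb)[ut]),
         perm_M = numeric(0), perm_S = numeric(0),
         perm_edge_diff = perm_edge, iterations = nrow(perm_edge),
         seed = 0, smooth = TRUE),
    class = "nct_result")
}

test_that("an edge that is zero everywhere tests as unchanged with p = 1", {
  wa <- wb <- matrix(0, 3, 3)
  perm <- matrix(0, 50, 3)
  tab <- edge_difference_tests(fabricated_nct(wa, wb, perm))
  expect_true(all(tab$p == 1))
  expect_true(all(tab$change == "unchanged"))
})

test_that("null comparisons of one resplit sample are not significant", {
  net <- random_pcor_net(8, 0.5, seed = 1)
  X <- gaussian_sample(net, 600, seed = 2)
  set.seed(3)
  idx <- sample(600, 300)
  res <- nct(X[idx, ], X[-idx, ], iterations = 150, seed = 4)
  expect_gt(res$p_M, 0.05)
  expect_gt(res$p_S, 0.05)
  # +1-smoothed permutation p-values live in [1/(it+1), 1]
  expect_gte(res$p_M, 1 / (res$iterations + 1))
  expect_lte(res$p_M, 1)
})

test_that("S reported by the test equals the gap of its own networks", {
  net <- random_pcor_net(6, 0.5, seed = 5)
  Xa <- gaussian_sample(net, 200, seed = 6)
  Xb <- gaussian_sample(net, 250, seed = 7)
  res <- nct(Xa, Xb, iterations = 100, seed = 8)
  expect_equal(res$S,
               abs(global_strength(res$networks$a) -
                     global_strength(res$networks$b)),
               tolerance = 1e-12)
  expect_equal(res$M, max(res$edge_diff$abs_diff))
})

test_that("swapping group labels leaves the observed statistics unchanged", {
  net <- random_pcor_net(6, 0.5, seed = 9)
  Xa <- gaussian_sample(net, 200, seed = 10)
  Xb <- gaussian_sample(net, 300, seed = 11)
  r1 <- nct(Xa, Xb, iterations = 100, seed = 12)
  r2 <- nct(Xb, Xa, iterations = 100, seed = 12)
  expect_equal(r1$M, r2$M)
  expect_equal(r1$S, r2$S)
  expect_equal(unname(r1$global_strength), rev(unname(r2$global_strength)))
  # p-values are exchangeable in distribution; with finite permutations they
  # agree only up to permutation noise
  expect_lt(abs(r1$p_S - r2$p_S), 0.2)
})

test_that("the planted group difference is detected and classified", {
  cfg <- default_study_config(n_control = 2500L, n_depressed = 2500L,
                              seed = 33L)
  st <- generate_two_group_study(cfg)
  gses <- paste0("s", 1:10)
  Xc <- st$data$values[st$group == "control", gses]
  Xd <- st$data$values[st$group == "depressed", gses]
  res <- nct(Xc, Xd, iterations = 200, seed = 44)
  expect_lte(res$p_S, 0.05)
  expect_equal(res$S, cfg$strength_gap, tolerance = 0.1)

  tab <- edge_difference_tests(res)
  row <- function(i, j) tab[tab$from == i & tab$to == j, ]
  expect_equal(row("s1", "s3")$change, "strengthened")
  expect_equal(row("s5", "s7")$change, "strengthened")
  expect_equal(row("s2", "s9")$change, "new link")
  # the planted lost edge attenuates toward zero; ordinal measurement can
  # leave a residual partial correlation, so either class is a recovery
  expect_true(row("s2", "s3")$change %in% c("lost", "weakened"))
  expect_lt(row("s2", "s3")$weight_b, row("s2", "s3")$weight_a)
  expect_equal(row("s3", "s5")$change, "weakened")
})
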