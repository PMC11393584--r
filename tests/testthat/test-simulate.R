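test_that("random planted networks have the declared edge count and are PD", {
  empty <- make_true_network(6, 0, seed = 1)
  expect_equal(sum(empty$weights != 0), 0)
  expect_equal(pcor_to_covariance(empty), diag(6),
               ignore_attr = TRUE)

  net <- make_true_network(19, 0.3, c(0.05, 0.35), seed = 2,
                           sign_policy = "mixed")
  expect_equal(sum(net$weights[upper.tri(net$weights)] != 0),
               floor(0.3 * 19 * 18 / 2))  # 51

  for (s in 1:5) {
    n <- make_true_network(12, 0.5, c(0.05, 0.3), seed = s,
                           sign_policy = "mixed")
    expect_gt(min_eig(pcor_to_precision(n$weights)), 0)
  }
})

test_that("partial-correlation/covariance maps round-trip", {
  # p = 2: partial equals marginal correlation
  net2 <- true_network(matrix(c(0, .5, .5, 0), 2), c("a", "b"))
  expect_equal(pcor_to_covariance(net2)["a", "b"], 0.5)

  net <- random_pcor_net(5, 0.6, seed = 3)
  S <- pcor_to_covariance(net)
  back <- precision_to_pcor(solve(S))
  expect_lt(max(abs(back - net$weights)), 1e-10)
})

test_that("edge edits apply exactly and enforce their preconditions", {
  W <- matrix(0, 7, 7, dimnames = list(paste0("S", 1:7), paste0("S", 1:7)))
  W["S5", "S7"] <- W["S7", "S5"] <- 0.13
  W["S2", "S3"] <- W["S3", "S2"] <- 0.16
  net <- true_network(W)

  ed <- edge_edits(from = c("S2", "S3", "S5"), to = c("S3", "S6", "S7"),
                   action = c("remove", "add", "strengthen"),
                   weight = c(NA, 0.11, 0.28))
  out <- apply_edge_edits(net, ed)
  expect_identical(out$weights["S2", "S3"], 0)
  expect_equal(out$weights["S3", "S6"], 0.11)
  expect_equal(out$weights["S5", "S7"], 0.28)

  expect_error(apply_edge_edits(net, edge_edits("S5", "S7", "add", 0.1)),
               class = "construction_error")
  expect_error(apply_edge_edits(net, edge_edits("S1", "S2", "remove", NA)),
               class = "construction_error")
  expect_error(apply_edge_edits(net, edge_edits("S1", "X9", "add", 0.1)),
               class = "construction_error")
})

test_that("PD repair never alters protected (edited) edges", {
  # a deliberately near-singular network that needs shrinking
  W <- matrix(0.3, 6, 6,
              dimnames = list(paste0("V", 1:6), paste0("V", 1:6)))
  diag(W) <- 0
  W["V1", "V2"] <- W["V2", "V1"] <- 0.45
  net <- true_network(W)   # uniform dense positives are infeasible
  rep <- repair_pd(net, protect = cbind("V1", "V2"))
  expect_gt(attr(rep, "n_shrink"), 0)
  expect_equal(rep$weights["V1", "V2"], 0.45)
  expect_gt(min_eig(pcor_to_precision(rep$weights)), 0)
})

test_that("likert sampling respects thresholds, shapes and determinism", {
  net <- random_pcor_net(4, 0.5, seed = 8)
  S <- pcor_to_covariance(net)
  # thresholds far out -> a single category
  one <- sample_likert(S, rep(list(c(-20, -10, -5)), 4), 30, seed = 1)
  expect_true(all(one == 4))

  th <- rep(list(qnorm(c(.25, .5, .75))), 4)
  X <- sample_likert(S, th, 100, seed = 2)
  expect_equal(dim(X), c(100, 4))
  expect_true(all(X >= 1 & X <= 4))
  expect_identical(X, sample_likert(S, th, 100, seed = 2))
  expect_error(sample_likert(S, rep(list(c(1, 1)), 4), 10),
               class = "sampling_error")
})

test_that("discretized correlations match the numerically attenuated value", {
  rho <- 0.45
  S <- matrix(c(1, rho, rho, 1), 2)
  cuts <- qnorm(c(.25, .5, .75))
  X <- sample_likert(S, list(cuts, cuts), 5e4, seed = 31)
  r_obs <- cor(X[, 1], X[, 2])
  r_oracle <- attenuated_likert_cor(rho, cuts, cuts)
  expect_lt(abs(r_oracle), rho)                 # discretization attenuates
  expect_equal(r_obs, r_oracle, tolerance = 0.03 / abs(r_oracle))
})

test_that("the two-group study generator plants its declared truth", {
  cfg <- default_study_config(n_control = 120L, n_depressed = 80L, seed = 4L)
  st <- generate_two_group_study(cfg)
  expect_equal(nrow(st$data$values), 200)
  expect_equal(as.vector(table(st$group)), c(120, 80))

  gn <- paste0("S", 1:10)
  gsC <- global_strength(st$networks$control$weights[gn, gn])
  gsD <- global_strength(st$networks$depressed$weights[gn, gn])
  expect_equal(gsC - gsD, cfg$strength_gap, tolerance = 1e-12)

  # planted edits present at their depressed-side values
  Wd <- st$networks$depressed$weights
  prof <- default_edit_profile()
  for (k in seq_len(nrow(prof)))
    expect_equal(Wd[prof$from[k], prof$to[k]], prof$depressed[k])
  # determinism: same config -> bit-identical data and networks
  st2 <- generate_two_group_study(cfg)
  expect_identical(st2$data$values, st$data$values)
  expect_identical(st2$networks$depressed$weights, Wd)
})

test_that("an empty edit list with no gap gives both groups one network", {
  cfg <- default_study_config(n_control = 50L, n_depressed = 40L, seed = 6L)
  cfg$edits <- cfg$edits[0, ]
  cfg$strength_gap <- 0
  st <- generate_two_group_study(cfg)
  expect_identical(st$networks$control$weights, st$networks$depressed$weights)
})

test_that("observed item correlations never exceed the latent ones by more
           than Monte-Carlo noise", {
  cfg <- default_study_config(n_control = 2000L, n_depressed = 50L, seed = 9L)
  st <- generate_two_group_study(cfg)
  latent <- pcor_to_covariance(st$networks$control)
  obs <- cor(st$data$values[st$group == "control", ])
  ut <- upper.tri(latent)
  expect_true(all(abs(obs[ut]) <= abs(latent[ut]) + 0.08))
})
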