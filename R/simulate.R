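#' Construct a planted ground-truth partial-correlation network
#'
#' @param pcor symmetric matrix of partial correlations, zero diagonal.
#' @param labels node labels.
#' @param communities named character vector mapping node -> community.
#' @return A `true_network` (also a `pcor_network`): list with `labels`,
#'   `weights` (partial correlations) and `communities`.
#' @export
true_network <- function(pcor, labels = colnames(pcor), communities = NULL) {
  pcor <- as.matrix(pcor)
  stopifnot(isSymmetric(unname(pcor)), all(diag(pcor) == 0),
            all(abs(pcor) < 1))
  if (is.null(labels)) labels <- paste0("V", seq_len(ncol(pcor)))
  dimnames(pcor) <- list(labels, labels)
  structure(list(labels = labels, weights = pcor, communities = communities),
            class = c("true_network", "pcor_network"))
}

#' Random sparse partial-correlation network
#'
#' Draws `floor(density * p(p-1)/2)` edges uniformly at random, with weights
#' uniform in `weight_range`. Signs follow `sign_policy`: `"positive"` keeps
#' all weights positive; `"mixed"` flips each sign with probability 1/2;
#' `"cross_negative"` keeps within-community edges positive and makes
#' cross-community edges negative (the pattern of self-efficacy/depression
#' bridges). The implied precision matrix is repaired to positive
#' definiteness by uniform shrinkage of the off-diagonals when needed.
#'
#' @param p number of nodes.
#' @param density fraction of possible edges present, in (0, 1].
#' @param weight_range absolute-weight range, within (0, 1).
#' @param communities optional named community vector (names = labels).
#' @param seed RNG seed.
#' @param labels node labels.
#' @param sign_policy one of `"positive"`, `"mixed"`, `"cross_negative"`.
#' @return A `true_network` with an attribute `n_shrink` recording how many
#'   shrinkage steps the positive-definiteness repair used.
#' @export
make_true_network <- function(p, density, weight_range = c(0.05, 0.35),
                              communities = NULL, seed = 1L,
                              labels = NULL,
                              sign_policy = c("positive", "mixed",
                                              "cross_negative")) {
  stopifnot(density >= 0, density <= 1,
            all(abs(weight_range) < 1), weight_range[1] <= weight_range[2])
  sign_policy <- match.arg(sign_policy)
  if (is.null(labels))
    labels <- if (!is.null(communities)) names(communities) else
      paste0("V", seq_len(p))
  n_edges <- floor(density * p * (p - 1) / 2)
  W <- matrix(0, p, p, dimnames = list(labels, labels))
  if (n_edges > 0) {
    pairs <- upper_pairs(p)
    withr_seed <- seed
    set.seed(withr_seed)
    chosen <- sample(nrow(pairs), n_edges)
    w <- stats::runif(n_edges, weight_range[1], weight_range[2])
    sgn <- switch(sign_policy,
      positive = rep(1, n_edges),
      mixed = sample(c(-1, 1), n_edges, replace = TRUE),
      cross_negative = {
        stopifnot(!is.null(communities))
        comm <- communities[labels]
        ifelse(comm[pairs[chosen, 1]] == comm[pairs[chosen, 2]], 1, -1)
      })
    for (k in seq_len(n_edges)) {
      i <- pairs[chosen[k], 1]; j <- pairs[chosen[k], 2]
      W[i, j] <- W[j, i] <- w[k] * sgn[k]
    }
  }
  net <- true_network(W, labels, communities)
  repair_pd(net)
}

#' Repair a planted network to positive definiteness by uniform shrinkage
#'
#' Multiplies non-protected off-diagonal partial correlations by 0.9 until
#' the implied precision matrix has smallest eigenvalue above `tol`.
#' Protected edges (e.g. planted edits) are never altered.
#'
#' @param net a `true_network`.
#' @param protect optional 2-column matrix of protected node-label pairs.
#' @param tol eigenvalue tolerance.
#' @param max_iter maximum shrinkage steps.
#' @return The repaired network; attribute `n_shrink` counts steps taken.
#' @export
repair_pd <- function(net, protect = NULL, tol = 1e-8, max_iter = 100L) {
  W <- net$weights
  mask <- matrix(TRUE, nrow(W), ncol(W), dimnames = dimnames(W))
  diag(mask) <- FALSE
  if (!is.null(protect) && nrow(protect) > 0) {
    for (k in seq_len(nrow(protect))) {
      i <- protect[k, 1]; j <- protect[k, 2]
      mask[i, j] <- mask[j, i] <- FALSE
    }
  }
  n_shrink <- 0L
  while (min_eigen(pcor_to_precision(W)) <= tol) {
    if (n_shrink >= max_iter)
      pkg_stop("construction_error",
               "cannot repair network to positive definiteness: ",
               "protected edges too strong")
    W[mask] <- W[mask] * 0.9
    n_shrink <- n_shrink + 1L
  }
  out <- true_network(W, net$labels, net$communities)
  attr(out, "n_shrink") <- n_shrink
  out
}

#' Precision matrix implied by a partial-correlation matrix
#'
#' Unit diagonal, off-diagonals `-rho_ij`. The inverse of the map used to
#' read partial correlations off an estimated precision matrix.
#'
#' @param pcor partial-correlation matrix (or `true_network`).
#' @return Precision matrix.
#' @export
pcor_to_precision <- function(pcor) {
  W <- as_weight_matrix(pcor)
  K <- -W
  diag(K) <- 1
  K
}

#' Covariance (correlation) matrix implied by a planted network
#'
#' Inverts the implied precision matrix and rescales to unit variances,
#' giving the latent correlation matrix from which data are sampled.
#' Round-trips with [precision_to_pcor()] to numerical precision.
#'
#' @param net a `true_network` or partial-correlation matrix.
#' @return Correlation matrix.
#' @export
pcor_to_covariance <- function(net) {
  K <- pcor_to_precision(net)
  if (!is_pd(K, 0))
    pkg_stop("construction_error", "implied precision is not positive definite")
  S <- solve(K)
  d <- sqrt(diag(S))
  S <- S / tcrossprod(d)
  dimnames(S) <- dimnames(as_weight_matrix(net))
  (S + t(S)) / 2
}

#' Edge-edit list for planting group differences
#'
#' @param from,to node labels of each edited edge.
#' @param action one of `"strengthen"`, `"weaken"`, `"add"`, `"remove"` per
#'   edge.
#' @param weight target weight (ignored for `"remove"`).
#' @return Data frame of class `edge_edits`.
#' @export
edge_edits <- function(from, to, action, weight) {
  if (length(action))
    action <- match.arg(action, c("strengthen", "weaken", "add", "remove"),
                        several.ok = TRUE)
  out <- data.frame(from = from, to = to, action = action, weight = weight,
                    stringsAsFactors = FALSE)
  class(out) <- c("edge_edits", "data.frame")
  out
}

#' Apply planted edge edits to a network
#'
#' `add` requires the current weight to be zero; `remove` sets it to zero;
#' `strengthen`/`weaken` move an existing edge to the target weight. After
#' editing, positive definiteness is re-verified; any repair shrinks only
#' non-edited edges, so planted values survive exactly.
#'
#' @param net a `true_network`.
#' @param edits an [edge_edits()] frame.
#' @param extra_protect additional label pairs the repair must not touch.
#' @return The edited `true_network`.
#' @export
apply_edge_edits <- function(net, edits, extra_protect = NULL) {
  W <- net$weights
  for (k in seq_len(nrow(edits))) {
    i <- edits$from[k]; j <- edits$to[k]
    if (!(i %in% net$labels) || !(j %in% net$labels))
      pkg_stop("construction_error", "edit references unknown node")
    cur <- W[i, j]
    act <- edits$action[k]
    if (act == "add" && cur != 0)
      pkg_stop("construction_error", "add requires absent edge ", i, "-", j)
    if (act == "remove" && cur == 0)
      pkg_stop("construction_error", "remove requires present edge ", i, "-", j)
    w <- if (act == "remove") 0 else edits$weight[k]
    W[i, j] <- W[j, i] <- w
  }
  protect <- rbind(as.matrix(edits[, c("from", "to")]), extra_protect)
  repair_pd(true_network(W, net$labels, net$communities), protect = protect)
}

#' The planted group-difference profile used by the default study generator
#'
#' Eight edited self-efficacy edges: two strengthened, two weakened, one
#' lost and three newly appearing in the depressed group, with the control
#' and depressed weights used for planting.
#'
#' @return Data frame with `from`, `to`, `control`, `depressed`, `action`.
#' @export
default_edit_profile <- function() {
  data.frame(
    from      = c("S1", "S2", "S2", "S3", "S3", "S5", "S1", "S2"),
    to        = c("S3", "S3", "S4", "S5", "S6", "S7", "S9", "S9"),
    control   = c(0.04, 0.16, 0.00, 0.22, 0.00, 0.13, 0.14, 0.00),
    depressed = c(0.16, 0.00, 0.07, 0.09, 0.11, 0.28, 0.04, 0.08),
    action    = c("strengthen", "remove", "add", "weaken", "add",
                  "strengthen", "weaken", "add"),
    stringsAsFactors = FALSE)
}

#' Scale a network's edges so its block global strength sits a fixed gap
#' below a reference network's
#'
#' Multiplies the non-protected edges among `nodes` by a common factor so
#' that the global strength of that block equals the reference block's
#' global strength minus `gap`. Positive definiteness is then re-verified;
#' repair shrinks only edges outside the block, leaving the gap exact.
#'
#' @param net network to rescale.
#' @param reference network defining the target strength.
#' @param gap required strength deficit (reference minus net), >= 0.
#' @param nodes labels of the block over which strength is measured.
#' @param protect label pairs whose weights must not change.
#' @return Rescaled `true_network`.
#' @export
plant_strength_gap <- function(net, reference, gap, nodes = net$labels,
                               protect = NULL) {
  W <- net$weights
  gs_ref <- global_strength(reference$weights[nodes, nodes])
  mask <- matrix(FALSE, nrow(W), ncol(W), dimnames = dimnames(W))
  mask[nodes, nodes] <- TRUE
  diag(mask) <- FALSE
  fixed <- matrix(FALSE, nrow(W), ncol(W), dimnames = dimnames(W))
  if (!is.null(protect) && nrow(protect) > 0)
    for (k in seq_len(nrow(protect))) {
      i <- protect[k, 1]; j <- protect[k, 2]
      fixed[i, j] <- fixed[j, i] <- TRUE
    }
  free <- mask & !fixed
  s_fixed <- sum(abs(W[mask & fixed & upper.tri(W)]))
  s_free <- sum(abs(W[free & upper.tri(W)]))
  target_free <- gs_ref - gap - s_fixed
  if (target_free < 0 || (s_free == 0 && target_free > 0))
    pkg_stop("construction_error", "strength gap infeasible: planted edits ",
             "already exceed the target block strength")
  if (s_free > 0) W[free] <- W[free] * (target_free / s_free)
  out <- true_network(W, net$labels, net$communities)
  # repair, if needed, may only touch edges outside the strength block
  block_pairs <- which(mask & upper.tri(mask), arr.ind = TRUE)
  prot <- cbind(net$labels[block_pairs[, 1]], net$labels[block_pairs[, 2]])
  repair_pd(out, protect = prot)
}

#' Threshold cut-points for a Likert item from category probabilities
#'
#' Places cut-points at standard-normal quantiles of the cumulative
#' category probabilities, so a latent N(0,1) variable discretized at the
#' cut-points has the requested marginal distribution.
#'
#' @param probs category probabilities (sum to 1, all positive).
#' @return Strictly increasing numeric vector of length `length(probs) - 1`.
#' @export
likert_thresholds <- function(probs) {
  stopifnot(all(probs > 0), abs(sum(probs) - 1) < 1e-8)
  qnorm(cumsum(probs)[-length(probs)])
}

#' Discretize multivariate-normal draws into ordinal item responses
#'
#' @param cov latent correlation matrix (positive definite).
#' @param thresholds list of strictly increasing cut-point vectors, one per
#'   item (column of `cov`).
#' @param n number of participants.
#' @param seed RNG seed.
#' @param min_codes integer vector (or scalar) of lowest category codes.
#' @return Integer matrix n x p of category codes.
#' @export
sample_likert <- function(cov, thresholds, n, seed = 1L, min_codes = 1L) {
  p <- ncol(cov)
  stopifnot(length(thresholds) == p)
  for (th in thresholds)
    if (is.unsorted(th, strictly = TRUE))
      pkg_stop("sampling_error", "thresholds must be strictly increasing")
  if (!is_pd(cov, 0)) pkg_stop("sampling_error", "covariance not PD")
  min_codes <- rep_len(as.integer(min_codes), p)
  set.seed(seed)
  Z <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = cov)
  if (n == 1) Z <- matrix(Z, nrow = 1)
  X <- matrix(0L, n, p, dimnames = list(NULL, colnames(cov)))
  for (j in seq_len(p))
    X[, j] <- min_codes[j] + findInterval(Z[, j], thresholds[[j]])
  X
}

#' Default configuration of the synthetic two-group study
#'
#' Emulates the design of the motivating study: a control group (n = 3,094)
#' and a depressed group (n = 560) answering the 10-item GSES (codes 1-4)
#' and the 9-item PHQ-9 (codes 0-3). The depressed group's self-efficacy
#' network carries the planted edit profile plus a global-strength deficit
#' of 0.25 over the GSES block; cross-community (bridge) edges are negative,
#' concentrated on S6 and D9. Item marginals per group approximate the
#' published group means (GSES totals about 27.3 vs 21.9, PHQ-9 totals about
#' 3.4 vs 13.7).
#'
#' @param n_control,n_depressed group sizes.
#' @param density edge density within each instrument's block (questionnaire
#'   item networks are dense; cross-instrument edges are limited to the
#'   planted bridges).
#' @param weight_range absolute weight range for random within-block edges.
#' @param strength_gap planted GSES-block global-strength deficit of the
#'   depressed network.
#' @param edits edit profile data frame (see [default_edit_profile()]).
#' @param seed master seed; all stages derive child seeds from it.
#' @return Named list of generator settings.
#' @export
default_study_config <- function(n_control = 3094L, n_depressed = 560L,
                                 density = 0.82,
                                 weight_range = c(0.03, 0.20),
                                 strength_gap = 0.25,
                                 edits = default_edit_profile(),
                                 seed = 1L) {
  labels <- c(paste0("S", 1:10), paste0("D", 1:9))
  communities <- stats::setNames(
    rep(c("self-efficacy", "depression"), c(10, 9)), labels)
  list(
    n_control = n_control, n_depressed = n_depressed,
    p = 19L, labels = labels, communities = communities,
    density = density, weight_range = weight_range,
    strength_gap = strength_gap, edits = edits,
    # negative self-efficacy <-> depression bridges, hubs S6 and D9
    bridge_edges = data.frame(
      from = c("S6", "S6", "S6", "D9", "D9"),
      to   = c("D1", "D7", "D9", "S1", "S4"),
      weight = c(-0.04, -0.06, -0.05, -0.04, -0.05)),
    gses_probs = list(control  = c(0.08, 0.30, 0.43, 0.19),
                      depressed = c(0.25, 0.40, 0.26, 0.09)),
    phq_probs  = list(control  = c(0.72, 0.20, 0.06, 0.02),
                      depressed = c(0.12, 0.38, 0.36, 0.14)),
    covariates = list(
      age    = list(control = c(15.17, 2.09), depressed = c(14.88, 1.83)),
      female = list(control = 0.427, depressed = 0.5161),
      education = list(control = c(0.3862, 0.5743, 0.0395),
                       depressed = c(0.4392, 0.5392, 0.0216))),
    seed = as.integer(seed))
}

study_item_ids <- function() c(paste0("s", 1:10), paste0("d", 1:9))

#' Generate a synthetic two-group item-response study with planted truth
#'
#' Builds a base (control) network, pins the edit profile's control-side
#' weights into it, derives the depressed network by applying the edits and
#' planting the configured global-strength gap over the GSES block, then
#' samples ordinal responses from each network through the latent-Gaussian
#' threshold model and attaches simulated covariates.
#'
#' @param config list from [default_study_config()].
#' @return List with `data` (an `item_response_matrix` over both groups,
#'   lower-case column names), `group` (factor, planted membership),
#'   `networks` (`control` and `depressed` `true_network`s), and `config`.
#' @export
generate_two_group_study <- function(config = default_study_config()) {
  cfg <- config
  if (cfg$n_control < cfg$p + 1 || cfg$n_depressed < cfg$p + 1)
    warning("group size below p + 1; estimation will rely on regularization")
  # dense positive block per instrument; cross-instrument edges only at the
  # planted bridges
  gses_block <- make_true_network(10, cfg$density, cfg$weight_range,
                                  seed = derive_seed(cfg$seed, "gses-block"),
                                  labels = paste0("S", 1:10),
                                  sign_policy = "positive")
  phq_block <- make_true_network(9, cfg$density, cfg$weight_range,
                                 seed = derive_seed(cfg$seed, "phq-block"),
                                 labels = paste0("D", 1:9),
                                 sign_policy = "positive")
  W <- matrix(0, cfg$p, cfg$p, dimnames = list(cfg$labels, cfg$labels))
  W[paste0("S", 1:10), paste0("S", 1:10)] <- gses_block$weights
  W[paste0("D", 1:9), paste0("D", 1:9)] <- phq_block$weights
  # pin the control-side weights of the edit profile and the bridge edges
  for (k in seq_len(nrow(cfg$edits))) {
    i <- cfg$edits$from[k]; j <- cfg$edits$to[k]
    W[i, j] <- W[j, i] <- cfg$edits$control[k]
  }
  for (k in seq_len(nrow(cfg$bridge_edges))) {
    i <- cfg$bridge_edges$from[k]; j <- cfg$bridge_edges$to[k]
    W[i, j] <- W[j, i] <- cfg$bridge_edges$weight[k]
  }
  pins <- rbind(as.matrix(cfg$edits[, c("from", "to")]),
                as.matrix(cfg$bridge_edges[, c("from", "to")]))
  net_control <- repair_pd(true_network(W, cfg$labels, cfg$communities),
                           protect = pins)
  ed <- edge_edits(cfg$edits$from, cfg$edits$to, cfg$edits$action,
                   cfg$edits$depressed)
  net_depressed <- apply_edge_edits(net_control, ed, extra_protect = pins)
  if (!is.null(cfg$strength_gap) && cfg$strength_gap > 0)
    net_depressed <- plant_strength_gap(
      net_depressed, net_control, cfg$strength_gap,
      nodes = paste0("S", 1:10),
      protect = as.matrix(cfg$edits[, c("from", "to")]))

  thresholds <- function(grp) c(
    rep(list(likert_thresholds(cfg$gses_probs[[grp]])), 10),
    rep(list(likert_thresholds(cfg$phq_probs[[grp]])), 9))
  min_codes <- rep(c(1L, 0L), c(10, 9))
  Xc <- sample_likert(pcor_to_covariance(net_control), thresholds("control"),
                      cfg$n_control, derive_seed(cfg$seed, "likert-control"),
                      min_codes)
  Xd <- sample_likert(pcor_to_covariance(net_depressed),
                      thresholds("depressed"), cfg$n_depressed,
                      derive_seed(cfg$seed, "likert-depressed"), min_codes)
  X <- rbind(Xc, Xd)
  colnames(X) <- study_item_ids()
  group <- factor(rep(c("control", "depressed"),
                      c(cfg$n_control, cfg$n_depressed)),
                  levels = c("control", "depressed"))
  covs <- simulate_covariates(cfg, group)
  data <- item_response_matrix(X, list(gses_scale(), phq9_scale()),
                               covariates = covs)
  list(data = data, group = group,
       networks = list(control = net_control, depressed = net_depressed),
       config = cfg)
}

simulate_covariates <- function(cfg, group) {
  set.seed(derive_seed(cfg$seed, "covariates"))
  n <- length(group)
  grp <- as.character(group)
  age <- numeric(n); gender <- integer(n); edu <- integer(n)
  for (g in c("control", "depressed")) {
    idx <- grp == g
    mpar <- cfg$covariates$age[[g]]
    a <- round(stats::rnorm(sum(idx), mpar[1], mpar[2]))
    age[idx] <- pmin(pmax(a, 12), 18)
    gender[idx] <- rbinom(sum(idx), 1, cfg$covariates$female[[g]])
    ep <- cfg$covariates$education[[g]]
    edu[idx] <- sample(1:3, sum(idx), replace = TRUE, prob = ep / sum(ep))
  }
  data.frame(age = age, gender = gender, education = edu)
}
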