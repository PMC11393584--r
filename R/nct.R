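#' Global strength of a network
#'
#' Sum of absolute edge weights over all unordered node pairs.
#'
#' @param net a `pcor_network` or weight matrix.
#' @return Scalar.
#' @export
global_strength <- function(net) {
  W <- as_weight_matrix(net)
  sum(abs(W[upper.tri(W)]))
}

#' Permutation network comparison test between two groups
#'
#' Estimates one network per group with identical settings, computes the
#' structure-invariance statistic `M` (maximum absolute edge-weight
#' difference) and the global-strength statistic `S` (absolute difference
#' of global strengths), and builds their null distributions by pooling the
#' rows, re-splitting at random into the original group sizes and
#' re-estimating both networks each iteration (penalty re-selected per
#' permuted group). P-values use the add-one smoothing
#' `(#{perm >= obs} + 1) / (iterations + 1)` unless `smooth = FALSE`.
#'
#' @param data_a,data_b item-response matrices (or numeric matrices) for the
#'   two groups, same columns. Group A is conventionally the control group.
#' @param iterations number of permutations.
#' @param seed RNG seed.
#' @param gamma,n_lambda,min_ratio,method estimator settings passed to
#'   [estimate_network()].
#' @param smooth use add-one p-value smoothing.
#' @return An `nct_result`: observed `M`, `S`, `p_M`, `p_S`, per-group
#'   networks and global strengths, permutation distributions (`perm_M`,
#'   `perm_S`), per-edge observed absolute differences (`edge_diff`) and the
#'   per-edge permutation distribution matrix (`perm_edge_diff`).
#' @export
nct <- function(data_a, data_b, iterations = 1000L, seed = 1L,
                gamma = 0.5, n_lambda = 100L, min_ratio = 0.01,
                method = "pearson", smooth = TRUE) {
  Xa <- if (inherits(data_a, "item_response_matrix")) data_a$values else
    as.matrix(data_a)
  Xb <- if (inherits(data_b, "item_response_matrix")) data_b$values else
    as.matrix(data_b)
  if (!identical(colnames(Xa), colnames(Xb)))
    pkg_stop("comparison_error", "groups must share the same item set")
  if (iterations < 100)
    warning("fewer than 100 permutations; p-values are coarse")
  est <- function(X) estimate_network(X, gamma = gamma, n_lambda = n_lambda,
                                      min_ratio = min_ratio, method = method)
  net_a <- est(Xa)
  net_b <- est(Xb)
  ut <- upper.tri(net_a$weights)
  obs_diff <- abs(net_a$weights - net_b$weights)[ut]
  M_obs <- max(obs_diff)
  gs_a <- global_strength(net_a)
  gs_b <- global_strength(net_b)
  S_obs <- abs(gs_a - gs_b)

  pool <- rbind(Xa, Xb)
  na <- nrow(Xa); n <- nrow(pool)
  set.seed(seed)
  perm_M <- perm_S <- numeric(iterations)
  perm_edge <- matrix(NA_real_, iterations, sum(ut))
  failures <- 0L
  for (it in seq_len(iterations)) {
    idx <- sample.int(n, na)
    res <- tryCatch({
      pa <- est(pool[idx, , drop = FALSE])
      pb <- est(pool[-idx, , drop = FALSE])
      d <- abs(pa$weights - pb$weights)[ut]
      list(M = max(d), S = abs(global_strength(pa) - global_strength(pb)),
           edge = d)
    }, error = function(e) NULL)
    if (is.null(res)) {
      failures <- failures + 1L
      perm_M[it] <- perm_S[it] <- NA
      next
    }
    perm_M[it] <- res$M
    perm_S[it] <- res$S
    perm_edge[it, ] <- res$edge
  }
  if (failures > 0.05 * iterations)
    pkg_stop("comparison_error", "estimation failed in ", failures,
             " of ", iterations, " permutations")
  ok <- !is.na(perm_M)
  pval <- function(perm, obs) {
    if (smooth) (sum(perm[ok] >= obs) + 1) / (sum(ok) + 1)
    else mean(perm[ok] >= obs)
  }
  pairs <- which(ut, arr.ind = TRUE)
  labels <- net_a$labels
  structure(
    list(M = M_obs, S = S_obs,
         p_M = pval(perm_M, M_obs), p_S = pval(perm_S, S_obs),
         global_strength = c(a = gs_a, b = gs_b),
         networks = list(a = net_a, b = net_b),
         edge_diff = data.frame(from = labels[pairs[, 1]],
                                to = labels[pairs[, 2]],
                                weight_a = net_a$weights[ut],
                                weight_b = net_b$weights[ut],
                                abs_diff = obs_diff),
         perm_M = perm_M[ok], perm_S = perm_S[ok],
         perm_edge_diff = perm_edge[ok, , drop = FALSE],
         iterations = sum(ok), seed = seed, smooth = smooth),
    class = "nct_result")
}

#' Classify an edge's change between control and depressed networks
#'
#' @param weight_control,weight_depressed the two edge weights.
#' @param significant logical significance flag from the permutation test.
#' @return One of `"unchanged"`, `"lost"`, `"new link"`, `"strengthened"`,
#'   `"weakened"`.
#' @export
classify_edge_change <- function(weight_control, weight_depressed,
                                 significant) {
  if (!significant) return("unchanged")
  if (weight_control != 0 && weight_depressed == 0) return("lost")
  if (weight_control == 0 && weight_depressed != 0) return("new link")
  if (abs(weight_depressed) > abs(weight_control)) return("strengthened")
  if (abs(weight_depressed) < abs(weight_control)) return("weakened")
  "unchanged"
}

#' Per-edge invariance tests from a network comparison result
#'
#' Permutation tail probability of each edge's absolute weight difference,
#' with a change taxonomy (group A read as control, group B as depressed):
#' significant edges are strengthened, weakened, lost (present only in
#' control) or new links (present only in depressed).
#'
#' @param result an `nct_result`.
#' @param alpha significance level for the change classification.
#' @param correction `"none"` (default) or `"holm"` multiplicity correction.
#' @return Data frame with per-edge weights, `abs_diff`, `p` and `change`.
#' @export
edge_difference_tests <- function(result, alpha = 0.05,
                                  correction = c("none", "holm")) {
  correction <- match.arg(correction)
  stopifnot(inherits(result, "nct_result"))
  ed <- result$edge_diff
  nperm <- nrow(result$perm_edge_diff)
  p <- vapply(seq_len(nrow(ed)), function(k) {
    if (result$smooth)
      (sum(result$perm_edge_diff[, k] >= ed$abs_diff[k]) + 1) / (nperm + 1)
    else mean(result$perm_edge_diff[, k] >= ed$abs_diff[k])
  }, numeric(1))
  if (correction == "holm") p <- stats::p.adjust(p, "holm")
  ed$p <- p
  ed$change <- vapply(seq_len(nrow(ed)), function(k)
    classify_edge_change(ed$weight_a[k], ed$weight_b[k], p[k] <= alpha),
    character(1))
  ed
}

#' @export
print.nct_result <- function(x, ...) {
  cat("Network comparison test (", x$iterations, " permutations)\n", sep = "")
  cat(sprintf("  M = %.3f (p = %.3f)   S = %.3f (p = %.3f)\n",
              x$M, x$p_M, x$S, x$p_S))
  cat(sprintf("  global strength: A = %.3f, B = %.3f\n",
              x$global_strength["a"], x$global_strength["b"]))
  invisible(x)
}
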