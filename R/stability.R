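#' Nonparametric bootstrap of edge weights
#'
#' Resamples participants with replacement, re-estimates the network per
#' replicate (penalty re-selected), and summarizes each edge with its point
#' estimate, bootstrap mean and quantile confidence interval.
#'
#' @param data item-response matrix or numeric matrix (rows = participants).
#' @param B bootstrap replicates (warned below 100: CIs get unstable).
#' @param seed RNG seed.
#' @param conf confidence level for the quantile interval.
#' @param ... estimator settings passed to [estimate_network()].
#' @return An `edge_bootstrap_result`: data frame `edges` (per-edge point
#'   estimate, bootstrap mean, CI), matrix `replicates` (B x edges), the
#'   original network, `B`, `seed` and the replicate failure count.
#' @export
edge_bootstrap <- function(data, B = 1000L, seed = 1L, conf = 0.95, ...) {
  X <- if (inherits(data, "item_response_matrix")) data$values else
    as.matrix(data)
  if (B < 100) warning("B < 100: bootstrap CIs will be unstable")
  net <- estimate_network(X, ...)
  ut <- upper.tri(net$weights)
  pairs <- which(ut, arr.ind = TRUE)
  reps <- matrix(NA_real_, B, sum(ut))
  set.seed(seed)
  failures <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(nrow(X), replace = TRUE)
    fit <- tryCatch(estimate_network(X[idx, , drop = FALSE], ...),
                    error = function(e) NULL)
    if (is.null(fit)) { failures <- failures + 1L; next }
    reps[b, ] <- fit$weights[ut]
  }
  if (failures > 0.1 * B)
    pkg_stop("stability_error", failures, " of ", B,
             " bootstrap replicates failed")
  a <- (1 - conf) / 2
  ok <- stats::complete.cases(reps)
  edges <- data.frame(
    from = net$labels[pairs[, 1]], to = net$labels[pairs[, 2]],
    estimate = net$weights[ut],
    boot_mean = colMeans(reps[ok, , drop = FALSE]),
    ci_lower = apply(reps[ok, , drop = FALSE], 2, quantile, a),
    ci_upper = apply(reps[ok, , drop = FALSE], 2, quantile, 1 - a))
  structure(list(edges = edges, replicates = reps[ok, , drop = FALSE],
                 network = net, B = B, seed = seed, failures = failures,
                 conf = conf),
            class = "edge_bootstrap_result")
}

#' Default drop-proportion grid for the case-dropping bootstrap
#'
#' Ten equally spaced proportions from 0.05 to 0.75 (0.05, 0.128, ...,
#' 0.672, 0.75), the grid on which reported CS-coefficients land after
#' rounding.
#'
#' @return Numeric vector of length 10.
#' @export
case_drop_grid <- function() seq(0.05, 0.75, length.out = 10)

#' Case-dropping subset bootstrap of centrality (and edge) stability
#'
#' For each drop proportion q, draws B subsamples retaining
#' `ceiling((1 - q) n)` rows without replacement, re-estimates the network,
#' and records the Pearson correlation between the original sample's
#' centrality vector and the subset's, for each requested index. The index
#' `"edge"` correlates the edge-weight vectors instead.
#'
#' @param data item-response matrix or numeric matrix.
#' @param proportions drop-proportion grid, increasing, within (0, 1).
#' @param B subsamples per proportion.
#' @param seed RNG seed.
#' @param indices subset of `"edge"`, `"strength"`, `"closeness"`,
#'   `"betweenness"`, `"expected_influence"`.
#' @param cor_method correlation between original and subset vectors.
#' @param ... estimator settings passed to [estimate_network()].
#' @return A `case_drop_result`: list with `proportions`, `correlations` (a
#'   named list of B x length(grid) matrices, one per index), `B`, `seed`.
#' @export
case_dropping_bootstrap <- function(data, proportions = case_drop_grid(),
                                    B = 1000L, seed = 1L,
                                    indices = c("edge", "strength",
                                                "closeness", "betweenness",
                                                "expected_influence"),
                                    cor_method = "pearson", ...) {
  X <- if (inherits(data, "item_response_matrix")) data$values else
    as.matrix(data)
  stopifnot(all(proportions > 0), all(proportions < 1),
            !is.unsorted(proportions))
  indices <- match.arg(indices, several.ok = TRUE)
  n <- nrow(X); p <- ncol(X)
  if (ceiling((1 - max(proportions)) * n) < 3 * p)
    warning("smallest retained subsample has fewer than 3p rows")
  net0 <- estimate_network(X, ...)
  ref <- reference_vectors(net0, indices)
  cors <- lapply(indices, function(i)
    matrix(NA_real_, B, length(proportions)))
  names(cors) <- indices
  set.seed(seed)
  failures <- 0L
  for (qi in seq_along(proportions)) {
    keep <- ceiling((1 - proportions[qi]) * n)
    for (b in seq_len(B)) {
      idx <- sample.int(n, keep)
      fit <- tryCatch(estimate_network(X[idx, , drop = FALSE], ...),
                      error = function(e) NULL)
      if (is.null(fit)) { failures <- failures + 1L; next }
      sub <- reference_vectors(fit, indices)
      for (i in indices) {
        if (sd(sub[[i]]) == 0 || sd(ref[[i]]) == 0) next
        cors[[i]][b, qi] <- cor(ref[[i]], sub[[i]], method = cor_method)
      }
    }
  }
  if (failures > 0.1 * B * length(proportions))
    pkg_stop("stability_error", "too many failed subset estimations")
  structure(list(proportions = proportions, correlations = cors,
                 network = net0, B = B, seed = seed, failures = failures),
            class = "case_drop_result")
}

reference_vectors <- function(net, indices) {
  out <- list()
  if ("edge" %in% indices)
    out$edge <- net$weights[upper.tri(net$weights)]
  if ("strength" %in% indices) out$strength <- strength(net)
  if ("closeness" %in% indices) out$closeness <- closeness_centrality(net)
  if ("betweenness" %in% indices)
    out$betweenness <- betweenness_centrality(net)
  if ("expected_influence" %in% indices)
    out$expected_influence <- expected_influence(net)
  out
}

#' Correlation-stability (CS) coefficient
#'
#' The largest drop proportion in the grid at which the lower
#' `(1 - confidence)` empirical quantile of the bootstrap correlations still
#' reaches `cor_threshold`; 0 when no proportion qualifies (reported as
#' "< grid minimum").
#'
#' @param result a `case_drop_result`.
#' @param index which stored index to evaluate.
#' @param cor_threshold required correlation with the original sample.
#' @param confidence probability with which the threshold must be met.
#' @return Named numeric CS value.
#' @export
cs_coefficient <- function(result, index = "strength", cor_threshold = 0.7,
                           confidence = 0.95) {
  stopifnot(inherits(result, "case_drop_result"))
  m <- result$correlations[[index]]
  if (is.null(m)) pkg_stop("stability_error", "index not stored: ", index)
  qs <- apply(m, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(NA_real_)
    quantile(col, 1 - confidence, names = FALSE)
  })
  ok <- which(!is.na(qs) & qs >= cor_threshold)
  cs <- if (length(ok)) max(result$proportions[ok]) else 0
  stats::setNames(cs, index)
}
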