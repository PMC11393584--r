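#' Node strength
#'
#' Sum of absolute edge weights incident to each node.
#'
#' @param net a `pcor_network` or weight matrix.
#' @return Named numeric vector.
#' @export
strength <- function(net) {
  W <- as_weight_matrix(net)
  rowSums(abs(W))
}

#' One-step expected influence
#'
#' Signed sum of each node's edge weights; equals strength on an
#' all-positive network.
#'
#' @inheritParams strength
#' @return Named numeric vector.
#' @export
expected_influence <- function(net) {
  W <- as_weight_matrix(net)
  rowSums(W)
}

# igraph representation with lengths 1/|w| on the edges
as_distance_graph <- function(W) {
  A <- abs(W)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$length <- 1 / igraph::E(g)$weight
  g
}

#' Closeness centrality on inverse-absolute-weight distances
#'
#' Edge lengths are `1/|w_ij|`; `closeness(i) = 1 / sum_j d(i, j)` over
#' shortest-path distances. Nodes that cannot reach every other node get
#' closeness 0 (the convention for disconnected symptom networks).
#'
#' @inheritParams strength
#' @return Named numeric vector.
#' @export
closeness_centrality <- function(net) {
  W <- as_weight_matrix(net)
  p <- ncol(W)
  if (p == 1) return(stats::setNames(0, colnames(W)))
  g <- as_distance_graph(W)
  d <- igraph::distances(g, weights = igraph::E(g)$length)
  tot <- rowSums(d)
  out <- ifelse(is.finite(tot) & tot > 0, 1 / tot, 0)
  stats::setNames(out, colnames(W))
}

#' Betweenness centrality on inverse-absolute-weight distances
#'
#' Weighted shortest-path betweenness with fractional splitting over equal
#' length geodesics and endpoints excluded.
#'
#' @inheritParams strength
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(net) {
  W <- as_weight_matrix(net)
  g <- as_distance_graph(W)
  b <- igraph::betweenness(g, weights = igraph::E(g)$length, directed = FALSE)
  stats::setNames(as.numeric(b), colnames(W))
}

#' Centrality table with optional z-standardization
#'
#' @inheritParams strength
#' @param standardize append z-standardized columns (mean 0, SD 1 across
#'   nodes); a constant column standardizes to zeros with a warning.
#' @return Data frame, one row per node, columns `betweenness`, `closeness`,
#'   `strength`, `expected_influence` and (optionally) their `z_` versions.
#' @export
centrality_table <- function(net, standardize = TRUE) {
  W <- as_weight_matrix(net)
  out <- data.frame(
    node = colnames(W) %||% paste0("V", seq_len(ncol(W))),
    betweenness = betweenness_centrality(W),
    closeness = closeness_centrality(W),
    strength = strength(W),
    expected_influence = expected_influence(W),
    row.names = NULL)
  if (standardize) {
    for (v in c("betweenness", "closeness", "strength",
                "expected_influence")) {
      x <- out[[v]]
      s <- sd(x)
      if (s == 0) {
        warning("constant ", v, " column; z-scores set to 0")
        out[[paste0("z_", v)]] <- rep(0, length(x))
      } else {
        out[[paste0("z_", v)]] <- (x - mean(x)) / s
      }
    }
  }
  out
}
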