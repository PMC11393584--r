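#' Validate a community specification against a network
#'
#' @param net network or weight matrix.
#' @param communities named character vector mapping every node label to a
#'   community.
#' @return The communities vector ordered like the network's nodes.
#' @export
community_spec <- function(net, communities) {
  W <- as_weight_matrix(net)
  labels <- colnames(W) %||% paste0("V", seq_len(ncol(W)))
  missing_nodes <- setdiff(labels, names(communities))
  if (length(missing_nodes))
    pkg_stop("spec_error", "nodes without a community: ",
             paste(missing_nodes, collapse = ", "))
  communities[labels]
}

#' Bridge strength
#'
#' Per node, the sum of absolute edge weights crossing to nodes in other
#' communities; with within-community strength it partitions total strength
#' exactly.
#'
#' @param net network or weight matrix.
#' @param communities named community vector (see [community_spec()]).
#' @return Named numeric vector.
#' @export
bridge_strength <- function(net, communities) {
  W <- as_weight_matrix(net)
  comm <- community_spec(net, communities)
  cross <- outer(comm, comm, "!=")
  rowSums(abs(W) * cross)
}

#' Bridge expected influence (one-step)
#'
#' Signed sum of each node's cross-community edge weights.
#'
#' @inheritParams bridge_strength
#' @return Named numeric vector.
#' @export
bridge_expected_influence <- function(net, communities) {
  W <- as_weight_matrix(net)
  comm <- community_spec(net, communities)
  cross <- outer(comm, comm, "!=")
  rowSums(W * cross)
}

#' Bridge centrality table with the ranked cross-community edge list
#'
#' @inheritParams bridge_strength
#' @return A `bridge_table`: list with `nodes` (per-node bridge strength and
#'   bridge expected influence plus community) and `cross_edges` (cross
#'   community edges sorted by absolute weight, descending).
#' @export
bridge_table <- function(net, communities) {
  W <- as_weight_matrix(net)
  comm <- community_spec(net, communities)
  labels <- colnames(W)
  nodes <- data.frame(
    node = labels, community = unname(comm),
    bridge_strength = unname(bridge_strength(W, communities)),
    bridge_expected_influence =
      unname(bridge_expected_influence(W, communities)),
    row.names = NULL)
  ut <- which(upper.tri(W) & outer(comm, comm, "!=") & W != 0,
              arr.ind = TRUE)
  cross <- data.frame(from = labels[ut[, 1]], to = labels[ut[, 2]],
                      weight = W[ut])
  cross <- cross[order(-abs(cross$weight)), , drop = FALSE]
  rownames(cross) <- NULL
  structure(list(nodes = nodes, cross_edges = cross),
            class = "bridge_table")
}

#' Top bridge nodes by bridge strength
#'
#' @param table a `bridge_table`.
#' @param k how many nodes to report; ties broken by node label order.
#' @return Data frame of the k highest bridge-strength nodes (nodes with
#'   zero bridge strength are excluded; may be empty).
#' @export
top_bridge_nodes <- function(table, k = 2L) {
  stopifnot(k >= 1)
  nodes <- table$nodes
  nodes <- nodes[nodes$bridge_strength > 0, , drop = FALSE]
  nodes <- nodes[order(-nodes$bridge_strength, nodes$node), , drop = FALSE]
  if (k > nrow(nodes))
    warning("k exceeds number of bridging nodes; truncating")
  utils::head(nodes, k)
}
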