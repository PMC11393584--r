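#' Full analysis configuration
#'
#' Bundles generator, estimator, bootstrap and comparison settings with one
#' master seed from which every stochastic stage derives its own stream.
#'
#' @param generator generator settings (see [default_study_config()]); its
#'   seed is overridden by `seed`.
#' @param gamma,n_lambda,min_ratio,method estimator settings.
#' @param boot_B bootstrap replicates for edge accuracy and case dropping.
#' @param drop_grid case-dropping proportion grid.
#' @param stability_indices indices tracked by the case-dropping bootstrap.
#' @param nct_iterations permutations for the network comparison test.
#' @param alpha significance level for edge-change classification.
#' @param correction per-edge multiplicity correction (`"none"`/`"holm"`).
#' @param seed master seed.
#' @return Named list of class `analysis_config`.
#' @export
analysis_config <- function(generator = default_study_config(),
                            gamma = 0.5, n_lambda = 100L, min_ratio = 0.01,
                            method = "pearson",
                            boot_B = 1000L, drop_grid = case_drop_grid(),
                            stability_indices = c("edge", "strength",
                                                  "closeness", "betweenness",
                                                  "expected_influence"),
                            nct_iterations = 1000L, alpha = 0.05,
                            correction = "none", seed = 1L) {
  generator$seed <- as.integer(seed)
  structure(list(generator = generator, gamma = gamma, n_lambda = n_lambda,
                 min_ratio = min_ratio, method = method, boot_B = boot_B,
                 drop_grid = drop_grid,
                 stability_indices = stability_indices,
                 nct_iterations = nct_iterations, alpha = alpha,
                 correction = correction, seed = as.integer(seed)),
            class = "analysis_config")
}

# polynomial rolling hash of the deparsed config, for report provenance
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Run the complete two-group network study
#'
#' Generates (or accepts) a two-group sample, scores and describes it,
#' estimates the per-group self-efficacy networks with centrality and
#' stability analyses, compares the groups with the permutation network
#' comparison test plus per-edge invariance tests, and estimates the pooled
#' combined network with bridge centrality across the two instruments.
#'
#' @param config an [analysis_config()].
#' @param study optional pre-generated study (output of
#'   [generate_two_group_study()]); generated from `config$generator` when
#'   missing.
#' @return A `study_report` list: `descriptives`, `correlations`,
#'   `networks`, `summaries`, `centrality`, `stability` (CS-coefficients and
#'   raw results), `edge_accuracy`, `nct`, `edge_changes`, `bridge`,
#'   `provenance`.
#' @export
run_full_analysis <- function(config = analysis_config(), study = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(study)) study <- generate_two_group_study(config$generator)
  est_args <- list(gamma = config$gamma, n_lambda = config$n_lambda,
                   min_ratio = config$min_ratio, method = config$method)

  scored <- score_sample(study$data)
  descr <- group_comparison_table(scored)
  corr <- correlation_table(
    scored[, c("age", "gender", "education", "phq9_total", "gses_total")])

  gses_cols <- paste0("s", 1:10)
  items <- study$data$values
  groups <- list(control = items[study$group == "control", gses_cols],
                 depressed = items[study$group == "depressed", gses_cols])
  nets <- lapply(groups, function(X) do.call(estimate_network,
                                             c(list(X), est_args)))
  summaries <- lapply(nets, network_summary)
  centr <- lapply(nets, centrality_table)

  stab <- list(); cs <- list(); acc <- list()
  for (g in names(groups)) {
    cd <- do.call(case_dropping_bootstrap,
                  c(list(groups[[g]], proportions = config$drop_grid,
                         B = config$boot_B,
                         seed = derive_seed(config$seed,
                                            paste0("casedrop-", g)),
                         indices = config$stability_indices),
                    est_args))
    stab[[g]] <- cd
    cs[[g]] <- vapply(config$stability_indices,
                      function(i) cs_coefficient(cd, i), numeric(1))
    acc[[g]] <- do.call(edge_bootstrap,
                        c(list(groups[[g]], B = config$boot_B,
                               seed = derive_seed(config$seed,
                                                  paste0("edgeboot-", g))),
                          est_args))
  }

  comparison <- do.call(nct, c(list(groups$control, groups$depressed,
                                    iterations = config$nct_iterations,
                                    seed = derive_seed(config$seed, "nct")),
                               est_args))
  changes <- edge_difference_tests(comparison, alpha = config$alpha,
                                   correction = config$correction)

  pooled <- do.call(estimate_network,
                    c(list(toupper_items(items)), est_args))
  communities <- study$config$communities
  br <- bridge_table(pooled, communities)

  structure(
    list(descriptives = descr, correlations = corr,
         scored = scored, study = study,
         networks = c(nets, list(pooled = pooled)),
         summaries = summaries, centrality = centr,
         stability = stab, cs = cs, edge_accuracy = acc,
         nct = comparison, edge_changes = changes, bridge = br,
         provenance = list(config = config, seed = config$seed,
                           config_hash = config_hash(config),
                           package_version =
                             as.character(utils::packageVersion("psychnet")))),
    class = "study_report")
}

# item columns s1..s10/d1..d9 -> node labels S1..S10/D1..D9
toupper_items <- function(items) {
  out <- items
  colnames(out) <- toupper(colnames(items))
  out
}

#' Export a network as GraphML and as an edge-list CSV
#'
#' @param net `pcor_network` or weight matrix.
#' @param path output path (`.graphml` or `.csv` decides the format).
#' @export
write_network <- function(net, path) {
  W <- as_weight_matrix(net)
  if (grepl("\\.graphml$", path)) {
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    ut <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
    labels <- colnames(W)
    write.csv(data.frame(from = labels[ut[, 1]], to = labels[ut[, 2]],
                         weight = W[ut]),
              path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a GraphML network back into a weight matrix
#'
#' @param path GraphML file written by [write_network()].
#' @return Symmetric weight matrix.
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  n <- igraph::vcount(g)
  A <- if (igraph::ecount(g) == 0) matrix(0, n, n) else
    igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  labels <- igraph::vertex_attr(g, "name") %||%
    igraph::vertex_attr(g, "id") %||% paste0("V", seq_len(n))
  dimnames(A) <- list(labels, labels)
  A
}

#' Export a study report to CSV/JSON/GraphML files
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @param formats subset of `"csv"`, `"json"`, `"graphml"`.
#' @return Invisibly, the paths written.
#' @export
export_report <- function(report, dir,
                          formats = c("csv", "json", "graphml")) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  put <- function(p) { paths <<- c(paths, p); p }
  if ("csv" %in% formats) {
    write.csv(report$descriptives,
              put(file.path(dir, "table1_descriptives.csv")),
              row.names = FALSE)
    write.csv(as.data.frame(report$correlations$r),
              put(file.path(dir, "table2_correlations.csv")))
    for (g in names(report$centrality))
      write.csv(report$centrality[[g]],
                put(file.path(dir, paste0("centrality_", g, ".csv"))),
                row.names = FALSE)
    write.csv(report$edge_changes,
              put(file.path(dir, "table3_edge_changes.csv")),
              row.names = FALSE)
    write.csv(report$bridge$nodes, put(file.path(dir, "bridge_nodes.csv")),
              row.names = FALSE)
    write.csv(report$bridge$cross_edges,
              put(file.path(dir, "bridge_cross_edges.csv")),
              row.names = FALSE)
    for (g in names(report$networks))
      write_network(report$networks[[g]],
                    put(file.path(dir, paste0("network_", g, ".csv"))))
  }
  if ("json" %in% formats)
    jsonlite::write_json(report_summary(report),
                         put(file.path(dir, "report.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if ("graphml" %in% formats)
    for (g in names(report$networks))
      write_network(report$networks[[g]],
                    put(file.path(dir, paste0("network_", g, ".graphml"))))
  invisible(paths)
}

#' Numeric summary of a study report (the JSON payload)
#'
#' @param report a `study_report`.
#' @return Nested list of the report's headline numbers.
#' @export
report_summary <- function(report) {
  s <- report$summaries
  list(
    provenance = list(seed = report$provenance$seed,
                      config_hash = report$provenance$config_hash,
                      package_version = report$provenance$package_version),
    group_sizes = as.list(table(report$scored$group)),
    networks = lapply(s, function(x) x[c("n_nodes", "n_edges", "pct_edges",
                                         "mean_abs_weight",
                                         "global_strength")]),
    cs_coefficients = lapply(report$cs, as.list),
    nct = list(M = report$nct$M, S = report$nct$S,
               p_M = report$nct$p_M, p_S = report$nct$p_S,
               global_strength = as.list(report$nct$global_strength)),
    n_significant_edge_changes =
      sum(report$edge_changes$change != "unchanged"),
    top_bridge_nodes = top_bridge_nodes(report$bridge, 2)$node,
    bridge_strengths = stats::setNames(
      as.list(report$bridge$nodes$bridge_strength),
      report$bridge$nodes$node))
}
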