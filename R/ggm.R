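#' Extract the edge-weight matrix from a network object or matrix
#'
#' @param x a `pcor_network`, `true_network` or symmetric numeric matrix.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
as_weight_matrix <- function(x) {
  if (inherits(x, "pcor_network")) return(x$weights)
  x <- as.matrix(x)
  stopifnot(isSymmetric(unname(x)))
  x
}

#' Correlation input for network estimation
#'
#' Computes the pairwise Pearson (default) or Spearman correlation matrix of
#' an item-response matrix and records the effective sample size. Mildly
#' indefinite matrices are repaired to the nearest positive-definite
#' correlation matrix (eigenvalue clipping), with the repair flagged.
#'
#' @param data an `item_response_matrix` or numeric matrix (rows =
#'   participants).
#' @param method `"pearson"` or `"spearman"`.
#' @return A `correlation_input`: list with `S`, `n`, `method`, `repaired`.
#' @export
correlation_matrix <- function(data, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  X <- if (inherits(data, "item_response_matrix")) data$values else
    as.matrix(data)
  if (nrow(X) < 3) pkg_stop("estimation_error", "need at least 3 rows")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    pkg_stop("estimation_error", "constant item(s): ",
             paste(colnames(X)[sds == 0], collapse = ", "))
  S <- cor(X, method = method)
  repaired <- !is_pd(S, 1e-8)
  if (repaired) S <- repair_correlation(S)
  structure(list(S = S, n = nrow(X), method = method, repaired = repaired),
            class = "correlation_input")
}

as_correlation_input <- function(x, n = NULL) {
  if (inherits(x, "correlation_input")) return(x)
  if (inherits(x, "item_response_matrix") ||
      (is.matrix(x) && (is.null(dim(x)) || nrow(x) != ncol(x) ||
                        !isSymmetric(unname(x)))))
    return(correlation_matrix(x))
  if (is.matrix(x)) {
    stopifnot(!is.null(n))
    return(structure(list(S = x, n = n, method = "pearson", repaired = FALSE),
                     class = "correlation_input"))
  }
  pkg_stop("estimation_error", "cannot interpret input as correlation data")
}

#' Graphical lasso fit at a single penalty
#'
#' Maximizes `log det(Theta) - tr(S Theta) - lambda * sum_{i != j} |theta_ij|`
#' (off-diagonal penalty only, diagonal unpenalized) by block coordinate
#' descent.
#'
#' @param S correlation/covariance matrix or `correlation_input`.
#' @param lambda penalty, >= 0.
#' @param tol convergence tolerance on the maximum parameter change.
#' @param maxit maximum sweeps.
#' @return List with `theta` (precision matrix), `w` (estimated covariance)
#'   and `converged`.
#' @export
glasso_fit <- function(S, lambda, tol = 1e-6, maxit = 10000L) {
  if (inherits(S, "correlation_input")) S <- S$S
  stopifnot(lambda >= 0)
  fit <- .glasso_fit_cpp(S, lambda, tol, maxit)
  if (!fit$converged)
    pkg_stop("convergence_error", "glasso did not converge in ", maxit,
             " sweeps at lambda = ", lambda)
  dimnames(fit$theta) <- dimnames(S)
  fit
}

#' Logarithmic penalty grid for the glasso path
#'
#' Spaced from `lambda_max = max_{i != j} |S_ij|` (the smallest penalty that
#' yields an empty network) down to `lambda_max * min_ratio`.
#'
#' @param S correlation matrix or `correlation_input`.
#' @param n_lambda number of grid points.
#' @param min_ratio smallest penalty as a fraction of `lambda_max`.
#' @return Strictly decreasing numeric vector.
#' @export
lambda_grid <- function(S, n_lambda = 100L, min_ratio = 0.01) {
  if (inherits(S, "correlation_input")) S <- S$S
  lmax <- max(abs(S[upper.tri(S)]))
  if (lmax == 0) {
    warning("all off-diagonal correlations are zero; single-point grid")
    return(0)
  }
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' Extended Bayesian information criterion for a fitted precision matrix
#'
#' `EBIC = -2 L + E log(n) + 4 E gamma log(p)` with
#' `L = (n/2) (log det Theta - tr(S Theta))` and `E` the number of nonzero
#' off-diagonal pairs. `gamma = 0` reduces to the BIC.
#'
#' @param theta precision matrix (positive definite).
#' @param S sample correlation matrix.
#' @param n sample size.
#' @param gamma EBIC hyperparameter, default 0.5.
#' @return EBIC value.
#' @export
ebic <- function(theta, S, n, gamma = 0.5) {
  p <- ncol(theta)
  E <- sum(theta[upper.tri(theta)] != 0)
  L <- (n / 2) * (determinant(theta, logarithm = TRUE)$modulus[1] -
                    sum(S * theta))
  -2 * L + E * log(n) + 4 * E * gamma * log(p)
}

#' Partial correlations from a precision matrix
#'
#' `w_ij = -theta_ij / sqrt(theta_ii theta_jj)`, zero diagonal.
#'
#' @param theta precision matrix.
#' @return Partial-correlation matrix.
#' @export
precision_to_pcor <- function(theta) {
  d <- sqrt(diag(theta))
  W <- -theta / tcrossprod(d)
  diag(W) <- 0
  (W + t(W)) / 2
}

#' Estimate a regularized partial-correlation network
#'
#' Fits the graphical lasso over a descending log-spaced penalty path with
#' warm starts and selects the penalty minimizing the EBIC; ties are broken
#' toward the larger penalty (sparser model). The selected precision matrix
#' is converted to partial correlations.
#'
#' @param x item-response data, numeric matrix, or `correlation_input`.
#' @param gamma EBIC hyperparameter.
#' @param n_lambda,min_ratio penalty-path settings (see [lambda_grid()]).
#' @param method correlation type when `x` is raw data.
#' @param tol,maxit glasso convergence settings.
#' @param n sample size (required only when `x` is a bare correlation
#'   matrix).
#' @return A `pcor_network`: list with `labels`, `weights` (partial
#'   correlations), `theta`, `lambda`, `gamma`, `ebic`, `path` (grid, EBIC
#'   and edge counts per penalty) and `n`.
#' @export
estimate_network <- function(x, gamma = 0.5, n_lambda = 100L,
                             min_ratio = 0.01,
                             method = c("pearson", "spearman"),
                             tol = 1e-6, maxit = 10000L, n = NULL) {
  method <- match.arg(method)
  ci <- if (inherits(x, "correlation_input")) x else
    if (is.matrix(x) && isSymmetric(unname(x)) && all(diag(x) == 1) &&
        !is.null(n)) as_correlation_input(x, n) else
      correlation_matrix(x, method)
  if (ci$n < 10)
    pkg_stop("estimation_error", "need at least 10 observations")
  if (ci$n < ncol(ci$S))
    warning("n < p; estimates rely entirely on regularization")
  grid <- lambda_grid(ci$S, n_lambda, min_ratio)
  path <- .glasso_path_cpp(ci$S, grid, tol, maxit)
  if (any(path$converged == 0))
    pkg_stop("convergence_error", "glasso failed to converge on the path")
  p <- ncol(ci$S)
  ebics <- -ci$n * path$loglik_core + path$n_edges * log(ci$n) +
    4 * path$n_edges * gamma * log(p)
  best <- which.min(ebics)   # grid descends, so first minimum = largest lambda
  theta <- matrix(path$thetas[, best], p, p, dimnames = dimnames(ci$S))
  W <- precision_to_pcor(theta)
  structure(
    list(labels = colnames(ci$S) %||% paste0("V", seq_len(p)),
         weights = W, theta = theta,
         lambda = grid[best], gamma = gamma, ebic = ebics[best],
         path = data.frame(lambda = grid, ebic = ebics,
                           n_edges = path$n_edges),
         n = ci$n, method = ci$method),
    class = "pcor_network")
}

#' Summary statistics of an estimated network
#'
#' @param net a `pcor_network` or weight matrix.
#' @return List with `n_nodes`, `possible_edges`, `n_edges`, `pct_edges`,
#'   `mean_abs_weight` (over nonzero edges; `NA` for an empty network) and
#'   `global_strength`.
#' @export
network_summary <- function(net) {
  W <- as_weight_matrix(net)
  p <- ncol(W)
  w <- W[upper.tri(W)]
  nz <- w[w != 0]
  list(n_nodes = p,
       possible_edges = p * (p - 1) / 2,
       n_edges = length(nz),
       pct_edges = 100 * length(nz) / (p * (p - 1) / 2),
       mean_abs_weight = if (length(nz)) mean(abs(nz)) else NA_real_,
       global_strength = sum(abs(w)))
}

#' @export
print.pcor_network <- function(x, ...) {
  s <- network_summary(x)
  cat("Partial-correlation network:", s$n_nodes, "nodes,", s$n_edges, "of",
      s$possible_edges, sprintf("edges (%.2f%%)", s$pct_edges), "\n")
  if (!is.null(x$lambda))
    cat(sprintf("  lambda = %.4g (EBIC %.1f, gamma %.2g), n = %d\n",
                x$lambda, x$ebic, x$gamma, x$n))
  cat(sprintf("  global strength = %.3f\n", s$global_strength))
  invisible(x)
}
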