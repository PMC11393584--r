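# Independent oracles used across the suite. Each deliberately avoids the
# code path it checks.

# ADMM solver for the penalized log-likelihood
#   max log det(Theta) - tr(S Theta) - lambda * sum_{i != j} |theta_ij|
# (off-diagonal penalty, unpenalized diagonal). Independent of the block
# coordinate-descent implementation in the package.
admm_glasso <- function(S, lambda, rho = 1, iters = 10000, tol = 1e-10) {
  p <- ncol(S)
  Z <- diag(p); U <- matrix(0, p, p)
  for (k in seq_len(iters)) {
    e <- eigen(rho * (Z - U) - S, symmetric = TRUE)
    xi <- (e$values + sqrt(e$values^2 + 4 * rho)) / (2 * rho)
    Theta <- e$vectors %*% (xi * t(e$vectors))
    Zold <- Z
    A <- Theta + U
    Z <- sign(A) * pmax(abs(A) - lambda / rho, 0)
    diag(Z) <- diag(A)
    U <- U + Theta - Z
    if (max(abs(Z - Zold)) < tol && max(abs(Theta - Z)) < tol) break
  }
  Z
}

# All simple paths between two nodes of a weighted graph, by DFS.
all_simple_paths_lengths <- function(W, from, to) {
  p <- ncol(W)
  lens <- list()
  walk <- function(v, visited, len) {
    if (v == to) {
      lens[[length(lens) + 1]] <<- list(len = len, path = visited)
      return()
    }
    for (u in seq_len(p)) {
      if (W[v, u] != 0 && !(u %in% visited)) {
        walk(u, c(visited, u), len + 1 / abs(W[v, u]))
      }
    }
  }
  walk(from, from, 0)
  lens
}

# Brute-force weighted betweenness (fractional splitting, endpoints
# excluded) and shortest-path distances, by exhaustive path enumeration.
brute_force_paths <- function(W) {
  p <- ncol(W)
  btw <- numeric(p)
  dist <- matrix(Inf, p, p); diag(dist) <- 0
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    paths <- all_simple_paths_lengths(W, i, j)
    if (!length(paths)) next
    lens <- vapply(paths, `[[`, numeric(1), "len")
    dmin <- min(lens)
    dist[i, j] <- dist[j, i] <- dmin
    geo <- paths[lens < dmin + 1e-9 * (1 + dmin)]
    for (g in geo) {
      interior <- setdiff(g$path, c(i, j))
      btw[interior] <- btw[interior] + 1 / length(geo)
    }
  }
  list(betweenness = btw, dist = dist)
}

# Pearson correlation of two threshold-discretized standard normals with
# latent correlation rho, by 1-D numerical integration of the orthant
# probabilities (no sampling).
attenuated_likert_cor <- function(rho, cuts1, cuts2) {
  upper_orthant <- function(t, s) {
    f <- function(z) stats::dnorm(z) *
      stats::pnorm((s - rho * z) / sqrt(1 - rho^2), lower.tail = FALSE)
    stats::integrate(f, t, Inf, rel.tol = 1e-10)$value
  }
  m1 <- vapply(cuts1, function(t) stats::pnorm(t, lower.tail = FALSE),
               numeric(1))
  m2 <- vapply(cuts2, function(s) stats::pnorm(s, lower.tail = FALSE),
               numeric(1))
  # X = sum_k 1(Z > t_k): mean = sum m1, var from category probabilities
  px <- diff(c(0, stats::pnorm(cuts1), 1))
  py <- diff(c(0, stats::pnorm(cuts2), 1))
  vx <- sum((0:(length(px) - 1))^2 * px) - sum((0:(length(px) - 1)) * px)^2
  vy <- sum((0:(length(py) - 1))^2 * py) - sum((0:(length(py) - 1)) * py)^2
  cv <- 0
  for (t in seq_along(cuts1)) for (s in seq_along(cuts2))
    cv <- cv + upper_orthant(cuts1[t], cuts2[s]) - m1[t] * m2[s]
  cv / sqrt(vx * vy)
}

# Small random planted network with a guaranteed-PD precision.
random_pcor_net <- function(p, density = 0.4, seed = 1,
                            sign_policy = "mixed") {
  make_true_network(p, density, c(0.05, 0.3), seed = seed,
                    sign_policy = sign_policy)
}

# Write a small item-response CSV for the scales-io tests.
write_study_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

gaussian_sample <- function(net, n, seed) {
  set.seed(seed)
  MASS::mvrnorm(n, rep(0, length(net$labels)), pcor_to_covariance(net))
}

min_eig <- function(m) {
  min(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}
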