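#' @keywords internal
"_PACKAGE"

#' @useDynLib psychnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cor.test pchisq pnorm pt qnorm quantile rbinom sd
#' @importFrom utils read.csv write.csv
NULL

# Deterministic child seed for a named pipeline stage. Keeps every stage
# reproducible from one master seed while decoupling their random streams.
# Result is always a valid 32-bit integer seed.
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((abs(master) * 48271 + h) %% 2147483629)
}

min_eigen <- function(m) {
  min(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

is_pd <- function(m, tol = 1e-8) min_eigen(m) > tol

# Nearest-PD style repair for mildly indefinite correlation matrices:
# eigenvalue clipping followed by rescaling to unit diagonal.
repair_correlation <- function(S, tol = 1e-8) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(e$values) > tol) return(S)
  vals <- pmax(e$values, tol * 10)
  R <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- sqrt(diag(R))
  R <- R / tcrossprod(d)
  diag(R) <- 1
  (R + t(R)) / 2
}

upper_pairs <- function(p) {
  which(upper.tri(diag(p)), arr.ind = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pkg_stop <- function(class, ...) {
  stop(errorCondition(paste0(...), class = c(class, "psychnet_error")))
}
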