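#' Pooled-variance (Student) two-sample t statistic from summary statistics
#'
#' Computes the classical independent-samples t test with a pooled variance
#' estimate and df = n1 + n2 - 2, directly from group means, SDs and sizes,
#' so published summary tables can be recomputed without raw data. The
#' absolute value of t is reported alongside the signed statistic, matching
#' the usual table style.
#'
#' @param m1,sd1,n1 mean, SD and size of group 1.
#' @param m2,sd2,n2 mean, SD and size of group 2.
#' @return List with `t` (signed, m1 - m2 convention), `abs_t`, `df`, `p`
#'   (two-sided).
#' @export
pooled_t <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  sp <- pooled_sd(sd1, n1, sd2, n2)
  if (sp == 0 && m1 == m2)
    pkg_stop("undefined_statistic", "zero variance in both groups")
  tval <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tval, abs_t = abs(tval), df = df,
       p = 2 * pt(abs(tval), df, lower.tail = FALSE))
}

pooled_sd <- function(sd1, n1, sd2, n2) {
  sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
}

#' Cohen's d from summary statistics (pooled-SD standardizer)
#'
#' @inheritParams pooled_t
#' @return Non-negative effect size |m1 - m2| / pooled SD.
#' @export
cohen_d <- function(m1, sd1, n1, m2, sd2, n2) {
  sp <- pooled_sd(sd1, n1, sd2, n2)
  if (sp == 0)
    pkg_stop("undefined_statistic", "pooled SD is zero")
  abs(m1 - m2) / sp
}

#' Pearson chi-square test for a contingency table
#'
#' Applies the Yates continuity correction only to 2 x 2 tables (and only
#' when `continuity = TRUE`, the default), the convention under which the
#' published group-comparison statistics recompute from their printed counts.
#'
#' @param table matrix of non-negative counts, at least 2 x 2.
#' @param continuity apply Yates correction for 2 x 2 tables.
#' @return List with `chisq`, `df`, `p`.
#' @export
chi_square <- function(table, continuity = TRUE) {
  table <- as.matrix(table)
  stopifnot(nrow(table) >= 2, ncol(table) >= 2, all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    pkg_stop("degenerate_table", "zero marginal in contingency table")
  correct <- continuity && nrow(table) == 2 && ncol(table) == 2
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Group-comparison table for continuous and categorical variables
#'
#' Builds Table-1-style rows comparing depressed and control groups:
#' pooled-variance t tests with Cohen's d for continuous variables,
#' chi-square tests (Yates-corrected when 2 x 2) for categorical ones.
#'
#' @param scored data frame from [score_sample()] with a `group` column.
#' @param continuous character vector of continuous variable names.
#' @param categorical character vector of categorical variable names.
#' @return Data frame, one row per variable, with group summaries, the test
#'   statistic, df, p and d where applicable.
#' @export
group_comparison_table <- function(scored,
                                   continuous = c("age", "phq9_total",
                                                  "gses_total"),
                                   categorical = c("gender", "education")) {
  dep <- scored[scored$group == "depressed", , drop = FALSE]
  con <- scored[scored$group == "control", , drop = FALSE]
  rows <- list()
  for (v in intersect(continuous, names(scored))) {
    m1 <- mean(dep[[v]]); s1 <- sd(dep[[v]]); n1 <- nrow(dep)
    m2 <- mean(con[[v]]); s2 <- sd(con[[v]]); n2 <- nrow(con)
    tt <- pooled_t(m1, s1, n1, m2, s2, n2)
    rows[[v]] <- data.frame(
      variable = v, type = "continuous",
      depressed_mean = m1, depressed_sd = s1,
      control_mean = m2, control_sd = s2,
      statistic = tt$abs_t, df = tt$df, p = tt$p,
      cohen_d = cohen_d(m1, s1, n1, m2, s2, n2))
  }
  for (v in intersect(categorical, names(scored))) {
    tab <- table(scored$group, scored[[v]])
    cs <- chi_square(tab)
    rows[[v]] <- data.frame(
      variable = v, type = "categorical",
      depressed_mean = NA, depressed_sd = NA,
      control_mean = NA, control_sd = NA,
      statistic = cs$chisq, df = cs$df, p = cs$p, cohen_d = NA)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pairwise Pearson correlation table with two-sided p-values
#'
#' @param df data frame of numeric variables (>= 3 complete rows; gender and
#'   education should already be numerically coded).
#' @return List with `r` (correlation matrix, unit diagonal) and `p`
#'   (two-sided p-values, NA on the diagonal).
#' @export
correlation_table <- function(df) {
  df <- as.data.frame(df)
  stopifnot(nrow(df) >= 3)
  const <- vapply(df, function(x) sd(x) == 0, logical(1))
  if (any(const))
    pkg_stop("undefined_correlation", "constant column(s): ",
             paste(names(df)[const], collapse = ", "))
  p <- ncol(df)
  r <- cor(df)
  pv <- matrix(NA_real_, p, p, dimnames = dimnames(r))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    pv[i, j] <- pv[j, i] <- cor.test(df[[i]], df[[j]])$p.value
  }
  list(r = r, p = pv)
}
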