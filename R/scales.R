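#' Scale definitions for the GSES and PHQ-9 instruments
#'
#' A scale definition names the instrument, lists its item columns in order,
#' and records the admissible response codes per item. The GSES (General
#' Self-Efficacy Scale) has 10 items coded 1--4 (total 10--40); the PHQ-9
#' (Patient Health Questionnaire) has 9 items coded 0--3 (total 0--27).
#'
#' @param name scale name.
#' @param item_ids ordered character vector of item column names.
#' @param min_code,max_code admissible response codes, shared by all items.
#' @return An object of class `scale_definition` with fields `name`,
#'   `item_ids`, `min_code`, `max_code` and the implied `score_range`.
#' @export
scale_definition <- function(name, item_ids, min_code, max_code) {
  stopifnot(length(item_ids) >= 1, !anyDuplicated(item_ids),
            min_code < max_code)
  structure(
    list(name = name, item_ids = item_ids,
         min_code = min_code, max_code = max_code,
         score_range = c(min_code * length(item_ids),
                         max_code * length(item_ids))),
    class = "scale_definition")
}

#' @rdname scale_definition
#' @export
gses_scale <- function() {
  scale_definition("GSES", paste0("s", 1:10), 1L, 4L)
}

#' @rdname scale_definition
#' @export
phq9_scale <- function() {
  scale_definition("PHQ9", paste0("d", 1:9), 0L, 3L)
}

#' Construct a validated item-response matrix
#'
#' @param values integer matrix or data frame, participants in rows, items in
#'   columns named by `item_ids` of the schema scales.
#' @param scales list of [scale_definition()] objects covering every item
#'   column.
#' @param covariates optional data frame of per-participant covariates
#'   (e.g. age, gender, education), same row count.
#' @return An `item_response_matrix`: list with `values` (integer matrix),
#'   `item_ids`, `range` (2 x p matrix of min/max codes) and `covariates`.
#' @export
item_response_matrix <- function(values, scales, covariates = NULL) {
  values <- as.matrix(values)
  item_ids <- unlist(lapply(scales, `[[`, "item_ids"))
  if (anyDuplicated(item_ids))
    pkg_stop("schema_error", "duplicate item ids across scales")
  missing_cols <- setdiff(item_ids, colnames(values))
  if (length(missing_cols))
    pkg_stop("schema_error", "missing item columns: ",
             paste(missing_cols, collapse = ", "))
  values <- values[, item_ids, drop = FALSE]
  storage.mode(values) <- "integer"
  rng <- do.call(cbind, lapply(scales, function(s)
    matrix(c(s$min_code, s$max_code), 2, length(s$item_ids))))
  colnames(rng) <- item_ids
  bad <- rep(FALSE, nrow(values))
  for (j in seq_along(item_ids)) {
    v <- values[, j]
    bad <- bad | is.na(v) | v < rng[1, j] | v > rng[2, j]
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(bad))
  }
  out <- structure(
    list(values = values[!bad, , drop = FALSE],
         item_ids = item_ids,
         range = rng,
         covariates = if (is.null(covariates)) NULL else
           covariates[!bad, , drop = FALSE],
         n_dropped = sum(bad)),
    class = "item_response_matrix")
  if (nrow(out$values) == 0)
    pkg_stop("empty_data_error", "no rows survive validation")
  out
}

#' Read a wide-format item-response table from delimited text
#'
#' Expects a header row naming every item column of the supplied scales;
#' covariate columns (any column not belonging to a scale) are carried along.
#' Rows with a missing or out-of-range item response are dropped (complete
#' case filtering) and counted in `n_dropped`.
#'
#' @param path path to a CSV or TSV file (delimiter auto-detected from the
#'   header line unless `sep` is given).
#' @param scales list of [scale_definition()] objects.
#' @param sep optional field delimiter override.
#' @return An `item_response_matrix`.
#' @export
read_item_table <- function(path, scales, sep = NULL) {
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- read.csv(path, sep = sep, check.names = FALSE)
  item_ids <- unlist(lapply(scales, `[[`, "item_ids"))
  missing_cols <- setdiff(item_ids, names(df))
  if (length(missing_cols))
    pkg_stop("schema_error", "missing required columns: ",
             paste(missing_cols, collapse = ", "))
  cov_cols <- setdiff(names(df), item_ids)
  item_response_matrix(df[item_ids], scales,
                       covariates = if (length(cov_cols)) df[cov_cols])
}

#' Write an item-response matrix (plus covariates) back to CSV
#'
#' @param data an `item_response_matrix`.
#' @param path output path.
#' @export
write_item_table <- function(data, path) {
  df <- as.data.frame(data$values)
  if (!is.null(data$covariates)) df <- cbind(df, data$covariates)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Score a scale as the arithmetic sum of its item codes
#'
#' @param data an `item_response_matrix`.
#' @param scale a [scale_definition()]; all its items must be present.
#' @return Integer vector of per-participant totals, guaranteed to lie in the
#'   scale's `score_range`.
#' @export
score_scale <- function(data, scale) {
  missing_cols <- setdiff(scale$item_ids, data$item_ids)
  if (length(missing_cols))
    pkg_stop("schema_error", "scale items absent from matrix: ",
             paste(missing_cols, collapse = ", "))
  as.integer(rowSums(data$values[, scale$item_ids, drop = FALSE]))
}

#' Classify participants into depressed and control groups by PHQ-9 total
#'
#' Totals at or above the cutoff denote clinically significant depressive
#' symptoms; severity bands partition the depressed group into moderate
#' (10--14), moderate-severe (15--19) and severe (>= 20) at the default
#' cutoff of 10. Below-cutoff participants (including mild scorers) are
#' controls.
#'
#' @param totals integer vector of PHQ-9 totals (0--27).
#' @param cutoff classification cutoff, default 10.
#' @return Data frame with columns `group` (factor control/depressed) and
#'   `severity` (factor control/moderate/moderate-severe/severe).
#' @export
classify_depression <- function(totals, cutoff = 10L) {
  if (cutoff < 0 || cutoff > 27)
    pkg_stop("parameter_error", "cutoff must lie in [0, 27]")
  stopifnot(all(totals >= 0 & totals <= 27))
  group <- factor(ifelse(totals >= cutoff, "depressed", "control"),
                  levels = c("control", "depressed"))
  severity <- rep("control", length(totals))
  severity[totals >= cutoff & totals <= 14] <- "moderate"
  severity[totals >= pmax(cutoff, 15) & totals <= 19] <- "moderate-severe"
  severity[totals >= pmax(cutoff, 20)] <- "severe"
  data.frame(group = group,
             severity = factor(severity,
                               levels = c("control", "moderate",
                                          "moderate-severe", "severe")))
}

#' Score a sample on both instruments and attach group labels
#'
#' @param data an `item_response_matrix` containing both GSES and PHQ-9 items.
#' @param cutoff PHQ-9 group cutoff.
#' @return Data frame with `phq9_total`, `gses_total`, `group`, `severity`
#'   and any covariates.
#' @export
score_sample <- function(data, cutoff = 10L) {
  phq <- score_scale(data, phq9_scale())
  gses <- score_scale(data, gses_scale())
  cls <- classify_depression(phq, cutoff)
  out <- data.frame(phq9_total = phq, gses_total = gses,
                    group = cls$group, severity = cls$severity)
  if (!is.null(data$covariates)) out <- cbind(out, data$covariates)
  out
}

#' Cronbach's alpha for a set of items
#'
#' @param values numeric matrix, participants in rows, items in columns.
#' @return Alpha coefficient (k/(k-1)) * (1 - sum item variances / total
#'   variance).
#' @export
cronbach_alpha <- function(values) {
  k <- ncol(values)
  stopifnot(k >= 2)
  vi <- apply(values, 2, stats::var)
  vt <- stats::var(rowSums(values))
  (k / (k - 1)) * (1 - sum(vi) / vt)
}
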