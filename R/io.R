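#' Expression matrix container
#'
#' Holds a genes x samples matrix of log2(FPKM+1) values together with a
#' per-sample group label (`tumor` or `normal`). Gene and sample identifiers
#' live in the dimnames and must be unique; values must be finite and
#' nonnegative (the log2(FPKM+1) scale is bounded below by zero).
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param group character vector of length `ncol(values)` with entries in
#'   `c("tumor", "normal")`.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `group`.
#' @export
expr_matrix <- function(values, group) {
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("`values` must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stopf("duplicated gene ids: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stopf("duplicated sample ids: %s",
          paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values)))
    stopf("expression values must be finite")
  if (any(values < 0))
    stopf("expression values must be >= 0 (log2(FPKM+1) scale)")
  group <- as.character(group)
  if (length(group) != ncol(values) || !all(group %in% c("tumor", "normal")))
    stopf("`group` must be one of 'tumor'/'normal' per sample")
  both <- length(unique(group)) == 2L
  if (both && any(table(group) < 2L))
    stopf("at least 2 samples per group are required when both groups are present")
  structure(list(values = values, group = group), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples (%d tumor, %d normal)\n",
              nrow(x$values), ncol(x$values),
              sum(x$group == "tumor"), sum(x$group == "normal")))
  invisible(x)
}

gene_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

#' Subset an expression matrix to tumor samples
#' @param x an `expr_matrix`.
#' @return numeric matrix of the tumor columns.
#' @export
tumor_values <- function(x) x$values[, x$group == "tumor", drop = FALSE]

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample ids and a first column of gene ids.
#' Duplicate gene rows are collapsed by their arithmetic mean on the log2
#' scale (deterministic and order-independent); duplicate sample ids and
#' non-numeric cells are errors.
#'
#' @param path file path to a TSV.
#' @param group_label `"tumor"` or `"normal"`, applied to every sample.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, group_label = c("tumor", "normal")) {
  group_label <- match.arg(group_label)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", sep = "\t")
  if (ncol(raw) < 2L) stopf("expression file needs a gene-id column plus >=1 sample")
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples))
    stopf("duplicate sample id in header: %s",
          paste(unique(samples[duplicated(samples)]), collapse = ", "))
  genes <- raw[[1L]]
  vals <- matrix(NA_real_, nrow(raw), length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(raw[[j + 1L]]))
    bad <- which(is.na(v))
    if (length(bad))
      stopf("non-numeric value '%s' at gene '%s', sample '%s'",
            raw[[j + 1L]][bad[1L]], genes[bad[1L]], samples[j])
    vals[, j] <- v
  }
  # collapse duplicated gene rows by mean
  if (anyDuplicated(genes)) {
    vals <- rowsum(vals, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    rownames(vals) <- unique(genes)
  } else {
    rownames(vals) <- genes
  }
  expr_matrix(vals, rep(group_label, length(samples)))
}

#' Merge two cohorts on their shared genes
#'
#' Joins two expression matrices (e.g. a tumor and a normal cohort from
#' different sources) by intersecting gene ids and concatenating samples,
#' preserving each cohort's group labels.
#'
#' @param a,b `expr_matrix` objects with disjoint sample ids.
#' @return An [expr_matrix()] over the common genes.
#' @export
merge_cohorts <- function(a, b) {
  stopifnot(inherits(a, "expr_matrix"), inherits(b, "expr_matrix"))
  overlap <- intersect(sample_ids(a), sample_ids(b))
  if (length(overlap))
    stopf("sample ids present in both cohorts: %s",
          paste(utils::head(overlap, 5L), collapse = ", "))
  genes <- intersect(gene_ids(a), gene_ids(b))
  if (!length(genes)) stopf("no genes shared between the two cohorts")
  expr_matrix(cbind(a$values[genes, , drop = FALSE],
                    b$values[genes, , drop = FALSE]),
              c(a$group, b$group))
}

#' Read a clinical / survival table
#'
#' Requires columns `sample_id`, `time` (nonnegative), `event` (0/1);
#' optional clinical covariates `age`, `grade`, `stage` may contain `NA`.
#'
#' @param path TSV file path.
#' @return A `data.frame` with one row per sample.
#' @export
read_clinical <- function(path) {
  d <- utils::read.delim(path, header = TRUE, check.names = FALSE, sep = "\t")
  validate_survival(d)
}

#' Validate a survival table
#'
#' @param d data.frame with `sample_id`, `time`, `event` and optional
#'   `age`, `grade`, `stage` columns.
#' @return the validated data.frame (invisibly the same object).
#' @export
validate_survival <- function(d) {
  for (col in c("sample_id", "time", "event"))
    if (!col %in% names(d)) stopf("clinical table is missing column '%s'", col)
  if (anyDuplicated(d$sample_id))
    stopf("duplicated sample_id in clinical table")
  if (any(!is.finite(d$time)) || any(d$time < 0))
    stopf("`time` must be finite and >= 0")
  if (!all(d$event %in% c(0, 1)))
    stopf("`event` must be 0 or 1; offending values: %s",
          paste(unique(d$event[!d$event %in% c(0, 1)]), collapse = ", "))
  d$sample_id <- as.character(d$sample_id)
  d
}

#' Read a gene annotation table
#'
#' Two mandatory columns: `gene_id` and `biotype` (one of `lncRNA`,
#' `protein_coding`, `other`); optional logical/0-1 column `is_immune`
#' marking the immune-gene list among the protein-coding entries.
#'
#' @param path TSV file path.
#' @return data.frame with columns `gene_id`, `biotype`, `is_immune`.
#' @export
read_annotation <- function(path) {
  d <- utils::read.delim(path, header = TRUE, check.names = FALSE, sep = "\t")
  for (col in c("gene_id", "biotype"))
    if (!col %in% names(d)) stopf("annotation table is missing column '%s'", col)
  if (anyDuplicated(d$gene_id)) stopf("duplicated gene_id in annotation")
  if (!all(d$biotype %in% c("lncRNA", "protein_coding", "other")))
    stopf("biotype must be lncRNA / protein_coding / other")
  d$is_immune <- if ("is_immune" %in% names(d)) as.logical(d$is_immune) else FALSE
  d$is_immune[is.na(d$is_immune)] <- FALSE
  d
}

#' Write a result table as TSV
#'
#' Single serialization point for all stage outputs: tab-delimited, no
#' quoting, floats written with 9 significant digits so that a write/read
#' round trip is stable at the declared precision.
#'
#' @param d data.frame to serialize.
#' @param path output file path.
#' @export
write_table <- function(d, path) {
  out <- d
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.9g", out[[j]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a table written by [write_table()]
#' @param path TSV file path.
#' @return data.frame with numeric columns restored.
#' @export
read_table <- function(path) {
  utils::read.delim(path, header = TRUE, check.names = FALSE, sep = "\t")
}

#' Pipeline configuration
#'
#' Bundles the screening and modeling thresholds with their defaults:
#' coexpression correlation > 0.4 at p < 0.001, differential-expression
#' FDR < 0.01, univariate Cox p < 0.01, pair minority frequency > 0.20,
#' ten-fold cross-validation, and ROC horizons of 1/2/3 years.
#'
#' @param corr_min minimum lncRNA-immune gene correlation.
#' @param corr_p_max maximum correlation-test p-value.
#' @param de_fdr_max maximum BH-adjusted p for differential expression.
#' @param unicox_p_max maximum univariate Cox Wald p.
#' @param pair_minority_min minimum minority-indicator frequency for a pair.
#' @param cv_folds number of cross-validation folds for the lasso.
#' @param roc_horizons ROC evaluation horizons, in years.
#' @param time_unit unit of the clinical `time` column; days are converted
#'   to years internally (365.25 d/y).
#' @param rng_seed integer seed controlling fold assignment.
#' @return a list of class `pair_config`.
#' @export
pair_config <- function(corr_min = 0.4, corr_p_max = 0.001, de_fdr_max = 0.01,
                        unicox_p_max = 0.01, pair_minority_min = 0.20,
                        cv_folds = 10L, roc_horizons = c(1, 2, 3),
                        time_unit = c("years", "days"), rng_seed = 1L) {
  time_unit <- match.arg(time_unit)
  for (v in c(corr_min, corr_p_max, de_fdr_max, unicox_p_max, pair_minority_min))
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stopf("all thresholds must lie in (0, 1)")
  if (cv_folds < 2L) stopf("cv_folds must be >= 2")
  structure(list(corr_min = corr_min, corr_p_max = corr_p_max,
                 de_fdr_max = de_fdr_max, unicox_p_max = unicox_p_max,
                 pair_minority_min = pair_minority_min,
                 cv_folds = as.integer(cv_folds), roc_horizons = roc_horizons,
                 time_unit = time_unit, rng_seed = as.integer(rng_seed)),
            class = "pair_config")
}

#' Published seven-pair ovarian-cancer signature
#'
#' Returns the coefficient table of a published immune-related lncRNA
#' seven-pair prognostic model for ovarian cancer (per-pair multivariate Cox
#' coefficient, hazard ratio, 95% CI bounds, Wald p). Useful as a worked
#' reference model: its columns satisfy the Cox arithmetic identities
#' `HR = exp(Coef)` and `HR = sqrt(HR.95L * HR.95H)` and feed directly into
#' [risk_score()].
#'
#' @return data.frame with columns `pair_id`, `coef`, `hr`, `hr_ci_low`,
#'   `hr_ci_high`, `p`.
#' @export
published_pair_model <- function() {
  path <- system.file("extdata", "ovarian_pair_model.tsv", package = "pairRisk",
                      mustWork = TRUE)
  utils::read.delim(path, header = TRUE, sep = "\t")
}
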