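#' Identify immune-related lncRNAs by coexpression
#'
#' A lncRNA is called immune-related if it is correlated with at least one
#' immune gene above `corr_min` with a correlation-test p below `corr_p_max`.
#' Correlation is Pearson on the log2 values, computed across tumor samples
#' by default (the model targets tumor biology); the threshold is applied to
#' the signed coefficient unless `use_absolute = TRUE`.
#'
#' Constant lncRNAs (zero variance) have no defined correlation and are
#' excluded with a warning.
#'
#' @param expr an [expr_matrix()] containing both lncRNA and immune-gene rows.
#' @param annotation gene annotation as from [read_annotation()].
#' @param corr_min minimum correlation (default 0.4).
#' @param corr_p_max maximum correlation-test p-value (default 0.001).
#' @param use_absolute apply the threshold to |rho| instead of signed rho.
#' @param samples `"tumor"` (default) or `"all"`: which samples the
#'   correlation is computed on.
#' @return list with `ids` (retained lncRNA ids) and `hits` (data.frame of
#'   lncrna_id, immune_gene_id, rho, p for every passing combination).
#' @export
immune_coexpression <- function(expr, annotation, corr_min = 0.4,
                                corr_p_max = 0.001, use_absolute = FALSE,
                                samples = c("tumor", "all")) {
  samples <- match.arg(samples)
  x <- if (samples == "tumor") tumor_values(expr) else expr$values
  if (ncol(x) < 3L) stopf("need >= 3 samples for a correlation screen")
  lnc <- intersect(annotation$gene_id[annotation$biotype == "lncRNA"], rownames(x))
  imm <- intersect(
    annotation$gene_id[annotation$biotype == "protein_coding" & annotation$is_immune],
    rownames(x))
  if (!length(imm)) stopf("no immune genes present in the expression matrix")
  if (!length(lnc)) stopf("no lncRNA rows present in the expression matrix")

  sds <- apply(x[lnc, , drop = FALSE], 1L, stats::sd)
  if (any(sds == 0)) {
    warnf("%d constant lncRNA(s) excluded from the coexpression screen: %s",
          sum(sds == 0), paste(utils::head(lnc[sds == 0], 5L), collapse = ", "))
    lnc <- lnc[sds > 0]
    if (!length(lnc)) return(list(ids = character(0),
                                  hits = coexpression_hits_empty()))
  }
  imm_sd <- apply(x[imm, , drop = FALSE], 1L, stats::sd)
  imm <- imm[imm_sd > 0]
  if (!length(imm)) stopf("all immune genes are constant; correlation undefined")

  n <- ncol(x)
  r <- stats::cor(t(x[lnc, , drop = FALSE]), t(x[imm, , drop = FALSE]))
  r <- pmin(pmax(r, -1), 1)
  # two-sided t-test p for Pearson correlation
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  p[abs(r) == 1] <- 0
  stat <- if (use_absolute) abs(r) else r
  pass <- stat > corr_min & p < corr_p_max
  idx <- which(pass, arr.ind = TRUE)
  hits <- data.frame(lncrna_id = lnc[idx[, 1L]],
                     immune_gene_id = imm[idx[, 2L]],
                     rho = r[pass], p = p[pass],
                     stringsAsFactors = FALSE)
  hits <- hits[order(hits$lncrna_id, hits$immune_gene_id), , drop = FALSE]
  rownames(hits) <- NULL
  list(ids = intersect(lnc, unique(hits$lncrna_id)), hits = hits)
}

coexpression_hits_empty <- function() {
  data.frame(lncrna_id = character(0), immune_gene_id = character(0),
             rho = numeric(0), p = numeric(0))
}

#' Tumor-vs-normal differential expression by rank-sum test
#'
#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test per candidate gene,
#' exact when both groups have at most 12 samples and the data are tie-free,
#' otherwise the normal approximation with tie and continuity correction.
#' `log2fc` is the tumor-minus-normal mean difference on the log2 scale and
#' fixes the direction label; p-values are Benjamini-Hochberg adjusted
#' within the candidate set.
#'
#' @param expr an [expr_matrix()] with both groups present (>= 2 samples each).
#' @param candidates gene ids to test (default: all rows).
#' @param de_fdr_max FDR threshold defining the `significant` column.
#' @return data.frame with columns `gene_id`, `log2fc`, `p`, `fdr`,
#'   `direction`, `significant`, ordered as the candidates.
#' @export
differential_expression <- function(expr, candidates = NULL, de_fdr_max = 0.01) {
  g <- expr$group
  nt <- sum(g == "tumor"); nn <- sum(g == "normal")
  if (nt < 2L || nn < 2L)
    stopf("both groups need >= 2 samples (tumor %d, normal %d)", nt, nn)
  candidates <- candidates %||% gene_ids(expr)
  missing <- setdiff(candidates, gene_ids(expr))
  if (length(missing))
    stopf("candidate gene(s) absent from the matrix: %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  xt <- expr$values[candidates, g == "tumor", drop = FALSE]
  xn <- expr$values[candidates, g == "normal", drop = FALSE]

  p <- vapply(seq_along(candidates), function(i) {
    a <- xt[i, ]; b <- xn[i, ]
    exact <- nt <= 12L && nn <= 12L && !anyDuplicated(c(a, b))
    suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value)
  }, numeric(1))
  log2fc <- rowMeans(xt) - rowMeans(xn)
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(gene_id = candidates, log2fc = log2fc, p = p, fdr = fdr,
             direction = ifelse(log2fc > 0, "up", "down"),
             significant = fdr < de_fdr_max,
             row.names = NULL, stringsAsFactors = FALSE)
}
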