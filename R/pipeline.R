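#' Run the full pair-signature pipeline
#'
#' Chains every stage: immune coexpression screen, tumor-vs-normal
#' differential expression, pair-indicator construction on tumor samples,
#' minority filter, univariate Cox screen, cross-validated lasso Cox
#' selection, multivariate refit, exponential risk scoring, 1-year ROC with
#' Youden cut-point, stratification, Kaplan-Meier curves with log-rank test,
#' multi-horizon ROC and the clinical/immune association battery.
#'
#' @param expr an [expr_matrix()] with tumor and normal samples.
#' @param annotation gene annotation data.frame.
#' @param clinical survival data.frame (`sample_id`, `time`, `event`, plus
#'   optional `age`, `grade`, `stage`); times in `config$time_unit`.
#' @param config a [pair_config()].
#' @param infiltration optional cell-type x sample fraction matrix.
#' @param checkpoint optional checkpoint-gene x sample expression matrix.
#' @return list with every stage's output (see the vignette for a walk
#'   through the components).
#' @export
run_pair_pipeline <- function(expr, annotation, clinical,
                              config = pair_config(),
                              infiltration = NULL, checkpoint = NULL) {
  clinical <- validate_survival(clinical)
  if (config$time_unit == "days") clinical$time <- clinical$time / 365.25

  coexpr <- immune_coexpression(expr, annotation,
                                corr_min = config$corr_min,
                                corr_p_max = config$corr_p_max)
  if (!length(coexpr$ids)) stopf("no immune-related lncRNAs found")
  de <- differential_expression(expr, candidates = coexpr$ids,
                                de_fdr_max = config$de_fdr_max)
  de_ids <- de$gene_id[de$significant]
  if (length(de_ids) < 2L)
    stopf("fewer than 2 differentially expressed immune-related lncRNAs")

  pm <- filter_pairs(build_pairs(expr, genes = de_ids),
                     pair_minority_min = config$pair_minority_min)
  if (nrow(pm$indicators) < 2L) stopf("fewer than 2 pairs survive the filter")

  uni <- unicox_screen(pm, clinical, unicox_p_max = config$unicox_p_max)
  if (nrow(uni) < 2L) stopf("fewer than 2 pairs pass the univariate Cox screen")
  pm_uni <- pm
  keep <- match(uni$term, pair_ids(pm))
  pm_uni$indicators <- pm$indicators[keep, , drop = FALSE]
  pm_uni$gene1 <- pm$gene1[keep]; pm_uni$gene2 <- pm$gene2[keep]
  pm_uni$minority_frac <- pm$minority_frac[keep]

  sel <- lasso_cox_select(pm_uni, clinical, cv_folds = config$cv_folds,
                          rng_seed = config$rng_seed,
                          auc_horizon = config$roc_horizons[1L])
  model <- multicox_refit(sel$pairs, pm_uni, clinical)
  scores <- risk_score(model, pm_uni)

  roc1 <- time_dependent_roc(scores, clinical, horizon = config$roc_horizons[1L])
  cutoff <- youden_cutoff(roc1)
  strat <- stratify(scores, cutoff)
  lr <- logrank_test(clinical, strat$assignments)
  km <- lapply(split(clinical,
                     strat$assignments[clinical$sample_id]), km_estimate)
  rocs <- multi_horizon_roc(scores, clinical, horizons = config$roc_horizons)
  cli_roc <- covariate_roc_comparison(clinical, scores,
                                      horizon = config$roc_horizons[1L])

  clin_assoc <- NULL
  cvs <- intersect(c("age", "grade", "stage"), names(clinical))
  if (length(cvs)) {
    chi <- do.call(rbind, lapply(cvs, function(v)
      tryCatch(chisq_group_vs_clinical(strat, clinical, v),
               error = function(e) NULL)))
    wil <- do.call(rbind, lapply(cvs, function(v)
      tryCatch(riskscore_by_stratum(scores, clinical, v),
               error = function(e) NULL)))
    indep <- tryCatch(cox_independence(scores, clinical, covariates = cvs),
                      error = function(e) NULL)
    clin_assoc <- list(chisq = chi, wilcoxon = wil, cox = indep)
  }
  imm <- NULL
  if (!is.null(infiltration))
    imm <- immune_correlation(scores, infiltration)
  chk <- NULL
  if (!is.null(checkpoint))
    chk <- group_difference_tests(checkpoint, strat)

  list(coexpression = coexpr, de = de, de_ids = de_ids,
       pairs = pm, unicox = uni, selection = sel, model = model,
       scores = scores, roc1 = roc1, cutoff = cutoff,
       stratification = strat, logrank = lr, km = km, rocs = rocs,
       clinical_roc = cli_roc, clinical_assoc = clin_assoc,
       immune = imm, checkpoint = chk)
}
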