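#' Significance stars
#'
#' Conventional star coding: `***` for p < 0.001, `**` for p < 0.01,
#' `*` for p < 0.05, empty otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star labels.
#' @export
signif_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

assoc_row <- function(variable, test, statistic, p, effect = NA_real_) {
  data.frame(variable = variable, test = test, statistic = statistic,
             p = p, effect = effect, stars = signif_stars(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

# categorize a clinical variable; age dichotomized at `age_cut`
# (cohort median by default)
clinical_factor <- function(surv, variable, age_cut = NULL) {
  v <- surv[[variable]]
  if (is.null(v)) stopf("clinical table has no column '%s'", variable)
  if (variable == "age") {
    cut <- age_cut %||% stats::median(v, na.rm = TRUE)
    factor(ifelse(v > cut, sprintf(">%g", cut), sprintf("<=%g", cut)))
  } else factor(v)
}

#' Chi-square association of risk group with a clinical variable
#'
#' Pearson chi-square (no Yates correction) on the risk-group x category
#' contingency table; when any expected count falls below 5 the test falls
#' back to Fisher's exact test (noted in the `test` field).
#'
#' @param strat a `risk_strata` object.
#' @param surv clinical data.frame.
#' @param variable clinical column name; `age` is dichotomized at `age_cut`.
#' @param age_cut threshold for the age split (default: cohort median).
#' @return one-row association data.frame.
#' @export
chisq_group_vs_clinical <- function(strat, surv, variable, age_cut = NULL) {
  surv <- validate_survival(surv)
  grp <- strat$assignments[surv$sample_id]
  v <- clinical_factor(surv, variable, age_cut)
  ok <- !is.na(grp) & !is.na(v)
  tab <- table(group = grp[ok], value = droplevels(v[ok]))
  if (any(dim(tab) < 2L)) stopf("'%s' has a single observed level", variable)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 5)) {
    message(sprintf("expected count < 5 for '%s'; using Fisher's exact test", variable))
    ft <- stats::fisher.test(tab)
    assoc_row(variable, "fisher_exact", NA_real_, ft$p.value)
  } else {
    assoc_row(variable, "chi_square", unname(ct$statistic), ct$p.value)
  }
}

#' Compare risk scores across clinical strata
#'
#' Two-level variables: two-sided unpaired Wilcoxon rank-sum test of the
#' scores. Variables with more than two levels use Kruskal-Wallis, or
#' pairwise rank-sum tests when `pairwise = TRUE`.
#'
#' @param scores risk scores (data.frame or named vector).
#' @param surv clinical data.frame.
#' @param variable clinical column; `age` dichotomized at `age_cut`.
#' @param age_cut age split threshold (default cohort median).
#' @param pairwise emit one rank-sum row per level pair for multi-level
#'   variables instead of a single Kruskal-Wallis row.
#' @return association data.frame (effect = difference of stratum medians
#'   for two-group comparisons).
#' @export
riskscore_by_stratum <- function(scores, surv, variable, age_cut = NULL,
                                 pairwise = FALSE) {
  surv <- validate_survival(surv)
  sc <- as_score_vector(scores, surv$sample_id)
  v <- clinical_factor(surv, variable, age_cut)
  ok <- !is.na(v)
  sc <- sc[ok]; v <- droplevels(v[ok])
  counts <- table(v)
  if (any(counts == 0L) || nlevels(v) < 2L)
    stopf("stratum '%s' of '%s' is empty",
          names(counts)[which(counts == 0L)[1]] %||% "(single level)", variable)
  if (nlevels(v) == 2L || pairwise) {
    lev <- levels(v)
    combs <- utils::combn(lev, 2L, simplify = FALSE)
    out <- lapply(combs, function(pr) {
      a <- sc[v == pr[1]]; b <- sc[v == pr[2]]
      exact <- length(a) <= 12L && length(b) <= 12L && !anyDuplicated(c(a, b))
      wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact))
      assoc_row(sprintf("%s: %s vs %s", variable, pr[1], pr[2]),
                "wilcoxon", unname(wt$statistic), wt$p.value,
                effect = stats::median(a) - stats::median(b))
    })
    do.call(rbind, out)
  } else {
    kt <- stats::kruskal.test(sc, v)
    assoc_row(variable, "kruskal_wallis", unname(kt$statistic), kt$p.value)
  }
}

#' Cox independence of the risk score from clinical covariates
#'
#' Enters the risk score (as log(score) = the model's linear predictor by
#' default, since the score is an exponential) into univariate and
#' multivariate Cox models alongside the clinical covariates, reporting
#' per-term HR, 95% CI and Wald p for both analyses.
#'
#' @param scores risk scores.
#' @param surv clinical data.frame with the covariate columns.
#' @param covariates covariate names, default age/grade/stage (used as
#'   numeric/ordinal codes).
#' @param use_log model log(score) rather than the raw score.
#' @return data.frame of Cox rows with a `model` column (`uni`/`multi`).
#' @export
cox_independence <- function(scores, surv, covariates = c("age", "grade", "stage"),
                             use_log = TRUE) {
  surv <- validate_survival(surv)
  sc <- as_score_vector(scores, surv$sample_id)
  risk <- if (use_log) log(sc) else sc
  covs <- list(risk_score = risk)
  for (cv in covariates)
    if (cv %in% names(surv)) covs[[cv]] <- as.numeric(surv[[cv]])
  keep_var <- vapply(covs, function(v) stats::var(v, na.rm = TRUE) > 0, logical(1))
  covs <- covs[keep_var]
  X <- do.call(cbind, covs)
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]
  y <- survival::Surv(surv$time[ok], surv$event[ok])

  uni <- do.call(rbind, lapply(colnames(X), function(nm) {
    fit <- survival::coxph(y ~ X[, nm], ties = "breslow")
    r <- cox_result_row(nm, unname(fit$coefficients), sqrt(fit$var[1, 1]))
    cbind(model = "uni", r)
  }))
  if (ncol(X) > 1L) {
    qx <- qr(scale(X, scale = FALSE))
    if (qx$rank < ncol(X)) {
      bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
      stopf("collinear covariate(s): %s", paste(bad, collapse = ", "))
    }
  }
  fit <- survival::coxph(y ~ X, ties = "breslow")
  multi <- cbind(model = "multi",
                 cox_result_row(colnames(X), unname(fit$coefficients),
                                sqrt(diag(fit$var))))
  rbind(uni, multi)
}

#' Spearman correlation of risk score with immune infiltration
#'
#' One Spearman correlation (with asymptotic p) per cell type; constant
#' fractions or a constant score have no defined rank correlation and are
#' flagged and excluded from the significance calls.
#'
#' @param scores risk scores.
#' @param infiltration cell-type x sample numeric matrix of fractions.
#' @param p_max significance threshold for the `significant` flag (0.05).
#' @return data.frame with `cell_type`, `rho`, `p`, `stars`, `significant`,
#'   `flag`.
#' @export
immune_correlation <- function(scores, infiltration, p_max = 0.05) {
  sc <- as_score_vector(scores, colnames(infiltration))
  out <- lapply(rownames(infiltration), function(ct) {
    f <- infiltration[ct, ]
    if (stats::sd(f) == 0 || stats::sd(sc) == 0) {
      data.frame(cell_type = ct, rho = NA_real_, p = NA_real_, stars = "",
                 significant = FALSE, flag = "constant_input",
                 stringsAsFactors = FALSE)
    } else {
      ctst <- suppressWarnings(stats::cor.test(sc, f, method = "spearman",
                                               exact = FALSE))
      data.frame(cell_type = ct, rho = unname(ctst$estimate), p = ctst$p.value,
                 stars = signif_stars(ctst$p.value),
                 significant = ctst$p.value < p_max, flag = "",
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' High- vs low-risk group differences for a value table
#'
#' Per-row unpaired rank-sum test of a values matrix (immune-cell fractions
#' or checkpoint-gene expression) between the high- and low-risk groups.
#' Direction is the sign of (median high - median low); a BH-adjusted column
#' accompanies the per-test stars.
#'
#' @param values features x samples numeric matrix.
#' @param strat a `risk_strata`.
#' @return data.frame with `feature`, `statistic`, `p`, `fdr`, `direction`,
#'   `stars`, `flag` (rows with near-degenerate data are flagged
#'   `low_information`).
#' @export
group_difference_tests <- function(values, strat) {
  grp <- strat$assignments[colnames(values)]
  if (anyNA(grp)) stopf("stratification missing for some samples")
  hi <- grp == "high"; lo <- grp == "low"
  if (!any(hi) || !any(lo)) stopf("both risk groups must be non-empty")
  rows <- lapply(rownames(values), function(f) {
    a <- values[f, hi]; b <- values[f, lo]
    exact <- length(a) <= 12L && length(b) <= 12L && !anyDuplicated(c(a, b))
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact))
    dmed <- stats::median(a) - stats::median(b)
    nz <- sum(c(a, b) != 0)
    data.frame(feature = f, statistic = unname(wt$statistic), p = wt$p.value,
               direction = if (dmed < 0) "lower_in_high"
                           else if (dmed > 0) "higher_in_high" else "none",
               flag = if (nz <= 1L) "low_information" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$stars <- signif_stars(out$p)
  out[, c("feature", "statistic", "p", "fdr", "direction", "stars", "flag")]
}
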