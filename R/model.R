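#' Univariate Cox screen over pair indicators
#'
#' Fits one single-covariate Cox proportional-hazards model per pair
#' (partial likelihood, Breslow tie handling — indicator covariates are
#' heavily tied) and retains pairs with two-sided Wald p below
#' `unicox_p_max`. Confidence intervals are `coef +/- 1.959964 * se` on the
#' log scale. Constant or non-converging pairs are dropped with a warning.
#'
#' @param pm a `pair_matrix` (typically after [filter_pairs()]).
#' @param surv survival data.frame with `sample_id`, `time`, `event`.
#' @param unicox_p_max retention threshold on the Wald p, default 0.01.
#' @param ties tie method passed to [survival::coxph()], default `"breslow"`.
#' @return data.frame (one row per retained pair) with `term`, `coef`, `se`,
#'   `hr`, `hr_ci_low`, `hr_ci_high`, `p`; attribute `n_tested` records how
#'   many pairs entered the screen.
#' @export
unicox_screen <- function(pm, surv, unicox_p_max = 0.01, ties = "breslow") {
  al <- align_surv(pm, surv)
  if (sum(al$surv$event) < 2L) stopf("need >= 2 events for a Cox screen")
  ind <- al$ind
  y <- survival::Surv(al$surv$time, al$surv$event)
  rows <- lapply(rownames(ind), function(id) {
    x <- ind[id, ]
    if (stats::var(x) == 0) {
      warnf("pair '%s' is constant across samples; dropped", id)
      return(NULL)
    }
    fit <- tryCatch(
      survival::coxph(y ~ x, ties = ties,
                      control = survival::coxph.control(iter.max = 100)),
      warning = function(w) NULL, error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$coefficients) ||
        !is.finite(sqrt(fit$var[1, 1]))) {
      warnf("pair '%s' did not converge; dropped", id)
      return(NULL)
    }
    cox_result_row(id, unname(fit$coefficients), sqrt(fit$var[1, 1]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- cox_result_row(character(0), numeric(0), numeric(0))
  res <- out[out$p < unicox_p_max, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_tested") <- nrow(ind)
  attr(res, "all") <- out
  res
}

cox_result_row <- function(term, coef, se) {
  data.frame(term = term, coef = coef, se = se,
             hr = exp(coef),
             hr_ci_low = exp(coef - Z975 * se),
             hr_ci_high = exp(coef + Z975 * se),
             p = 2 * stats::pnorm(-abs(coef / se)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# inner join of pair matrix samples and survival rows, in matrix order
align_surv <- function(pm, surv) {
  surv <- validate_survival(surv)
  ids <- intersect(colnames(pm$indicators), surv$sample_id)
  dropped <- ncol(pm$indicators) - length(ids)
  if (dropped > 0L)
    message(sprintf("%d sample(s) without clinical rows dropped", dropped))
  if (!length(ids)) stopf("no samples shared between pair matrix and survival table")
  list(ind = pm$indicators[, ids, drop = FALSE],
       surv = surv[match(ids, surv$sample_id), , drop = FALSE])
}

#' Lasso Cox selection with cross-validated path
#'
#' Runs an L1-penalized Cox regression over a log-spaced lambda path with
#' `cv_folds`-fold cross-validated partial-likelihood deviance (folds
#' stratified by event status and fixed by `rng_seed`). Every distinct
#' nonempty active set along the path is a candidate model; the returned
#' candidate is the one whose 1-year time-dependent AUC is maximal, ties
#' resolved toward the sparser model.
#'
#' @param pm a `pair_matrix` restricted to the uniCox-retained pairs.
#' @param surv survival data.frame.
#' @param cv_folds number of folds, default 10.
#' @param rng_seed integer seed fixing the fold assignment.
#' @param auc_horizon horizon (same unit as `surv$time`) for the AUC
#'   arbiter, default 1 year.
#' @return list of class `pair_model` with `pairs`, `coefs` (penalized, at
#'   the chosen lambda), `lambda_path`, `chosen_lambda`, `auc`, `cv` (the
#'   `cv.glmnet` object).
#' @export
lasso_cox_select <- function(pm, surv, cv_folds = 10L, rng_seed = 1L,
                             auc_horizon = 1) {
  al <- align_surv(pm, surv)
  if (nrow(al$ind) < 2L) stopf("need >= 2 pairs for lasso selection")
  x <- t(al$ind)
  y <- survival::Surv(al$surv$time, al$surv$event)
  foldid <- with_seed(rng_seed, stratified_folds(al$surv$event, cv_folds))
  fit <- glmnet::glmnet(x, y, family = "cox")
  cv <- with_seed(rng_seed + 1L,
                  glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                                    type.measure = "deviance"))
  beta <- as.matrix(fit$beta)
  active <- apply(beta != 0, 2L, which, simplify = FALSE)
  sizes <- lengths(active)
  if (all(sizes == 0L)) stopf("lasso path is empty at every lambda")
  # one candidate per distinct nonempty active set (largest lambda attaining it)
  keys <- vapply(active, function(i) paste(i, collapse = ","), character(1))
  cand <- which(!duplicated(keys) & sizes > 0L)
  aucs <- vapply(cand, function(j) {
    lp <- drop(x %*% beta[, j])
    sc <- data.frame(sample_id = al$surv$sample_id, score = exp(lp))
    tryCatch(time_dependent_roc(sc, al$surv, horizon = auc_horizon)$auc,
             error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(aucs))) stopf("time-dependent AUC undefined for every candidate")
  best <- cand[which.max(aucs)]   # which.max takes the first (sparser) on ties
  sel <- active[[best]]
  structure(list(pairs = colnames(x)[sel],
                 coefs = beta[sel, best],
                 lambda_path = fit$lambda,
                 chosen_lambda = fit$lambda[best],
                 auc = max(aucs, na.rm = TRUE),
                 cv = cv),
            class = "pair_model")
}

# fold labels balanced within event strata
stratified_folds <- function(event, k) {
  foldid <- integer(length(event))
  for (e in unique(event)) {
    i <- which(event == e)
    foldid[i] <- sample(rep_len(seq_len(k), length(i)))
  }
  foldid
}

#' Multivariate Cox refit of the selected pairs
#'
#' Refits the selected pairs jointly in an unpenalized Cox model; the refit
#' coefficients (with per-term Wald tests and 95% CIs, which penalized fits
#' lack) are the final model. Collinear or duplicated indicator rows are an
#' error naming the offending pairs.
#'
#' @param pairs character vector of pair ids to refit.
#' @param pm the `pair_matrix` containing them.
#' @param surv survival data.frame.
#' @param ties tie method for [survival::coxph()], default `"breslow"`.
#' @return `pair_model` with `pairs`, `coefs` (refit values) and
#'   `fit_details` (a data.frame with coef/hr/CI/p per pair).
#' @export
multicox_refit <- function(pairs, pm, surv, ties = "breslow") {
  missing <- setdiff(pairs, pair_ids(pm))
  if (length(missing))
    stopf("pair(s) absent from the matrix: %s", paste(missing, collapse = ", "))
  al <- align_surv(pm, surv)
  x <- t(al$ind[pairs, , drop = FALSE])
  qx <- qr(cbind(x))
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    stopf("collinear pair indicator(s): %s", paste(bad, collapse = ", "))
  }
  y <- survival::Surv(al$surv$time, al$surv$event)
  fit <- survival::coxph(y ~ x, ties = ties,
                         control = survival::coxph.control(iter.max = 100))
  coefs <- unname(fit$coefficients)
  se <- sqrt(diag(fit$var))
  details <- cox_result_row(pairs, coefs, se)
  structure(list(pairs = pairs, coefs = stats::setNames(coefs, pairs),
                 fit_details = details, fit = fit),
            class = "pair_model")
}

#' @export
print.pair_model <- function(x, ...) {
  cat(sprintf("<pair_model> %d pairs\n", length(x$pairs)))
  if (!is.null(x$fit_details)) print(x$fit_details)
  else print(data.frame(pair = x$pairs, coef = unname(x$coefs)))
  invisible(x)
}

#' Exponential pair risk score
#'
#' Scores each sample as `exp(sum_i coef_i * indicator_i)`: the exponential
#' of the Cox linear predictor over the model's pair indicators. A sample
#' with all indicators 0 therefore scores exactly 1.
#'
#' @param model a `pair_model` (its `coefs` are used).
#' @param pm a `pair_matrix` containing every model pair.
#' @return data.frame with `sample_id` and `score` (> 0).
#' @export
risk_score <- function(model, pm) {
  stopifnot(inherits(model, "pair_model"))
  missing <- setdiff(model$pairs, pair_ids(pm))
  if (length(missing))
    stopf("pair(s) missing from indicator matrix: %s", paste(missing, collapse = ", "))
  ind <- pm$indicators[model$pairs, , drop = FALSE]
  lp <- drop(crossprod(ind, unname(model$coefs)))
  data.frame(sample_id = colnames(ind), score = exp(lp),
             row.names = NULL, stringsAsFactors = FALSE)
}
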