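#' Kaplan-Meier product-limit estimate
#'
#' @param surv survival data.frame (`sample_id`, `time`, `event`).
#' @return data.frame with one row per observed time: `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`.
#' @export
km_estimate <- function(surv) {
  surv <- validate_survival(surv)
  if (!nrow(surv)) stopf("empty survival table")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = surv)
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             n_censor = sf$n.censor, survival = sf$surv)
}

# step-function evaluation of a KM curve at time t (S(0) = 1)
km_at <- function(km, t) {
  i <- which(km$time <= t)
  if (!length(i)) 1 else km$survival[max(i)]
}

# product-limit survival at time t from times sorted ascending; tied event
# times aggregated as (1 - d_u / n_u)
km_surv_at <- function(time_sorted, event, t) {
  ev_t <- time_sorted[event == 1 & time_sorted <= t]
  if (!length(ev_t)) return(1)
  r <- rle(ev_t)
  first <- match(r$values, time_sorted)
  n_risk <- length(time_sorted) - first + 1L
  prod(1 - r$lengths / n_risk)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square (1 df for two groups) with hypergeometric
#' variance, via [survival::survdiff()].
#'
#' @param surv survival data.frame.
#' @param assignments per-sample group labels: named character vector
#'   (names = sample ids) or a vector aligned with `surv` rows.
#' @return list with `chi2` and `p`.
#' @export
logrank_test <- function(surv, assignments) {
  surv <- validate_survival(surv)
  g <- if (!is.null(names(assignments))) {
    unname(assignments[surv$sample_id])
  } else assignments
  if (length(g) != nrow(surv) || anyNA(g))
    stopf("assignments must cover every survival row")
  if (length(unique(g)) < 2L) stopf("need two groups for a log-rank test")
  sd <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ g)
  df <- length(sd$n) - 1L
  list(chi2 = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Time-dependent ROC with Kaplan-Meier weighting
#'
#' Cumulative/dynamic ROC at a fixed horizon t: cases are subjects with an
#' event by t, controls those surviving past t. Under censoring both error
#' rates are estimated from KM curves: with `S` the overall survival and
#' `S_{>c}` / `S_{<=c}` the KM curves inside each score stratum,
#' \deqn{Sens(c) = (1 - S_{>c}(t)) P(score > c) / (1 - S(t))}
#' \deqn{Spec(c) = S_{<=c}(t) P(score <= c) / S(t).}
#' With no censoring before t this reduces exactly to the empirical ROC of
#' the binary outcome "event by t". The KM estimates can make the raw
#' sens/spec non-monotone in c; both are monotonized (cumulative maxima)
#' and clamped to [0, 1] before the trapezoidal AUC.
#'
#' @param scores data.frame (`sample_id`, `score`) or named numeric vector.
#' @param surv survival data.frame.
#' @param horizon evaluation time, same unit as `surv$time`.
#' @return list of class `time_roc`: `horizon`, `cutpoints` (sorted unique
#'   scores with -Inf/+Inf sentinels), `sens`, `spec`, `auc`.
#' @export
time_dependent_roc <- function(scores, surv, horizon) {
  surv <- validate_survival(surv)
  sc <- as_score_vector(scores, surv$sample_id)
  # pre-sort by time so the per-cutpoint KM evaluation is a linear pass
  o <- order(surv$time)
  tm <- surv$time[o]; ev <- surv$event[o]; sc <- sc[o]
  St <- km_surv_at(tm, ev, horizon)
  if (St >= 1) stopf("no events observed before the horizon")
  if (St <= 0) stopf("no subjects at risk beyond the horizon")

  cuts <- c(-Inf, sort(unique(sc)))
  sens <- numeric(length(cuts)); spec <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    c0 <- cuts[i]
    hi <- sc > c0
    p_hi <- mean(hi)
    S_hi <- if (any(hi)) km_surv_at(tm[hi], ev[hi], horizon) else 1
    S_lo <- if (any(!hi)) km_surv_at(tm[!hi], ev[!hi], horizon) else 1
    sens[i] <- (1 - S_hi) * p_hi / (1 - St)
    spec[i] <- S_lo * (1 - p_hi) / St
  }
  sens <- pmin(pmax(sens, 0), 1)
  spec <- pmin(pmax(spec, 0), 1)
  # enforce sens non-increasing, spec non-decreasing in the cutpoint
  sens <- rev(cummax(rev(sens)))
  spec <- cummax(spec)
  x <- 1 - spec; y <- sens
  ord <- order(x, y)
  auc <- sum(diff(x[ord]) * (utils::head(y[ord], -1) + utils::tail(y[ord], -1)) / 2)
  structure(list(horizon = horizon, cutpoints = cuts, sens = sens, spec = spec,
                 auc = auc),
            class = "time_roc")
}

as_score_vector <- function(scores, sample_ids) {
  if (is.data.frame(scores)) {
    sc <- stats::setNames(scores$score, scores$sample_id)[sample_ids]
  } else if (!is.null(names(scores))) {
    sc <- scores[sample_ids]
  } else {
    if (length(scores) != length(sample_ids))
      stopf("unnamed score vector must match the survival table length")
    sc <- scores
  }
  if (anyNA(sc)) stopf("missing risk score for some samples")
  unname(sc)
}

#' @export
print.time_roc <- function(x, ...) {
  cat(sprintf("<time_roc> horizon %g, AUC %.4f (%d cutpoints)\n",
              x$horizon, x$auc, length(x$cutpoints)))
  invisible(x)
}

#' Youden-index optimal cut-point
#'
#' Returns the cutpoint maximizing sensitivity + specificity; ties are
#' broken toward the smaller cutoff.
#'
#' @param roc a `time_roc`.
#' @return the optimal cutoff (a score value).
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "time_roc"))
  j <- roc$sens + roc$spec
  roc$cutpoints[which.max(j)]   # which.max returns the first (smallest cut) on ties
}

#' Stratify samples by a risk-score cutoff
#'
#' High risk iff score strictly exceeds the cutoff; a score equal to the
#' cutoff goes to the low group.
#'
#' @param scores data.frame (`sample_id`, `score`) or named numeric vector.
#' @param cutoff the threshold.
#' @return list of class `risk_strata`: `cutoff`, `assignments` (named
#'   character vector, `"high"`/`"low"`), `n_high`, `n_low`.
#' @export
stratify <- function(scores, cutoff) {
  if (is.data.frame(scores)) scores <- stats::setNames(scores$score, scores$sample_id)
  a <- ifelse(scores > cutoff, "high", "low")
  structure(list(cutoff = cutoff, assignments = a,
                 n_high = sum(a == "high"), n_low = sum(a == "low")),
            class = "risk_strata")
}

#' @export
print.risk_strata <- function(x, ...) {
  cat(sprintf("<risk_strata> cutoff %g: %d high / %d low\n",
              x$cutoff, x$n_high, x$n_low))
  invisible(x)
}

#' Time-dependent ROC at several horizons
#'
#' @param scores risk scores as in [time_dependent_roc()].
#' @param surv survival data.frame.
#' @param horizons numeric vector of horizons (default 1/2/3 years).
#' @return named list of `time_roc` objects.
#' @export
multi_horizon_roc <- function(scores, surv, horizons = c(1, 2, 3)) {
  stats::setNames(lapply(horizons, function(h) time_dependent_roc(scores, surv, h)),
                  paste0("t", horizons))
}

#' Compare the risk score's AUC with clinical covariates
#'
#' Evaluates each covariate (ordinal covariates used directly as scores) by
#' the same time-dependent ROC machinery, at one horizon. Samples missing a
#' covariate are dropped for that covariate only.
#'
#' @param surv survival data.frame containing the covariate columns.
#' @param scores risk scores.
#' @param covariates covariate column names, default age/grade/stage.
#' @param horizon ROC horizon, default 1 year.
#' @return data.frame with `covariate`, `auc`, `n`.
#' @export
covariate_roc_comparison <- function(surv, scores,
                                     covariates = c("age", "grade", "stage"),
                                     horizon = 1) {
  surv <- validate_survival(surv)
  sc <- as_score_vector(scores, surv$sample_id)
  rows <- list(data.frame(covariate = "risk_score",
                          auc = time_dependent_roc(sc, surv, horizon)$auc,
                          n = nrow(surv)))
  for (cv in covariates) {
    if (!cv %in% names(surv)) next
    v <- as.numeric(surv[[cv]])
    ok <- !is.na(v)
    rows[[length(rows) + 1L]] <- data.frame(
      covariate = cv,
      auc = time_dependent_roc(v[ok], surv[ok, , drop = FALSE], horizon)$auc,
      n = sum(ok))
  }
  do.call(rbind, rows)
}
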