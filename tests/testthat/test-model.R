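mk_pm <- function(ind) {
  if (is.null(colnames(ind))) colnames(ind) <- sprintf("s%03d", seq_len(ncol(ind)))
  structure(list(indicators = ind,
                 gene1 = sub("\\|.*", "", rownames(ind)),
                 gene2 = sub(".*\\|", "", rownames(ind)),
                 minority_frac = pmin(rowMeans(ind), 1 - rowMeans(ind))),
            class = "pair_matrix")
}

surv_for <- function(ind, time, event) {
  data.frame(sample_id = colnames(ind), time = time, event = event,
             stringsAsFactors = FALSE)
}

test_that("univariate Cox agrees with brute-force partial-likelihood maximization", {
  # four-subject instance with a finite maximizer, against the grid oracle
  ind <- matrix(c(1L, 0L, 1L, 0L), nrow = 1,
                dimnames = list("A|B", sprintf("s%d", 1:4)))
  surv <- surv_for(ind, time = c(1, 2, 3, 4), event = rep(1L, 4))
  res <- unicox_screen(mk_pm(ind), surv, unicox_p_max = 1)
  expect_equal(res$coef,
               oracle_unicox_coef(surv$time, surv$event, ind[1, ]),
               tolerance = 1e-3)

  # random instances with censoring and ties
  set.seed(23)
  for (i in 1:4) {
    x <- rbinom(30, 1, 0.45)
    sv <- random_surv(30, censor = 0.25, ties = (i %% 2 == 0))
    indi <- matrix(as.integer(x), nrow = 1,
                   dimnames = list("P|Q", sv$sample_id))
    r <- unicox_screen(mk_pm(indi), sv, unicox_p_max = 1)
    expect_equal(r$coef, oracle_unicox_coef(sv$time, sv$event, x),
                 tolerance = 2e-3)
    # Wald arithmetic identities
    expect_equal(r$hr, exp(r$coef))
    expect_equal(r$p, 2 * pnorm(-abs(r$coef / r$se)))
    expect_equal(r$se, (log(r$hr_ci_high) - log(r$hr_ci_low)) / (2 * 1.959964),
                 tolerance = 1e-9)
  }
})

test_that("degenerate pairs are dropped and eventless data rejected", {
  ind <- rbind("A|B" = rep(1L, 10), "C|D" = rep(c(0L, 1L), 5))
  colnames(ind) <- sprintf("s%03d", 1:10)
  sv <- random_surv(10, censor = 0.2, seed = 2)
  expect_warning(res <- unicox_screen(mk_pm(ind), sv, unicox_p_max = 1),
                 "constant")
  expect_equal(res$term, "C|D")

  sv0 <- sv; sv0$event <- 0L
  expect_error(unicox_screen(mk_pm(ind), sv0, unicox_p_max = 1), ">= 2 events")
})

test_that("null pair indicators are retained at about the nominal 1% rate", {
  set.seed(91)
  n <- 200; n_pairs <- 500
  ind <- matrix(rbinom(n_pairs * n, 1, 0.5), nrow = n_pairs,
                dimnames = list(sprintf("N%03d|M%03d", 1:n_pairs, 1:n_pairs),
                                sprintf("s%03d", 1:n)))
  sv <- surv_for(ind, time = rexp(n, 0.2), event = rbinom(n, 1, 0.75))
  res <- suppressWarnings(unicox_screen(mk_pm(ind), sv, unicox_p_max = 0.01))
  rate <- nrow(res) / attr(res, "n_tested")
  expect_lt(rate, 0.03)
})

test_that("lasso path candidates behave at the penalty limits", {
  s <- sim_scenario(n_tumor = 250, n_normal = 0, n_lncrna = 10,
                    n_immune_gene = 4, n_de_up = 10, n_de_down = 0,
                    n_causal_pairs = 3, causal_betas = c(1.2, -1.2, 1.2),
                    censor_rate = 0.2, rng_seed = 55)
  sim <- simulate_expression(s)
  sv <- simulate_survival(sim$expr, s)
  pm <- filter_pairs(build_pairs(sim$expr,
                                 genes = attr(sim$expr, "sim_info")$de_up))
  sel <- lasso_cox_select(pm, sv, cv_folds = 10, rng_seed = 9)
  expect_true(all(sel$pairs %in% rownames(pm$indicators)))
  expect_true(all(sel$coefs != 0))
  expect_true(is.finite(sel$auc) && sel$auc > 0.5)
  expect_true(sel$chosen_lambda %in% sel$lambda_path)
  # the penalty path starts empty (full shrinkage) and grows as lambda drops
  beta <- as.matrix(sel$cv$glmnet.fit$beta)
  expect_equal(sum(beta[, 1] != 0), 0L)
  expect_gt(sum(beta[, ncol(beta)] != 0), sum(beta[, 2] != 0))
  # active-set size is non-increasing in lambda at the path endpoints
  sizes <- colSums(beta != 0)
  expect_lte(sizes[1], sizes[length(sizes)])
})

test_that("multivariate refit reduces to uniCox for one pair and flags collinearity", {
  set.seed(12)
  ind <- matrix(rbinom(80, 1, 0.5), nrow = 2,
                dimnames = list(c("A|B", "C|D"), sprintf("s%03d", 1:40)))
  sv <- random_surv(40, censor = 0.2, seed = 13)
  pm <- mk_pm(ind)
  uni <- unicox_screen(pm, sv, unicox_p_max = 1)
  refit <- multicox_refit("A|B", pm, sv)
  expect_equal(unname(refit$coefs), uni$coef[uni$term == "A|B"], tolerance = 1e-7)

  dup <- mk_pm(rbind(ind, "E|F" = ind["A|B", ]))
  expect_error(multicox_refit(c("A|B", "C|D", "E|F"), dup, sv),
               "collinear.*E\\|F")
  expect_error(multicox_refit("X|Y", pm, sv), "absent")
})

test_that("two independent planted pair effects are recovered by the refit", {
  # beta = (1, -1), n_tumor = 600: average refit error within +/- 0.2
  reps <- 40
  est <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    s <- sim_scenario(n_tumor = 600, n_normal = 0, n_lncrna = 4,
                      n_immune_gene = 2, n_de_up = 4, n_de_down = 0,
                      n_causal_pairs = 2, causal_betas = c(1, -1),
                      censor_rate = 0.25, rng_seed = 7000 + r)
    sim <- simulate_expression(s)
    sv <- simulate_survival(sim$expr, s)
    causal <- attr(sv, "causal")
    pm <- build_pairs(sim$expr, genes = attr(sim$expr, "sim_info")$de_up)
    fit <- multicox_refit(causal$pair_id, pm, sv)
    est[r, ] <- unname(fit$coefs[causal$pair_id])
  }
  expect_lt(abs(mean(est[, 1]) - 1), 0.2)
  expect_lt(abs(mean(est[, 2]) + 1), 0.2)
})

test_that("risk scores are the exponential of the indicator linear predictor", {
  ind <- rbind("A|B" = c(0L, 1L, 1L), "C|D" = c(0L, 0L, 1L))
  colnames(ind) <- c("s1", "s2", "s3")
  pm <- mk_pm(ind)
  model <- structure(list(pairs = c("A|B", "C|D"),
                          coefs = c("A|B" = 0.5, "C|D" = -1.2)),
                     class = "pair_model")
  sc <- risk_score(model, pm)
  expect_equal(sc$score, c(1, exp(0.5), exp(0.5 - 1.2)))
  expect_true(all(sc$score > 0))
  # monotone: raising an indicator with positive coefficient raises the score
  ind2 <- ind; ind2["A|B", "s1"] <- 1L
  sc2 <- risk_score(model, mk_pm(ind2))
  expect_gt(sc2$score[1], sc$score[1])
  expect_error(risk_score(structure(list(pairs = "Z|W", coefs = c("Z|W" = 1)),
                                    class = "pair_model"), pm),
               "missing")
})
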