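mk_strat <- function(labels, ids = sprintf("s%03d", seq_along(labels))) {
  structure(list(cutoff = 0, assignments = setNames(labels, ids),
                 n_high = sum(labels == "high"), n_low = sum(labels == "low")),
            class = "risk_strata")
}

mk_clin <- function(n, ...) {
  data.frame(sample_id = sprintf("s%03d", seq_len(n)),
             time = seq_len(n), event = rep(1L, n), ...,
             stringsAsFactors = FALSE)
}

test_that("chi-square association matches hand computation and falls back to Fisher", {
  # diagonal 10/10 table: Pearson statistic is exactly 20 without correction
  strat <- mk_strat(rep(c("high", "low"), each = 10))
  clin <- mk_clin(20, grade = rep(c(1, 2), each = 10))
  res <- chisq_group_vs_clinical(strat, clin, "grade")
  expect_equal(res$test, "chi_square")
  expect_equal(res$statistic, 20)
  expect_lt(res$p, 0.001)
  expect_equal(res$stars, "***")

  # identical distributions across risk groups
  clin2 <- mk_clin(20, grade = rep(c(1, 2), each = 10))
  res2 <- chisq_group_vs_clinical(mk_strat(rep(c("high", "low"), 10)),
                                  clin2, "grade")
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p, 1)

  # small expected counts: exact p equals the hypergeometric enumeration
  strat3 <- mk_strat(rep(c("high", "low"), c(4, 4)))
  clin3 <- mk_clin(8, grade = c(1, 1, 1, 2, 1, 2, 2, 2))
  expect_message(res3 <- chisq_group_vs_clinical(strat3, clin3, "grade"),
                 "Fisher")
  expect_equal(res3$test, "fisher_exact")
  tab <- matrix(c(3, 1, 1, 3), 2, byrow = TRUE)
  expect_equal(res3$p, oracle_fisher_p(tab), tolerance = 1e-10)
})

test_that("risk-score stratum comparisons use the exact rank-sum distribution", {
  clin <- mk_clin(6, grade = rep(c(1, 2), each = 3))
  sc <- setNames(c(4, 5, 6, 1, 2, 3), clin$sample_id)
  res <- riskscore_by_stratum(sc, clin, "grade")
  expect_equal(res$p, 0.1)
  expect_equal(res$p, oracle_ranksum_p(c(4, 5, 6), c(1, 2, 3)))
  expect_equal(res$effect, 3)

  # identical multisets across strata
  sc2 <- setNames(c(1, 2, 3, 3, 2, 1), clin$sample_id)
  expect_equal(riskscore_by_stratum(sc2, clin, "grade")$p, 1)

  clin_empty <- mk_clin(6, grade = c(1, 1, 1, 1, NA, NA))
  expect_error(riskscore_by_stratum(sc, clin_empty, "grade"), "empty|single level")

  # multi-level: one Kruskal-Wallis row, or all pairwise rows on request
  clin3 <- mk_clin(9, stage = rep(1:3, each = 3))
  sc3 <- setNames(rnorm(9), clin3$sample_id)
  expect_equal(riskscore_by_stratum(sc3, clin3, "stage")$test, "kruskal_wallis")
  expect_equal(nrow(riskscore_by_stratum(sc3, clin3, "stage", pairwise = TRUE)), 3L)
})

test_that("Cox independence keeps the risk effect alongside clinical covariates", {
  # constant covariates are dropped: multivariate equals univariate for risk
  set.seed(61)
  n <- 120
  lp <- rnorm(n)
  clin <- mk_clin(n, age = rep(60, n), grade = rep(2, n))
  clin$time <- rexp(n, 0.2 * exp(lp)); clin$event <- rbinom(n, 1, 0.8)
  sc <- setNames(exp(lp), clin$sample_id)
  res <- cox_independence(sc, clin)
  uni <- res[res$model == "uni" & res$term == "risk_score", ]
  multi <- res[res$model == "multi" & res$term == "risk_score", ]
  expect_equal(multi$coef, uni$coef, tolerance = 1e-9)

  # perfectly collinear covariates are refused by name
  clin2 <- mk_clin(n, age = round(runif(n, 40, 80)))
  clin2$grade <- clin2$age / 20
  clin2$time <- clin$time; clin2$event <- clin$event
  expect_error(cox_independence(sc, clin2, covariates = c("age", "grade")),
               "collinear")

  # planted risk effect with independent covariates stays significant
  hits <- 0L
  for (r in 1:10) {
    set.seed(700 + r)
    lp <- rnorm(400, sd = 0.8)
    clin3 <- mk_clin(400, age = round(runif(400, 40, 80)),
                     grade = sample(1:3, 400, TRUE),
                     stage = sample(1:4, 400, TRUE))
    clin3$time <- rexp(400, 0.2 * exp(lp))
    clin3$event <- rbinom(400, 1, 0.75)
    res3 <- cox_independence(setNames(exp(lp), clin3$sample_id), clin3)
    pm <- res3$p[res3$model == "multi" & res3$term == "risk_score"]
    hits <- hits + (pm < 0.001)
  }
  expect_gte(hits, 9L)
})

test_that("Spearman immune correlation handles monotone, null and constant inputs", {
  set.seed(8)
  n <- 374
  sc <- setNames(exp(rnorm(n)), sprintf("s%03d", 1:n))
  infil <- rbind(perfect = rank(sc),
                 noise = rnorm(n),
                 flat = rep(0.1, n))
  colnames(infil) <- names(sc)
  res <- immune_correlation(sc, infil)
  expect_equal(res$rho[res$cell_type == "perfect"], 1)
  expect_true(res$significant[res$cell_type == "perfect"])
  expect_lt(abs(res$rho[res$cell_type == "noise"]), 0.15)
  expect_equal(res$flag[res$cell_type == "flat"], "constant_input")
  expect_false(res$significant[res$cell_type == "flat"])

  # rank invariance under monotone transforms of either variable
  res2 <- immune_correlation(sc^3, infil[1:2, , drop = FALSE])
  expect_equal(res2$rho, res$rho[1:2])
})

test_that("group difference tests recover planted directions and flag degenerate rows", {
  set.seed(15)
  n <- 374
  strat <- mk_strat(rep(c("high", "low"), c(150, 224)), sprintf("s%03d", 1:n))
  hi <- strat$assignments == "high"

  vals <- matrix(rnorm(100 * n, mean = 5), nrow = 100,
                 dimnames = list(sprintf("CHK%03d", 1:100), names(strat$assignments)))
  vals[, hi] <- vals[, hi] - 1   # one log2 unit down in high risk
  res <- group_difference_tests(vals, strat)
  expect_gte(mean(res$direction == "lower_in_high"), 0.95)
  expect_true(all(res$stars == signif_stars(res$p)))
  expect_equal(res$fdr, oracle_bh(res$p))

  # identical groups: same values duplicated -> p = 1, no stars
  m <- matrix(rep(rnorm(20, 5), 2), nrow = 1,
              dimnames = list("G", sprintf("s%03d", 1:40)))
  st <- mk_strat(rep(c("high", "low"), each = 20), sprintf("s%03d", 1:40))
  # make the two groups carry identical multisets
  m[1, 21:40] <- m[1, 1:20]
  r <- group_difference_tests(m, st)
  expect_equal(r$p, 1)
  expect_equal(r$stars, "")

  one <- matrix(c(3, rep(0, 39)), nrow = 1,
                dimnames = list("RARE", sprintf("s%03d", 1:40)))
  r2 <- group_difference_tests(one, st)
  expect_equal(r2$flag, "low_information")
  expect_true(is.finite(r2$p))
})

test_that("star coding is a pure threshold function of p", {
  expect_equal(signif_stars(c(0.0009, 0.009, 0.049, 0.05, 0.5)),
               c("***", "**", "*", "", ""))
})
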