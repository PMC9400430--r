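# pairRisk

Prognostic modeling for tumor cohorts from **relative** expression: pairRisk
builds immune-related lncRNA *pair* signatures, where each feature is a
binary within-sample comparison rather than an expression level. For an
ordered pair of lncRNAs (a, b) and sample s,

    I_ab(s) = 1  if  x_a(s) > x_b(s),   else 0.

Because the indicator only compares two genes inside the same sample, it is
invariant to any per-sample strictly increasing transform of the data —
normalization, log base, platform or batch-specific monotone distortion —
so cohorts can be merged without batch correction and the signature applies
to any sample where the two genes can be ranked. The fitted model is a Cox
proportional-hazards model on a small selected set of indicators, and each
sample's risk is

    score(s) = exp( Σ_i β_i · I_i(s) ),

thresholded at the Youden-optimal point of a Kaplan–Meier-weighted
time-dependent ROC curve. The package is aimed at researchers building or
auditing pair-based prognostic signatures from bulk RNA-seq with survival
follow-up (the motivating setting is ovarian-cancer tumor/normal cohorts),
and ships a seeded synthetic-cohort generator so the entire pipeline runs
and is testable at desk scale, without any data downloads.

## The pipeline

1. **Screen** — lncRNAs coexpressed with immune genes (Pearson r > 0.4,
   p < 0.001, tumor samples), then differentially expressed tumor vs normal
   (rank-sum test, BH FDR < 0.01).
2. **Pair** — all k(k−1)/2 indicator pairs of the DE lncRNAs; keep pairs
   whose minority indicator value occurs in > 20% of samples.
3. **Fit** — univariate Cox screen (p < 0.01) → ten-fold cross-validated
   lasso Cox; among the active sets along the path, the one with the best
   1-year time-dependent AUC → unpenalized multivariate refit (per-pair
   coefficient, HR, 95% CI, Wald p).
4. **Evaluate** — exponential risk score, Youden cut-point, high/low
   stratification, Kaplan–Meier + log-rank, ROC at 1/2/3 years, AUC
   comparison against age/grade/stage.
5. **Associate** — chi-square / rank-sum tests of risk against clinical
   variables, uni/multivariate Cox independence, Spearman correlation with
   immune infiltration, checkpoint-gene group differences.

## Worked example

```r
library(pairRisk)

s <- sim_scenario(n_tumor = 300, n_normal = 80, n_lncrna = 40,
                  n_immune_gene = 20, n_de_up = 12, n_de_down = 2,
                  n_causal_pairs = 4, causal_betas = c(0.9, -0.9, 0.9, -0.9),
                  rng_seed = 11)
sim  <- simulate_expression(s)
surv <- simulate_survival(sim$expr, s)

res <- run_pair_pipeline(sim$expr, sim$annotation, surv,
                         pair_config(rng_seed = 12))

cat(sprintf("DE immune-related lncRNAs: %d\n", length(res$de_ids)))
cat(sprintf("pairs after minority filter: %d\n", nrow(res$pairs$indicators)))
cat(sprintf("pairs past uniCox (p<0.01): %d\n", nrow(res$unicox)))
cat(sprintf("pairs in final model: %d\n", length(res$model$pairs)))
cat(sprintf("1-year AUC: %.3f  cutoff: %.3f\n", res$roc1$auc, res$cutoff))
cat(sprintf("high/low risk: %d/%d, log-rank p = %.2e\n",
            res$stratification$n_high, res$stratification$n_low, res$logrank$p))
truth <- attr(surv, "causal")$pair_id
cat(sprintf("planted causal pairs recovered: %d/%d\n",
            sum(truth %in% res$model$pairs), length(truth)))
```

This prints (numbers from this exact seed):

```
DE immune-related lncRNAs: 14
pairs after minority filter: 52
pairs past uniCox (p<0.01): 11
pairs in final model: 10
1-year AUC: 0.723  cutoff: 1.175
high/low risk: 112/188, log-rank p = 1.11e-26
planted causal pairs recovered: 4/4
```

Reading this: of 40 simulated lncRNAs, 14 pass the immune-coexpression and
differential-expression screen (the scenario planted 14). Their 91 pairs
shrink to 52 after the 20% minority filter, 11 survive the univariate Cox
screen, and the lasso/AUC step keeps 10 — including all 4 pairs whose
indicators actually drive the simulated hazard. The fitted score separates
the cohort into 112 high- and 188 low-risk samples at the Youden cutoff
1.175; a 1-year AUC of 0.723 and a log-rank p of ~1e−26 say the score
discriminates 1-year status well and the two survival curves are far apart.
`res$model$fit_details` holds the per-pair coefficient/HR/CI/p table, and
`published_pair_model()` returns a published seven-pair ovarian-cancer
signature in the same format for comparison or scoring via `risk_score()`.

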