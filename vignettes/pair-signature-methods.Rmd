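---
title: "Rank-based lncRNA pair signatures: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based lncRNA pair signatures: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairRisk)
```

## The model

pairRisk builds prognostic signatures from *relative* expression. For an
ordered pair of lncRNAs $(a, b)$ and a sample $s$, the pair indicator is

$$ I_{ab}(s) = \mathbf{1}\{x_a(s) > x_b(s)\}, $$

i.e. 1 when $a$ is the higher-expressed member within that sample, 0
otherwise (ties fall to 0: the rule keys on one gene being strictly lower).
Because $I_{ab}$ compares two measurements inside the same sample, it is
unchanged by any strictly increasing per-sample transform of the expression
values — library-size scaling, quantile shifts, log bases, batch-specific
monotone distortions. Signatures built on such indicators can therefore be
ported across platforms and merged across cohorts without batch correction;
the suite tests this invariance directly by distorting each sample with a
different random increasing function and asserting bit-identical indicators.

The fitted model is a Cox proportional-hazards model on a small set of
selected indicators, and each sample's risk score is the exponential of its
linear predictor,

$$ \text{score}(s) = \exp\Big(\sum_i \beta_i \, I_i(s)\Big), $$

so a sample with all indicators at 0 scores exactly 1. Samples are split
into high and low risk at the score threshold maximizing the Youden index
(sensitivity + specificity) on a time-dependent ROC curve.

## The pipeline and its thresholds

1. **Immune coexpression screen** — a lncRNA is *immune-related* when its
   Pearson correlation (log2 scale) with at least one immune gene exceeds
   `corr_min = 0.4` at correlation-test p < `corr_p_max = 0.001`.
   The correlation is computed on tumor samples only by default, since the
   survival model only ever sees tumors; `samples = "all"` pools both
   groups. The threshold is applied to the *signed* coefficient by default
   (`use_absolute` flips this): the screen looks for positively coupled
   immune programs, and 0.4 is a conventional moderate-correlation cut.
2. **Differential expression** — per-gene two-sample Wilcoxon rank-sum test
   tumor vs normal, Benjamini–Hochberg adjusted within the immune-related
   candidate set (the screen defines the family), kept at
   `de_fdr_max = 0.01`. The test is exact when both groups have ≤ 12
   samples and the data are tie-free, otherwise the normal approximation
   with tie and continuity corrections. The groups are independent samples,
   so the unpaired rank-sum test is the correct member of the Wilcoxon
   family here; a paired (signed-rank) design is impossible with unequal
   tumor and normal cohorts.
3. **Pairing and the minority filter** — all $k(k-1)/2$ unordered pairs of
   the DE lncRNAs, orientation fixed by input gene order so results are
   deterministic. A pair is retained only when its indicator mean lies
   strictly inside (`pair_minority_min`, 1 − `pair_minority_min`) =
   (0.2, 0.8): a pair whose minority value occurs in ≤ 20% of samples is
   nearly constant and can only stratify a sliver of the cohort. Constant
   pairs carry no ranking information at all and are always dropped. Both
   boundaries are strict and tested at the boundary.
4. **Univariate Cox screen** — one single-covariate Cox fit per pair,
   Breslow tie handling (indicator covariates make ties ubiquitous, and
   Breslow is the cheapest consistent choice; a `ties` argument switches to
   Efron for sensitivity checks). Pairs are kept at Wald p < 0.01.
5. **Lasso Cox selection** — an L1-penalized Cox path with ten-fold
   cross-validated partial-likelihood deviance, folds stratified by event
   status and fixed by `rng_seed`. Every distinct nonempty active set along
   the path is a candidate model; the candidate with the best 1-year
   time-dependent AUC is returned, ties resolved toward the sparser model.
   Using deviance to shape the path and AUC as the final arbiter reflects
   that the signature's end use is discrimination at fixed horizons.
6. **Multivariate refit** — the selected pairs are refit jointly without
   penalty; these coefficients (with per-term Wald p and 95% CIs, which
   penalized estimates lack) are the reported model. Confidence intervals
   use the exact quantile z(0.975) = 1.959964, so the identities
   HR = exp(coef) and HR = √(CI_low × CI_high) hold to numerical precision.
7. **Evaluation** — Kaplan–Meier curves per risk group, the two-group
   log-rank test, ROC at 1/2/3 years, and a covariate comparison entering
   age/grade/stage as ordinal scores at the 1-year horizon.

## Time-dependent ROC

Sensitivity and specificity at horizon $t$ are cumulative/dynamic: cases
are subjects with an event by $t$, controls those surviving past $t$. Under
censoring both are estimated with Kaplan–Meier weighting: with $\hat S$ the
overall KM curve and $\hat S_{>c}$, $\hat S_{\le c}$ the KM curves within
the score strata,

$$ \widehat{\text{Sens}}(c) = \frac{(1-\hat S_{>c}(t))\,\hat P(X>c)}{1-\hat S(t)},
   \qquad
   \widehat{\text{Spec}}(c) = \frac{\hat S_{\le c}(t)\,\hat P(X\le c)}{\hat S(t)}. $$

With zero censoring before $t$ this collapses to the empirical binary ROC,
and the AUC equals the Mann–Whitney statistic — an exact equivalence the
tests assert. The KM estimator is simple and parameter-free, at the cost of
possible non-monotone raw sens/spec sequences; both are clamped to [0, 1]
and monotonized by cumulative maxima before the trapezoidal AUC, the same
convention the stratum-wise KM plots imply. Cutpoints are the observed
unique scores plus a −∞ sentinel. The stratification cutoff is chosen on
the 1-year ROC of the final model (the shortest horizon is the one the
cut-point is used at), and a score exactly at the cutoff goes to the *low*
group — a strict inequality, documented and tested.

Clinical times supplied in days are converted to years at 365.25 d/y.

## Clinical and immune associations

Risk-group versus clinical-category tables use the Pearson chi-square
without Yates correction, falling back to Fisher's exact test when any
expected count drops below 5. Age is dichotomized at the cohort median by
default (`age_cut` overrides; no principled external threshold exists for
a generic cohort). Score-by-stratum comparisons use the unpaired rank-sum
test (Kruskal–Wallis or pairwise tests for multi-level variables).
Independence of the risk score from age/grade/stage is assessed by
univariate and multivariate Cox models; the score enters as log(score) —
the linear predictor itself — because the score is defined as an
exponential and Cox covariates act linearly on the log hazard (`use_log =
FALSE` uses the raw score). Infiltration associations are Spearman
correlations flagged at p < 0.05; checkpoint-gene group differences are
per-gene rank-sum tests with conventional star coding and no cross-gene
correction (stars are reported per test, with a BH-adjusted column emitted
alongside for transparency).

## What the synthetic generator emulates

`sim_scenario()` defaults describe an ovarian-cancer-sized design: 379
tumors against 88 normals, 171 up- and 7 down-regulated lncRNAs, a 1
log2-unit tumor shift, lncRNA–immune correlation blocks at ρ = 0.6, seven
causal pairs with log-hazard coefficients of magnitude 0.6 and alternating
sign (the magnitude range seen in published pair models), a baseline hazard
of 0.15/year and 30% censoring. lncRNA baselines are drawn from U(1, 6)
with unit Gaussian noise, clamped at zero to stay on the log2(FPKM+1)
scale; each DE lncRNA shares a latent factor with one immune gene so their
population correlation is exactly ρ. Consecutive DE lncRNAs are laid out in
same-block couples with matched baselines (jitter U(−0.5, 0.5)) so the
planted causal pairs have balanced, informative indicators.

Survival is exponential given the pair indicators — the simplest member of
the Cox family; the pipeline never uses the baseline hazard, so a constant
baseline loses no generality for testing. The causal signal is planted at
the *pair* level, not the single-gene level, because that is the model
class being fitted. Censoring is uniform on (0, τ) with τ solved
numerically so the expected censored fraction hits `censor_rate`. Age
optionally tracks the latent risk (on by default, emulating the age–risk
association such cohorts show); grade and stage are always independent of
risk, mirroring the null pattern. Infiltration fractions are monotone in
the risk rank plus Gaussian noise — at zero noise the Spearman correlation
with risk is exactly 1 — and checkpoint genes shift by `checkpoint_shift`
log2 units in above-median-risk samples, twelve down and two up.

What the generator does **not** emulate: negative-binomial count noise on
raw reads, batch effects (the pairing transform is batch-free by
construction, which the suite verifies with monotone distortions instead),
gene–gene correlation beyond the planted blocks, informative censoring,
and non-proportional hazards. Passing tests therefore demonstrate that the
estimators and the selection chain recover what they model — not that the
model captures everything in real tumor data.

## Numerical choices and degenerate inputs

- Cox fits: Newton–Raphson via `survival::coxph` with iteration cap 100;
  non-converging or constant pairs are dropped with a warning rather than
  poisoning the screen (a pair whose indicator perfectly separates the
  risk sets has a divergent partial likelihood).
- Duplicate gene rows on input are collapsed by the arithmetic mean on the
  log2 scale — deterministic and order-independent; how duplicated symbols
  should be reconciled across sources is genuinely open, and mean-collapse
  is this package's choice.
- Sample/clinical joins are inner, with a message counting dropped samples.
- Output tables serialize floats with 9 significant digits; a write/read
  round trip is a fixed point at that precision.
- Constant lncRNAs, constant infiltration rows and constant risk vectors
  have undefined correlations; all are excluded or flagged, never silently
  zeroed.
- All Monte-Carlo machinery (fold assignment, generators) runs under local
  seeds that restore the caller's RNG state, so every generator is a pure
  function of (scenario, seed).

## Problem sizes in the test suite

The suite exercises the chain at the sizes its claims are about: oracle
equivalences on instances of n ≤ 60 against brute-force enumerations and
grid searches; correlation-block recovery over 200 replicates of a
200-vs-100 design; null calibrations (log-rank p uniformity, ~1% uniCox
retention at p < 0.01, AUC ≈ 0.5) over 100–200 replicates at n = 400; and
the full uniCox → lasso → multiCox recovery over 50 seeded replicates of a
400-tumor cohort with three causal pairs (β = 1.2) among the ~100 pairs
formed from 16 DE lncRNAs. These sizes were chosen as the smallest designs
at which the corresponding asymptotic claims are expected to hold cleanly.

## Known limitations

- The pairing transform discards magnitude: two cohorts that differ only
  by a within-sample monotone map are indistinguishable by design, so the
  method cannot detect global amplitude shifts that do not reorder genes.
- AUC-maximizing model choice along a lasso path can favor slightly larger
  active sets than deviance-minimizing choice; the multivariate refit
  reports honest per-term uncertainty, but selection inference is not
  corrected (coefficients of selected pairs are mildly biased away from
  zero, visible in the recovery tests' tolerance of ±0.2).
- The KM-weighted ROC assumes censoring independent of the score; under
  score-dependent censoring the nearest-neighbor estimator family would be
  preferable, and is deliberately out of scope here.
- Fisher's fallback for sparse contingency tables changes the test family
  mid-analysis; the `test` field records which was used per variable.
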