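#' Simulation scenario
#'
#' Defines the generative conditions for a synthetic tumor/normal study
#' with the statistical structure the pairing pipeline assumes: a tumor and
#' a normal group, a subset of lncRNAs differentially expressed (mostly up
#' in tumor), lncRNA-immune gene correlation blocks, exponential survival
#' whose hazard depends on a small set of latent pair indicators, and
#' infiltration fractions that rise monotonically with risk.
#'
#' Defaults mirror a TCGA-ovarian-sized design: 379 tumors vs 88 normals,
#' 171 up- and 7 down-regulated lncRNAs, a 1 log2-unit shift, correlation
#' blocks at rho 0.6, seven causal pairs with log-hazard coefficients of
#' alternating sign and magnitude 0.6, a baseline hazard of 0.15/year and
#' 30% censoring.
#'
#' @param n_tumor,n_normal group sizes.
#' @param n_lncrna,n_immune_gene numbers of lncRNA and immune-gene rows.
#' @param n_de_up,n_de_down numbers of up/down differentially expressed
#'   lncRNAs.
#' @param de_effect tumor shift of DE lncRNAs, log2 units.
#' @param corr_block_rho population correlation between a DE lncRNA and its
#'   block's immune gene.
#' @param n_causal_pairs number of pair indicators that drive the hazard.
#' @param causal_betas per-pair log-hazard coefficients (length
#'   `n_causal_pairs`); default alternating +/- 0.6.
#' @param baseline_hazard events per time unit at indicator vector zero.
#' @param censor_rate target fraction of censored tumor samples (uniform
#'   censoring calibrated to hit it in expectation).
#' @param age_risk_link if `TRUE` (default) age increases with the latent
#'   risk; grade and stage are always drawn independent of risk.
#' @param infiltration_noise_sd Gaussian noise on infiltration fractions.
#' @param checkpoint_shift log2 shift applied to checkpoint genes in
#'   high-risk samples.
#' @param rng_seed integer seed; every generator is a pure function of
#'   (scenario, seed).
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_tumor = 379L, n_normal = 88L,
                         n_lncrna = 400L, n_immune_gene = 120L,
                         n_de_up = 171L, n_de_down = 7L,
                         de_effect = 1, corr_block_rho = 0.6,
                         n_causal_pairs = 7L, causal_betas = NULL,
                         baseline_hazard = 0.15, censor_rate = 0.3,
                         age_risk_link = TRUE,
                         infiltration_noise_sd = 0.02,
                         checkpoint_shift = 1,
                         rng_seed = 1L) {
  causal_betas <- causal_betas %||% (rep_len(c(-1, 1), n_causal_pairs) * 0.6)
  s <- structure(as.list(environment()), class = "sim_scenario")
  if (s$n_tumor < 1L || s$n_normal < 0L) stopf("degenerate scenario: no samples")
  if (s$n_de_up + s$n_de_down > s$n_lncrna)
    stopf("n_de_up + n_de_down must not exceed n_lncrna")
  if (length(s$causal_betas) != s$n_causal_pairs)
    stopf("causal_betas must have length n_causal_pairs")
  if (s$corr_block_rho <= 0 || s$corr_block_rho >= 1)
    stopf("corr_block_rho must lie in (0, 1)")
  if (s$censor_rate < 0 || s$censor_rate >= 1)
    stopf("censor_rate must lie in [0, 1)")
  if (s$baseline_hazard <= 0) stopf("baseline_hazard must be positive")
  if (2L * s$n_causal_pairs > s$n_de_up + s$n_de_down)
    stopf("need at least 2 DE lncRNAs per causal pair")
  s
}

#' Simulate tumor/normal expression with planted structure
#'
#' lncRNA log2 values are Gaussian around gene-level baselines drawn from
#' U(1, 6) (sd 1, clamped at 0 to stay on the log2(FPKM+1) scale). DE
#' lncRNAs are shifted by +/- `de_effect` in the tumor group. Each DE
#' lncRNA shares a latent block factor with one immune gene so their
#' population correlation equals `corr_block_rho`; remaining genes are
#' independent. DE lncRNAs are laid out in consecutive same-block couples
#' with matched baselines (jittered by U(-0.5, 0.5)) so the first
#' `n_causal_pairs` couples form informative pair indicators for
#' [simulate_survival()].
#'
#' @param s a [sim_scenario()].
#' @return list with `expr` (an [expr_matrix()] carrying a `sim_info`
#'   attribute), and `annotation` (a gene annotation data.frame).
#' @export
simulate_expression <- function(s) {
  stopifnot(inherits(s, "sim_scenario"))
  with_seed(s$rng_seed, {
    n <- s$n_tumor + s$n_normal
    if (n < 2L) stopf("degenerate scenario: fewer than 2 samples")
    samples <- c(sprintf("T%04d", seq_len(s$n_tumor)),
                 sprintf("N%04d", seq_len(s$n_normal)))
    group <- rep(c("tumor", "normal"), c(s$n_tumor, s$n_normal))
    lnc_ids <- sprintf("LNC%04d", seq_len(s$n_lncrna))
    imm_ids <- sprintf("IMM%04d", seq_len(s$n_immune_gene))

    n_de <- s$n_de_up + s$n_de_down
    de_ids <- lnc_ids[seq_len(n_de)]
    de_dir <- rep(c(1, -1), c(s$n_de_up, s$n_de_down))

    mu_l <- stats::runif(s$n_lncrna, 1, 6)
    # matched baselines for consecutive DE couples -> balanced pair indicators
    if (n_de >= 2L) {
      half <- rep(seq_len(ceiling(n_de / 2)), each = 2L)[seq_len(n_de)]
      base <- stats::runif(max(half), 1.5, 5.5)
      mu_l[seq_len(n_de)] <- base[half] + stats::runif(n_de, -0.5, 0.5)
    }
    mu_i <- stats::runif(s$n_immune_gene, 2, 7)

    rho <- s$corr_block_rho
    n_block <- min(n_de, s$n_immune_gene)
    block_of <- if (n_de) ((seq_len(n_de) - 1L) %% max(n_block, 1L)) + 1L else integer(0)
    fac <- matrix(stats::rnorm(max(n_block, 1L) * n), ncol = n)

    z_l <- matrix(stats::rnorm(s$n_lncrna * n), ncol = n)
    if (n_de)
      z_l[seq_len(n_de), ] <- sqrt(rho) * fac[block_of, , drop = FALSE] +
        sqrt(1 - rho) * z_l[seq_len(n_de), , drop = FALSE]
    x_l <- mu_l + z_l
    if (n_de)
      x_l[seq_len(n_de), group == "tumor"] <-
        x_l[seq_len(n_de), group == "tumor", drop = FALSE] + de_dir * s$de_effect

    z_i <- matrix(stats::rnorm(s$n_immune_gene * n), ncol = n)
    if (n_block)
      z_i[seq_len(n_block), ] <- sqrt(rho) * fac[seq_len(n_block), , drop = FALSE] +
        sqrt(1 - rho) * z_i[seq_len(n_block), , drop = FALSE]
    x_i <- mu_i + z_i

    vals <- pmax(rbind(x_l, x_i), 0)
    dimnames(vals) <- list(c(lnc_ids, imm_ids), samples)
    expr <- expr_matrix(vals, group)

    causal <- NULL
    if (s$n_causal_pairs > 0L) {
      i1 <- 2L * seq_len(s$n_causal_pairs) - 1L
      causal <- data.frame(gene1 = de_ids[i1], gene2 = de_ids[i1 + 1L],
                           beta = s$causal_betas, stringsAsFactors = FALSE)
      causal$pair_id <- paste(causal$gene1, causal$gene2, sep = "|")
    }
    attr(expr, "sim_info") <- list(
      de_up = de_ids[de_dir > 0], de_down = de_ids[de_dir < 0],
      immune_partner = if (n_de) stats::setNames(imm_ids[block_of], de_ids),
      causal = causal)

    annotation <- data.frame(
      gene_id = c(lnc_ids, imm_ids),
      biotype = rep(c("lncRNA", "protein_coding"), c(s$n_lncrna, s$n_immune_gene)),
      is_immune = rep(c(FALSE, TRUE), c(s$n_lncrna, s$n_immune_gene)),
      stringsAsFactors = FALSE)

    list(expr = expr, annotation = annotation)
  })
}

#' Simulate survival driven by latent pair indicators
#'
#' For each tumor sample the causal pair indicators are computed exactly as
#' [build_pairs()] does; the event time is exponential with hazard
#' `baseline_hazard * exp(sum(causal_betas * indicators))`. Censoring is
#' uniform on (0, tau) with tau calibrated so the expected censored
#' fraction equals `censor_rate` (no censoring at rate 0). Age optionally
#' increases with the latent linear predictor; grade and stage are drawn
#' independent of risk.
#'
#' @param expr the expression matrix from [simulate_expression()] (its
#'   `sim_info` attribute supplies the causal pairs), or any `expr_matrix`
#'   if `causal` is given explicitly.
#' @param s the [sim_scenario()].
#' @param causal optional data.frame with `gene1`, `gene2`, `beta`
#'   overriding the planted pairs.
#' @return survival data.frame (`sample_id`, `time`, `event`, `age`,
#'   `grade`, `stage`) for the tumor samples, with attributes `causal` and
#'   `linpred`.
#' @export
simulate_survival <- function(expr, s, causal = NULL) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(s, "sim_scenario"))
  causal <- causal %||% attr(expr, "sim_info")$causal
  x <- tumor_values(expr)
  if (!ncol(x)) stopf("no tumor samples present")
  n <- ncol(x)
  lp <- rep(0, n)
  if (!is.null(causal) && nrow(causal)) {
    ind <- (x[causal$gene1, , drop = FALSE] > x[causal$gene2, , drop = FALSE]) * 1
    lp <- drop(crossprod(ind, causal$beta))
  }
  hazard <- s$baseline_hazard * exp(lp)
  with_seed(s$rng_seed + 1000003L, {
    t_event <- stats::rexp(n, rate = hazard)
    if (s$censor_rate == 0) {
      time <- t_event; event <- rep(1L, n)
    } else {
      # uniform censoring horizon tau solving the expected censored fraction
      cens_frac <- function(tau)
        mean((1 - exp(-hazard * tau)) / (hazard * tau)) - s$censor_rate
      tau <- stats::uniroot(cens_frac, lower = 1e-9, upper = 1e9)$root
      c_time <- stats::runif(n, 0, tau)
      event <- as.integer(t_event <= c_time)
      time <- pmin(t_event, c_time)
    }
    age <- 60 + (if (s$age_risk_link && stats::sd(lp) > 0)
      4 * as.vector(scale(lp)) else 0) + stats::rnorm(n, 0, 8)
    age <- pmin(pmax(round(age), 30), 90)
    grade <- sample(1:3, n, replace = TRUE, prob = c(0.1, 0.3, 0.6))
    stage <- sample(1:4, n, replace = TRUE, prob = c(0.05, 0.10, 0.35, 0.50))
    out <- data.frame(sample_id = colnames(x), time = time, event = event,
                      age = age, grade = grade, stage = stage,
                      row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "causal") <- causal
    attr(out, "linpred") <- stats::setNames(lp, colnames(x))
    out
  })
}

#' Simulate immune infiltration and checkpoint expression given risk
#'
#' Six cell-type fractions are monotone in the risk rank plus Gaussian
#' noise (so at zero noise the Spearman correlation with risk is exactly 1);
#' checkpoint genes are shifted by `checkpoint_shift` log2 units in samples
#' above the risk median — twelve down, two up. A constant risk vector has
#' no rank ordering; fractions are then flat in risk and flagged.
#'
#' @param risk named numeric vector of per-sample risk scores.
#' @param s the [sim_scenario()].
#' @return list with `fractions` (cell type x sample), `checkpoint`
#'   (gene x sample log2 expression), and `constant_risk` flag.
#' @export
simulate_infiltration <- function(risk, s) {
  stopifnot(inherits(s, "sim_scenario"))
  if (is.null(names(risk))) stopf("risk vector must be named by sample id")
  n <- length(risk)
  cells <- c("neutrophil", "endothelial_cell", "macrophage",
             "cancer_associated_fibroblast", "t_cell", "mast_cell")
  chk_dn <- c("CD244", "LAG3", "ICOS", "CTLA4", "CD48", "TNFRSF4", "CD80",
              "TMIGD2", "IDO1", "TNFRSF18", "CD274", "CD40")
  chk_up <- c("CD276", "TNFRSF25")
  constant <- stats::sd(risk) == 0
  u <- if (constant || n == 1L) rep(0, n) else (rank(risk) - 1) / (n - 1)
  with_seed(s$rng_seed + 2000003L, {
    base <- stats::runif(length(cells), 0.02, 0.15)
    fr <- vapply(seq_len(n), function(j)
      base * (1 + 0.8 * u[j]) +
        stats::rnorm(length(cells), 0, s$infiltration_noise_sd),
      numeric(length(cells)))
    fr <- pmax(fr, 0)
    dimnames(fr) <- list(cells, names(risk))

    genes <- c(chk_dn, chk_up)
    dir <- rep(c(-1, 1), c(length(chk_dn), length(chk_up)))
    mu <- stats::runif(length(genes), 2, 6)
    high <- if (constant) rep(FALSE, n) else risk > stats::median(risk)
    chk <- matrix(stats::rnorm(length(genes) * n), nrow = length(genes)) +
      mu + outer(dir * s$checkpoint_shift, as.numeric(high))
    chk <- pmax(chk, 0)
    dimnames(chk) <- list(genes, names(risk))
    if (constant) warnf("risk is constant; infiltration not linked to risk")
    list(fractions = fr, checkpoint = chk, constant_risk = constant)
  })
}
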