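# Independent brute-force oracles. These deliberately share no code with the
# package: each recomputes its quantity from first principles on small inputs.

# product-limit estimator by direct accumulation over unique event times
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    n_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  data.frame(time = ut, survival = out)
}

# two-group log-rank chi-square by per-event-time 2x2 accumulation
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group))
  ut <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (u in ut) {
    at_risk <- time >= u
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1L)
    d <- sum(time == u & event == 1)
    d1 <- sum(time == u & event == 1 & g == 1L)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# exact two-sided rank-sum p by enumerating every assignment of the pooled
# values to the first group (tie-free data)
oracle_ranksum_p <- function(a, b) {
  pool <- c(a, b)
  stopifnot(!anyDuplicated(pool))
  na <- length(a)
  u_obs <- sum(outer(a, b, ">"))
  splits <- utils::combn(length(pool), na)
  u_all <- apply(splits, 2L, function(i)
    sum(outer(pool[i], pool[-i], ">")))
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Benjamini-Hochberg step-up by definition: find the largest k with
# p_(k) <= k/m * q; adjusted values via the cumulative-minimum form
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Breslow log partial likelihood for a single covariate
oracle_logpl <- function(beta, time, event, x) {
  ll <- 0
  for (u in sort(unique(time[event == 1]))) {
    ev <- which(time == u & event == 1)
    risk <- which(time >= u)
    ll <- ll + sum(beta * x[ev]) - length(ev) * log(sum(exp(beta * x[risk])))
  }
  ll
}

# maximize the partial likelihood by grid search with one refinement pass
oracle_unicox_coef <- function(time, event, x) {
  grid <- seq(-10, 10, by = 0.01)
  ll <- vapply(grid, oracle_logpl, numeric(1), time = time, event = event, x = x)
  b0 <- grid[which.max(ll)]
  fine <- seq(b0 - 0.01, b0 + 0.01, by = 1e-4)
  llf <- vapply(fine, oracle_logpl, numeric(1), time = time, event = event, x = x)
  fine[which.max(llf)]
}

# empirical AUC of a score for a binary outcome (ties count half)
oracle_auc <- function(score, case) {
  s1 <- score[case]; s0 <- score[!case]
  mean(outer(s1, s0, ">")) + 0.5 * mean(outer(s1, s0, "=="))
}

# Fisher exact two-sided p for a 2x2 table by hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  sum(probs[probs <= stats::dhyper(tab[1, 1], m, n, k) * (1 + 1e-7)])
}

# small random survival fixture
random_surv <- function(n, censor = 0.3, ties = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  time <- if (ties) sample(1:8, n, replace = TRUE) else rexp(n, 0.3)
  data.frame(sample_id = sprintf("s%03d", seq_len(n)),
             time = time,
             event = as.integer(runif(n) > censor),
             stringsAsFactors = FALSE)
}
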