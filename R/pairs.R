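#' Build the binary lncRNA-pair indicator matrix
#'
#' For every unordered pair (a, b) with a preceding b in the input gene
#' order, the indicator for a sample is 1 when a's expression strictly
#' exceeds b's, and 0 otherwise (ties score 0: the rule keys on "lower
#' than", so equality falls to the 0 branch). Because each indicator only
#' compares two genes within the same sample, the matrix is invariant to
#' any per-sample strictly increasing transform of the expression values —
#' the property that makes pair signatures batch-free.
#'
#' @param expr an [expr_matrix()] or a plain genes x samples numeric matrix.
#' @param genes gene ids to pair (default: all rows); order fixes pair
#'   orientation.
#' @param samples sample ids to use; for an `expr_matrix` the default is its
#'   tumor samples (the survival model only sees tumors).
#' @return An object of class `pair_matrix`: list with `indicators`
#'   (pairs x samples 0/1 matrix, rownames `"a|b"`), `gene1`, `gene2`, and
#'   `minority_frac` (per-pair min(mean, 1 - mean)).
#' @export
build_pairs <- function(expr, genes = NULL, samples = NULL) {
  if (inherits(expr, "expr_matrix")) {
    x <- if (is.null(samples)) tumor_values(expr) else expr$values[, samples, drop = FALSE]
  } else {
    x <- if (is.null(samples)) expr else expr[, samples, drop = FALSE]
  }
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(x))
    if (length(missing))
      stopf("gene(s) not in matrix: %s", paste(utils::head(missing, 5L), collapse = ", "))
    x <- x[genes, , drop = FALSE]
  }
  k <- nrow(x)
  if (k < 2L) stopf("need >= 2 genes to form pairs")
  if (ncol(x) < 1L) stopf("need >= 1 sample")
  idx <- utils::combn(k, 2L)
  ind <- (x[idx[1L, ], , drop = FALSE] > x[idx[2L, ], , drop = FALSE]) * 1L
  g1 <- rownames(x)[idx[1L, ]]
  g2 <- rownames(x)[idx[2L, ]]
  rownames(ind) <- paste(g1, g2, sep = "|")
  m <- rowMeans(ind)
  structure(list(indicators = ind, gene1 = g1, gene2 = g2,
                 minority_frac = pmin(m, 1 - m)),
            class = "pair_matrix")
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("<pair_matrix> %d pairs x %d samples\n",
              nrow(x$indicators), ncol(x$indicators)))
  invisible(x)
}

#' Minority-frequency filter for pair indicators
#'
#' Retains a pair only when its indicator mean lies strictly inside
#' (`pair_minority_min`, 1 - `pair_minority_min`), i.e. the less common
#' indicator value occurs in more than the stated fraction of samples.
#' Constant pairs (all 0 or all 1) carry no ranking information and are
#' always dropped.
#'
#' @param pm a `pair_matrix` from [build_pairs()].
#' @param pair_minority_min minimum minority frequency, default 0.20.
#' @return the filtered `pair_matrix`.
#' @export
filter_pairs <- function(pm, pair_minority_min = 0.20) {
  stopifnot(inherits(pm, "pair_matrix"))
  if (!nrow(pm$indicators)) stopf("empty pair matrix")
  m <- rowMeans(pm$indicators)
  keep <- m > pair_minority_min & m < 1 - pair_minority_min
  structure(list(indicators = pm$indicators[keep, , drop = FALSE],
                 gene1 = pm$gene1[keep], gene2 = pm$gene2[keep],
                 minority_frac = pm$minority_frac[keep]),
            class = "pair_matrix")
}

pair_ids <- function(pm) rownames(pm$indicators)
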