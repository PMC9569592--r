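# Deterministic feature rankings on a training set: Wilcoxon rank-sum with
# Benjamini-Hochberg correction, and ReliefF.

# Two-sided rank-sum p-value: exact for combined n <= 25 without ties,
# normal approximation with tie correction otherwise; fully tied data
# (zero-variance statistic) gives p = 1.
ranksum_p <- function(x, y, exact_threshold = 25L) {
  n <- length(x) + length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  if (ties) {
    ranks <- rank(c(x, y))
    nx <- length(x)
    ny <- length(y)
    w <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
    tie_tab <- table(ranks)
    sigma2 <- nx * ny / 12 * (n + 1 - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- (w - nx * ny / 2) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  } else {
    suppressWarnings(
      wilcox.test(x, y, exact = n <= exact_threshold, correct = FALSE)$p.value
    )
  }
}

#' Rank features by the Wilcoxon rank-sum test
#'
#' Per-feature two-sided rank-sum p-value between the two classes (exact
#' for combined n <= 25 without ties, otherwise normal approximation with
#' tie correction; constant features get p = 1), Benjamini-Hochberg
#' adjusted across features. Features are ranked by ascending adjusted p,
#' ties broken by raw p, then input order.
#'
#' @param x Samples-by-features table or numeric matrix.
#' @param y Binary labels (benign/malignant, 0/1 or logical).
#' @return A `feature_ranking` tibble: `rank`, `feature`, `score` (adjusted
#'   p), `raw_p`, with attribute `method = "wilcoxon"`.
#' @examples
#' m <- cbind(signal = c(1, 2, 3, 7, 8, 9), noise = c(5, 1, 8, 2, 9, 3))
#' wilcoxon_rank(m, c(0, 0, 0, 1, 1, 1))
#' @export
wilcoxon_rank <- function(x, y) {
  m <- as_feature_matrix(x)
  y <- as_label_factor(y)
  if (nlevels(droplevels(y)) < 2) abort("both classes must be present in `y`.")
  if (length(y) != nrow(m)) abort("`y` length must match the sample count.")
  g1 <- y == "malignant"
  raw_p <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (length(unique(col)) <= 1L) return(1)
    ranksum_p(col[g1], col[!g1])
  }, numeric(1))
  adj_p <- p.adjust(raw_p, method = "BH")
  ord <- order(adj_p, raw_p, seq_along(adj_p))
  new_feature_ranking(colnames(m)[ord], adj_p[ord], raw_p[ord], "wilcoxon")
}

#' Rank features by ReliefF weights
#'
#' Standard ReliefF for a binary outcome: for each of `m_iterations`
#' sampled instances, the `k_neighbors` nearest hits and misses (Manhattan
#' distance on min-max-scaled features) pull each feature's weight down by
#' the mean hit difference and up by the mean miss difference, the latter
#' weighted by `P(miss class) / (1 - P(own class))` (equal to 1 for two
#' classes). Feature differences are range-normalized, so weights lie in
#' `[-1, 1]` and constant features score exactly 0. With the default
#' `m_iterations = "all"` every training instance is used once in input
#' order and the ranking is fully deterministic.
#'
#' @inheritParams wilcoxon_rank
#' @param k_neighbors Number of nearest hits/misses (must be at most the
#'   smallest class size minus 1).
#' @param m_iterations `"all"` or a positive count of sampled instances.
#' @param seed Seed for instance sampling when `m_iterations < n`.
#' @return A `feature_ranking` tibble ranked by descending weight, ties
#'   broken by input order; attribute `method = "relieff"`.
#' @export
relieff_rank <- function(x, y, k_neighbors = 10L, m_iterations = "all",
                         seed = 1L) {
  m <- as_feature_matrix(x)
  y <- as_label_factor(y)
  if (nlevels(droplevels(y)) < 2) abort("both classes must be present in `y`.")
  if (length(y) != nrow(m)) abort("`y` length must match the sample count.")
  n <- nrow(m)
  k_neighbors <- assert_count(k_neighbors, "k_neighbors")
  class_sizes <- table(y)
  if (k_neighbors > min(class_sizes) - 1) {
    abort("`k_neighbors` must be at most the smallest class size minus 1.")
  }

  rng <- apply(m, 2, function(col) diff(range(col)))
  scale <- ifelse(rng > 0, rng, 1)
  ms <- sweep(sweep(m, 2, apply(m, 2, min), "-"), 2, scale, "/")
  active <- rng > 0  # constant features contribute and receive nothing

  if (identical(m_iterations, "all")) {
    inst <- seq_len(n)
  } else {
    m_iterations <- assert_count(m_iterations, "m_iterations")
    inst <- with_rng(derive_seed(seed, 11L),
                     sample.int(n, m_iterations, replace = m_iterations > n))
  }

  d <- as.matrix(stats::dist(ms[, active, drop = FALSE], method = "manhattan"))
  w <- numeric(ncol(m))
  m_count <- length(inst)
  for (i in inst) {
    di <- d[i, ]
    di[i] <- Inf
    hits <- which(y == y[i] & di < Inf)
    misses <- which(y != y[i])
    hits <- hits[order(di[hits], hits)][seq_len(min(k_neighbors, length(hits)))]
    misses <- misses[order(di[misses], misses)][seq_len(min(k_neighbors, length(misses)))]
    diff_h <- abs(sweep(ms[hits, , drop = FALSE], 2, ms[i, ], "-"))
    diff_m <- abs(sweep(ms[misses, , drop = FALSE], 2, ms[i, ], "-"))
    w <- w - colSums(diff_h) / (m_count * k_neighbors) +
      colSums(diff_m) / (m_count * k_neighbors)
  }
  w[!active] <- 0
  ord <- order(-w, seq_along(w))
  new_feature_ranking(colnames(m)[ord], w[ord], raw_p = NULL, "relieff")
}

new_feature_ranking <- function(features, score, raw_p, method) {
  out <- tibble::tibble(rank = seq_along(features), feature = features,
                        score = unname(score))
  if (!is.null(raw_p)) out$raw_p <- raw_p
  structure(out, method = method,
            class = c("feature_ranking", class(out)))
}

#' Select the top N features of a ranking
#'
#' @param ranking A `feature_ranking` from [wilcoxon_rank()] or
#'   [relieff_rank()].
#' @param n Number of features, between 1 and the ranking length.
#' @return Character vector of `n` feature identifiers.
#' @export
select_top <- function(ranking, n) {
  n <- assert_count(n, "n")
  if (n > nrow(ranking)) abort("`n` exceeds the ranking length.")
  ranking$feature[seq_len(n)]
}
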