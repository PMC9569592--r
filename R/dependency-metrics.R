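# Pairwise dependency metrics between molecular features and the extracted
# clinical risk: Spearman rank correlation and the Kraskov k-nearest-
# neighbour mutual-information estimator.

#' Spearman correlations for all feature pairs
#'
#' Rank correlation (average ranks on ties) for every unordered pair of
#' expression features, and for each feature against an extra continuous
#' variable (typically the malignancy risk) if supplied.
#'
#' @param x Samples-by-features table (tibble with optional `sample_id`, or
#'   numeric matrix).
#' @param extra Optional numeric vector (or single-column table) scored
#'   against every feature; reported under pair partner `"malignancy_risk"`.
#' @return A tibble with columns `feature_a`, `feature_b`, `rho`. Constant
#'   features give `NA` with a warning.
#' @examples
#' cfg <- generator_config(n_samples = 30, n_genes = 4, seed = 2)
#' expr <- generate_expression(cfg, generate_clinical(cfg)$label)
#' spearman_pairs(expr)
#' @export
spearman_pairs <- function(x, extra = NULL) {
  m <- as_feature_matrix(x)
  if (nrow(m) < 3) abort("need at least 3 samples.")
  if (!is.null(extra)) {
    if (is.data.frame(extra)) {
      extra <- extra[[if ("malignancy_risk" %in% names(extra)) "malignancy_risk" else 1L]]
    }
    if (length(extra) != nrow(m)) abort("`extra` length must match sample count.")
    m <- cbind(m, setNames(data.frame(extra), RISK_FEATURE))
    m <- as.matrix(m)
  }
  const <- apply(m, 2, function(col) length(unique(col)) <= 1L)
  if (any(const)) {
    warn(sprintf("constant feature(s), correlations reported as NA: %s",
                 paste(colnames(m)[const], collapse = ", ")))
  }
  rho <- suppressWarnings(cor(m, method = "spearman"))
  rho[const, ] <- NA_real_
  rho[, const] <- NA_real_
  pairs <- which(upper.tri(rho), arr.ind = TRUE)
  out <- tibble::tibble(
    feature_a = colnames(m)[pairs[, 1]],
    feature_b = colnames(m)[pairs[, 2]],
    rho = rho[pairs]
  )
  if (!is.null(extra)) {
    out <- dplyr::filter(out, !(.data$feature_a == RISK_FEATURE &
                                  .data$feature_b == RISK_FEATURE))
  }
  out
}

#' Kraskov k-nearest-neighbour mutual information
#'
#' First Kraskov estimator: with `eps_i` the max-norm distance from point
#' `i` to its `k`-th nearest neighbour in the joint space,
#' `MI = psi(k) + psi(N) - mean(psi(n_x + 1) + psi(n_y + 1))`, where `n_x`
#' and `n_y` count the points strictly within `eps_i` on each marginal.
#' Exact ties are broken by an infinitesimal deterministic jitter. The
#' estimate is in nats and may dip slightly below zero for independent
#' variables.
#'
#' @param x,y Numeric vectors of equal length.
#' @param k Neighbour count (default 3).
#' @return Estimated mutual information in nats.
#' @examples
#' set.seed(1)
#' kraskov_mi(rnorm(500), rnorm(500)) # near 0
#' @export
kraskov_mi <- function(x, y, k = 3L) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  k <- assert_count(k, "k")
  if (k >= n - 1) abort("`k` must be smaller than length(x) - 1.")
  if (anyNA(x) || anyNA(y)) abort("missing values are not supported.")

  if (anyDuplicated(x) || anyDuplicated(y)) {
    jx <- if (sd(x) > 0) sd(x) else 1
    jy <- if (sd(y) > 0) sd(y) else 1
    jit <- with_rng(derive_seed(7L, n, k), {
      list(x = runif(n, -1, 1) * 1e-10 * jx, y = runif(n, -1, 1) * 1e-10 * jy)
    })
    x <- x + jit$x
    y <- y + jit$y
  }

  nx <- integer(n)
  ny <- integer(n)
  chunk <- 512L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    dx <- abs(outer(x[idx], x, "-"))
    dy <- abs(outer(y[idx], y, "-"))
    dj <- pmax(dx, dy)
    dj[cbind(seq_along(idx), idx)] <- Inf
    # eps_i = distance to the k-th nearest joint neighbour
    eps <- apply(dj, 1, function(row) sort.int(row, partial = k)[k])
    dx[cbind(seq_along(idx), idx)] <- Inf
    dy[cbind(seq_along(idx), idx)] <- Inf
    nx[idx] <- rowSums(dx < eps)
    ny[idx] <- rowSums(dy < eps)
  }
  digamma(k) + digamma(n) - mean(digamma(nx + 1) + digamma(ny + 1))
}

#' Dependency report for an expression panel
#'
#' Convenience wrapper producing the package's standard dependency summary:
#' Spearman rho for every pair and (optionally, `mi = TRUE`) Kraskov mutual
#' information for the same pairs.
#'
#' @inheritParams spearman_pairs
#' @param mi Also compute mutual information per pair (quadratic in the
#'   number of features; default FALSE).
#' @param k Neighbour count for [kraskov_mi()].
#' @return A tibble `feature_a`, `feature_b`, `rho` (and `mi_nats`).
#' @export
dependency_report <- function(x, extra = NULL, mi = FALSE, k = 3L) {
  out <- spearman_pairs(x, extra)
  if (mi) {
    m <- as_feature_matrix(x)
    if (!is.null(extra)) {
      if (is.data.frame(extra)) {
        extra <- extra[[if ("malignancy_risk" %in% names(extra)) "malignancy_risk" else 1L]]
      }
      m <- cbind(m, setNames(data.frame(extra), RISK_FEATURE))
      m <- as.matrix(m)
    }
    out$mi_nats <- purrr::map2_dbl(out$feature_a, out$feature_b,
                                   function(a, b) kraskov_mi(m[, a], m[, b], k = k))
  }
  out
}

#' Histogram summary of a dependency report column
#'
#' Fixed-width binning (default width 0.05) used for the package's
#' correlation and mutual-information histograms.
#'
#' @param report A tibble from [spearman_pairs()] or [dependency_report()].
#' @param value Column to bin (`"rho"` or `"mi_nats"`).
#' @param binwidth Bin width.
#' @return A tibble `bin_low`, `bin_high`, `count`.
#' @export
dependency_histogram <- function(report, value = "rho", binwidth = 0.05) {
  v <- report[[value]]
  v <- v[is.finite(v)]
  lo <- floor(min(v) / binwidth) * binwidth
  hi <- ceiling(max(v) / binwidth) * binwidth
  if (hi <= lo) hi <- lo + binwidth
  breaks <- seq(lo, hi, by = binwidth)
  counts <- as.vector(table(cut(v, breaks = breaks, include.lowest = TRUE)))
  tibble::tibble(bin_low = breaks[-length(breaks)],
                 bin_high = breaks[-1],
                 count = counts)
}
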