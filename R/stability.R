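# Feature-selection stability across bootstrap iterations: the Kuncheva
# index, chance-corrected mean pairwise overlap of equal-size subsets.

#' Kuncheva stability index of a selection sequence
#'
#' For K subsets of common size k drawn from a universe of n features,
#' \deqn{\kappa(S) = \frac{2}{K(K-1)} \sum_{i<j}
#'   \frac{|S_i \cap S_j| - k^2/n}{k - k^2/n},}
#' the mean pairwise set overlap corrected by its expectation `k^2/n` under
#' selection by chance. Equals 1 iff all subsets are identical; random
#' selection gives values near 0; disjoint subsets give negative values.
#'
#' @param sets A list of K >= 2 character (or integer) vectors, all of the
#'   same cardinality k.
#' @param n_universe Total number of selectable features, > k.
#' @return A single number <= 1.
#' @examples
#' kuncheva_index(list(c("a", "b"), c("c", "d")), n_universe = 10) # -0.25
#' @export
kuncheva_index <- function(sets, n_universe) {
  if (!is.list(sets) || length(sets) < 2) abort("need at least 2 sets.")
  sizes <- lengths(sets)
  k <- sizes[1]
  if (any(sizes != k)) abort("all sets must have the same cardinality.")
  if (k == 0) abort("sets must be nonempty.")
  n_universe <- assert_count(n_universe, "n_universe")
  if (k >= n_universe) {
    abort("the index is undefined when k equals the universe size (denominator 0).")
  }
  exp_overlap <- k^2 / n_universe
  denom <- k - exp_overlap
  K <- length(sets)
  total <- 0
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      total <- total + (length(intersect(sets[[i]], sets[[j]])) - exp_overlap) / denom
    }
  }
  2 * total / (K * (K - 1))
}

#' Gather per-iteration selection sets for stability scoring
#'
#' Returns the selection sequence a strategy's Kuncheva index is computed
#' on. For late fusion the model's feature set is the selected genomic
#' features plus the appended risk feature (cardinality nFeatures + 1) and
#' the universe includes the risk identifier, so early- and late-fusion
#' indices share a scale; for early/no fusion the recorded selections pass
#' through unchanged. Iterations whose set size deviates from the cell's
#' modal size are dropped with a warning.
#'
#' @param records A `bootstrap_records` tibble (one grid cell) from
#'   [run_experiment()], or a list of feature-identifier vectors.
#' @param strategy One of `"early"`, `"late"`, `"none"`; inferred from the
#'   records when present.
#' @param n_genes Genomic universe size; inferred when present.
#' @return A list with elements `sets` and `n_universe`.
#' @export
gather_selection_sets <- function(records, strategy = NULL, n_genes = NULL) {
  if (is.data.frame(records)) {
    strategy <- strategy %||% unique(records$strategy)
    n_genes <- n_genes %||% attr(records, "n_genes")
    sets <- records$selected
  } else {
    sets <- records
  }
  if (is.null(strategy) || length(strategy) != 1) {
    abort("records must come from a single strategy.")
  }
  if (is.null(n_genes)) abort("`n_genes` (genomic universe size) is required.")

  if (strategy == "late") {
    sets <- lapply(sets, function(s) union(s, RISK_FEATURE))
  }
  sizes <- lengths(sets)
  k_mode <- as.integer(names(which.max(table(sizes))))
  if (any(sizes != k_mode)) {
    warn(sprintf("dropping %d iteration(s) with off-modal selection size.",
                 sum(sizes != k_mode)))
    sets <- sets[sizes == k_mode]
  }
  n_universe <- if (strategy %in% c("early", "late", "clinical_only")) {
    n_genes + 1L
  } else {
    n_genes
  }
  list(sets = sets, n_universe = n_universe)
}

#' Kuncheva stability curve over the model-size grid
#'
#' One Kuncheva index per `n_features` value for the requested
#' strategy/method cells of a [run_experiment()] grid. Cells where the
#' selection cardinality equals the universe size (the index's undefined
#' degenerate point) are omitted with a warning.
#'
#' @param grid A `fusion_experiment` object.
#' @param strategies,methods Optional filters (default: all in the grid).
#' @return A `stability_curve` tibble: `strategy`, `method`, `n_features`,
#'   `kuncheva`.
#' @export
stability_curve <- function(grid, strategies = NULL, methods = NULL) {
  stopifnot(inherits(grid, "fusion_experiment"))
  cells <- grid$cells
  if (!is.null(strategies)) cells <- dplyr::filter(cells, .data$strategy %in% strategies)
  if (!is.null(methods)) cells <- dplyr::filter(cells, .data$method %in% methods)
  if (nrow(cells) == 0) abort("no matching cells in the grid.")
  n_genes <- grid$n_genes

  out <- purrr::pmap_dfr(
    cells[c("strategy", "method", "n_features", "selected")],
    function(strategy, method, n_features, selected) {
      if (strategy == "clinical_only") {
        return(tibble::tibble(strategy = strategy, method = method,
                              n_features = n_features, kuncheva = 1))
      }
      gathered <- gather_selection_sets(selected, strategy = strategy,
                                        n_genes = n_genes)
      k <- length(gathered$sets[[1]])
      if (k >= gathered$n_universe) {
        warn(sprintf("omitting %s/%s at n_features=%d: selection spans the whole universe.",
                     strategy, method, n_features))
        return(tibble::tibble(strategy = character(0), method = character(0),
                              n_features = integer(0), kuncheva = numeric(0)))
      }
      tibble::tibble(strategy = strategy, method = method,
                     n_features = n_features,
                     kuncheva = kuncheva_index(gathered$sets, gathered$n_universe))
    })
  structure(out, class = c("stability_curve", class(out)))
}

#' @describeIn autoplot_fusionlab Kuncheva index against model size.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.stability_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$n_features, y = .data$kuncheva,
                               colour = .data$strategy,
                               linetype = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "number of selected features", y = "Kuncheva index",
                  colour = "strategy", linetype = "selection") +
    ggplot2::theme_minimal()
}
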