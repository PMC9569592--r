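# Bootstrap evaluation of clinical-genomic fusion strategies: early fusion
# (risk competes in the ranking), late fusion (risk appended to the selected
# genes), no fusion (genes only) and clinical-only, with train-fitted
# z-score normalization and a linear SVM, all inside the resampling loop so
# no test information leaks into selection or normalization.

FUSION_STRATEGIES <- c("early", "late", "none", "clinical_only")

#' Z-score normalization fitted on the training split
#'
#' Column means and standard deviations (n - 1 denominator) are computed on
#' the training matrix only and applied to both matrices; zero-variance
#' training columns map to all-zeros in both.
#'
#' @param train,test Numeric matrices with matching columns (`test` may be
#'   NULL).
#' @return A list with normalized `train` and `test`.
#' @export
zscore_normalize <- function(train, test = NULL) {
  train <- as_feature_matrix(train)
  if (nrow(train) == 0) abort("`train` must be nonempty.")
  if (!is.null(test)) {
    test <- as_feature_matrix(test)
    if (!is.null(colnames(test)) && !is.null(colnames(train))) {
      extra <- setdiff(colnames(test), colnames(train))
      if (length(extra) > 0) {
        abort(sprintf("test columns absent from train: %s",
                      paste(extra, collapse = ", ")))
      }
      test <- test[, colnames(train), drop = FALSE]
    } else if (ncol(test) != ncol(train)) {
      abort("train and test must have the same columns.")
    }
  }
  mu <- colMeans(train)
  sigma <- apply(train, 2, sd)
  keep <- is.finite(sigma) & sigma > 0
  scale_by <- ifelse(keep, sigma, 1)
  norm <- function(m) {
    out <- sweep(sweep(m, 2, mu, "-"), 2, scale_by, "/")
    out[, !keep] <- 0
    out
  }
  list(train = norm(train), test = if (!is.null(test)) norm(test))
}

# Deterministic in-bag draw for iteration b; redraws until the in-bag part
# holds both classes and at least one sample is out of bag.
draw_inbag <- function(y, b, seed) {
  n <- length(y)
  for (attempt in 0:99) {
    inbag <- with_rng(derive_seed(seed, 300L, b, attempt),
                      sample.int(n, n, replace = TRUE))
    oob <- setdiff(seq_len(n), unique(inbag))
    if (length(unique(y[inbag])) == 2L && length(oob) > 0) {
      return(list(inbag = inbag, oob = oob, redraws = attempt))
    }
  }
  abort("could not draw an in-bag sample with both classes.")
}

rank_features <- function(m, y, method, k_neighbors) {
  if (method == "wilcoxon") {
    wilcoxon_rank(m, y)
  } else if (method == "relieff") {
    k_eff <- min(k_neighbors, min(table(droplevels(y))) - 1L)
    relieff_rank(m, y, k_neighbors = k_eff)
  } else {
    abort(sprintf("unknown feature-selection method '%s'.", method))
  }
}

# Feature set entering the classifier for one cell. `rankings` holds the
# in-bag rankings: $genes (genomic candidates) and $early (genes + risk).
cell_feature_set <- function(strategy, method, n_features, rankings) {
  switch(strategy,
         early = select_top(rankings[[method]]$early, n_features),
         late = c(select_top(rankings[[method]]$genes, n_features), RISK_FEATURE),
         none = select_top(rankings[[method]]$genes, n_features),
         clinical_only = RISK_FEATURE,
         abort(sprintf("unknown strategy '%s'.", strategy)))
}

fit_and_score <- function(x_all, y, sel, inbag, oob, cost) {
  # canonical column order: selections with equal content fit identically
  sel <- colnames(x_all)[colnames(x_all) %in% sel]
  train <- x_all[inbag, sel, drop = FALSE]
  test <- x_all[oob, sel, drop = FALSE]
  z <- zscore_normalize(train, test)
  fit <- e1071::svm(x = z$train, y = y[inbag], kernel = "linear",
                    cost = cost, scale = FALSE)
  mean(predict(fit, z$test) == y[oob])
}

#' Run one bootstrap iteration of a fusion strategy
#'
#' Draws an in-bag sample of size n with replacement (out-of-bag samples
#' form the test set), performs fusion, feature selection, train-fitted
#' z-score normalization and linear-SVM classification, and records the
#' out-of-bag accuracy together with the final feature set. Both ranking
#' methods are invariant to per-feature affine rescaling, so selection is
#' computed once on the raw in-bag data regardless of where normalization
#' sits in the strategy's pipeline.
#'
#' @param x_genes Samples-by-genes table or matrix.
#' @param risk Per-sample malignancy risk: numeric vector or the tibble
#'   from [extract_malignancy_risk()].
#' @param y Binary labels.
#' @param strategy `"early"`, `"late"`, `"none"` or `"clinical_only"`.
#' @param method `"wilcoxon"` or `"relieff"`.
#' @param n_features Model size: for `late`/`none`, the number of genomic
#'   features (late models additionally carry the risk feature); for
#'   `early`, the total number of selected features with the risk feature
#'   competing in the ranking (up to `n_genes + 1`).
#' @param iteration Iteration index (seeds the in-bag draw).
#' @param seed Experiment seed.
#' @param cost Linear SVM cost parameter.
#' @param k_neighbors ReliefF neighbour count (capped at the smallest
#'   in-bag class size minus 1).
#' @return A one-row tibble: `iteration`, `strategy`, `method`,
#'   `n_features`, `accuracy`, `n_oob`, and list-columns `selected`,
#'   `inbag`.
#' @export
run_iteration <- function(x_genes, risk, y, strategy, method, n_features,
                          iteration = 1L, seed = 1L, cost = 1,
                          k_neighbors = 10L) {
  xg <- as_feature_matrix(x_genes)
  risk <- as_risk_vector(risk, nrow(xg))
  y <- as_label_factor(y)
  strategy <- match.arg(strategy, FUSION_STRATEGIES)
  check_n_features(n_features, strategy, ncol(xg))

  x_all <- cbind(xg, setNames(data.frame(risk), RISK_FEATURE))
  x_all <- as.matrix(x_all)
  draw <- draw_inbag(y, iteration, seed)

  rankings <- list()
  rankings[[method]] <- list()
  if (strategy == "early") {
    rankings[[method]]$early <- rank_features(x_all[draw$inbag, , drop = FALSE],
                                              y[draw$inbag], method, k_neighbors)
  } else if (strategy != "clinical_only") {
    rankings[[method]]$genes <- rank_features(xg[draw$inbag, , drop = FALSE],
                                              y[draw$inbag], method, k_neighbors)
  }
  sel <- cell_feature_set(strategy, method, n_features, rankings)
  acc <- fit_and_score(x_all, y, sel, draw$inbag, draw$oob, cost)
  tibble::tibble(iteration = iteration, strategy = strategy, method = method,
                 n_features = as.integer(n_features), accuracy = acc,
                 n_oob = length(draw$oob),
                 selected = list(sel), inbag = list(draw$inbag))
}

as_risk_vector <- function(risk, n) {
  if (is.data.frame(risk)) {
    risk <- risk[[if ("malignancy_risk" %in% names(risk)) "malignancy_risk" else 1L]]
  }
  if (!is.numeric(risk) || length(risk) != n) {
    abort("`risk` must be a numeric vector (or risk tibble) with one value per sample.")
  }
  risk
}

check_n_features <- function(nf, strategy, n_genes) {
  limit <- if (strategy == "early") n_genes + 1L else n_genes
  if (strategy != "clinical_only" && (nf < 1 || nf > limit)) {
    abort(sprintf("n_features=%d out of range [1, %d] for strategy '%s'.",
                  nf, limit, strategy))
  }
  invisible(nf)
}

#' Bootstrap evaluation grid over fusion strategies, selectors and sizes
#'
#' Runs `B` bootstrap iterations for every (strategy, method, n_features)
#' cell. The in-bag draw at a given iteration index is shared across all
#' cells, so accuracies are paired between strategies and methods; in-bag
#' rankings are likewise computed once per iteration and method and reused
#' across strategies and model sizes. Each cell is summarized by its median
#' out-of-bag accuracy, 2.5/97.5 percentile interval, and the Kuncheva
#' stability index of its B selected feature sets.
#'
#' @inheritParams run_iteration
#' @param strategies Subset of `"early"`, `"late"`, `"none"`,
#'   `"clinical_only"`.
#' @param methods Subset of `"wilcoxon"`, `"relieff"`.
#' @param n_features Integer vector of model sizes; cells whose size is
#'   invalid for a strategy (e.g. beyond the genomic panel for `none`) are
#'   dropped with a warning. `clinical_only` contributes a single
#'   size-independent cell.
#' @param B Number of bootstrap iterations (>= 2).
#' @param seed Experiment seed; the entire grid is reproducible from it.
#' @return A `fusion_experiment` object; `$cells` is a tibble with one row
#'   per cell (`median_acc`, `ci_low`, `ci_high`, `kuncheva`, plus
#'   list-columns `accuracies` and `selected`). See [tidy.fusion_experiment()].
#' @export
run_experiment <- function(x_genes, risk, y,
                           strategies = c("early", "late", "none"),
                           methods = c("wilcoxon", "relieff"),
                           n_features = c(1L, 3L, 5L, 8L, 15L),
                           B = 500L, seed = 1L, cost = 1, k_neighbors = 10L) {
  xg <- as_feature_matrix(x_genes)
  n <- nrow(xg)
  G <- ncol(xg)
  risk <- as_risk_vector(risk, n)
  y <- as_label_factor(y)
  strategies <- match.arg(strategies, FUSION_STRATEGIES, several.ok = TRUE)
  methods <- match.arg(methods, c("wilcoxon", "relieff"), several.ok = TRUE)
  B <- assert_count(B, "B", lower = 2L)
  n_features <- vapply(n_features, assert_count, integer(1), field = "n_features")

  cells <- tidyr::expand_grid(
    strategy = setdiff(strategies, "clinical_only"),
    method = methods,
    n_features = as.integer(n_features)
  )
  valid <- purrr::pmap_lgl(cells, function(strategy, method, n_features) {
    n_features <= (if (strategy == "early") G + 1L else G)
  })
  if (any(!valid)) {
    warn(sprintf("dropping %d grid cell(s) with n_features beyond the panel.",
                 sum(!valid)))
    cells <- cells[valid, , drop = FALSE]
  }
  if ("clinical_only" %in% strategies) {
    cells <- dplyr::bind_rows(
      cells,
      tibble::tibble(strategy = "clinical_only", method = methods[1],
                     n_features = 1L)
    )
  }
  if (nrow(cells) == 0) abort("empty evaluation grid.")

  x_all <- cbind(xg, setNames(data.frame(risk), RISK_FEATURE))
  x_all <- as.matrix(x_all)
  need_early <- "early" %in% cells$strategy
  need_genes <- any(cells$strategy %in% c("late", "none"))

  acc <- matrix(NA_real_, B, nrow(cells))
  selected <- vector("list", nrow(cells))
  for (ci in seq_len(nrow(cells))) selected[[ci]] <- vector("list", B)
  total_redraws <- 0L

  for (b in seq_len(B)) {
    draw <- draw_inbag(y, b, seed)
    total_redraws <- total_redraws + draw$redraws
    y_in <- y[draw$inbag]
    rankings <- list()
    for (mth in methods) {
      rankings[[mth]] <- list()
      if (need_genes) {
        rankings[[mth]]$genes <- rank_features(xg[draw$inbag, , drop = FALSE],
                                               y_in, mth, k_neighbors)
      }
      if (need_early) {
        rankings[[mth]]$early <- rank_features(x_all[draw$inbag, , drop = FALSE],
                                               y_in, mth, k_neighbors)
      }
    }
    for (ci in seq_len(nrow(cells))) {
      sel <- cell_feature_set(cells$strategy[ci], cells$method[ci],
                              cells$n_features[ci], rankings)
      acc[b, ci] <- fit_and_score(x_all, y, sel, draw$inbag, draw$oob, cost)
      selected[[ci]][[b]] <- sel
    }
  }
  if (total_redraws > 0) {
    warn(sprintf("%d in-bag draw(s) redrawn to keep both classes in bag.",
                 total_redraws))
  }

  cells$accuracies <- lapply(seq_len(nrow(cells)), function(ci) acc[, ci])
  cells$selected <- selected
  summaries <- purrr::pmap_dfr(
    cells[c("strategy", "n_features", "accuracies", "selected")],
    function(strategy, n_features, accuracies, selected) {
      s <- summarize_accuracy(accuracies)
      s$kuncheva <- cell_kuncheva(strategy, selected, G)
      s
    })
  cells <- dplyr::bind_cols(cells[c("strategy", "method", "n_features")],
                            summaries,
                            cells[c("accuracies", "selected")])

  structure(
    list(cells = cells, B = B, seed = seed, n_samples = n, n_genes = G,
         majority_rate = max(table(y)) / n, redraws = total_redraws),
    class = "fusion_experiment"
  )
}

cell_kuncheva <- function(strategy, selected, n_genes) {
  if (strategy == "clinical_only") return(1)
  gathered <- gather_selection_sets(selected, strategy = strategy,
                                    n_genes = n_genes)
  k <- length(gathered$sets[[1]])
  if (k >= gathered$n_universe) return(NA_real_)
  kuncheva_index(gathered$sets, gathered$n_universe)
}

#' Median accuracy with a percentile interval
#'
#' @param records Numeric accuracy vector, or a records tibble with an
#'   `accuracy` column (>= 2 values).
#' @return A one-row tibble: `median_acc`, `ci_low`, `ci_high` (2.5 and
#'   97.5 percentiles).
#' @export
summarize_accuracy <- function(records) {
  accs <- if (is.data.frame(records)) records$accuracy else records
  if (!is.numeric(accs) || length(accs) < 2) {
    abort("need at least 2 accuracy values.")
  }
  q <- unname(quantile(accs, c(0.025, 0.975)))
  tibble::tibble(median_acc = median(accs), ci_low = q[1], ci_high = q[2])
}

#' Compare two models' bootstrap accuracies
#'
#' Two-sided Wilcoxon-Mann-Whitney test (exact for small untied samples,
#' normal approximation with tie correction otherwise; fully tied input
#' gives p = 1).
#'
#' @param acc_a,acc_b Numeric vectors of per-iteration accuracies.
#' @return Two-sided p-value.
#' @export
compare_models <- function(acc_a, acc_b) {
  if (length(acc_a) < 2 || length(acc_b) < 2) {
    abort("both accuracy vectors need at least 2 values.")
  }
  ranksum_p(acc_a, acc_b)
}

#' @export
print.fusion_experiment <- function(x, ...) {
  cat(sprintf("<fusion_experiment> %d cells, B = %d, n = %d, %d genes\n",
              nrow(x$cells), x$B, x$n_samples, x$n_genes))
  print(tidy(x), n = 20)
  invisible(x)
}

#' Tidy and summarize fusion experiments
#'
#' `tidy()` returns one row per grid cell (strategy, method, model size,
#' median accuracy, percentile interval, Kuncheva index); `glance()`
#' returns a one-row experiment summary including the best cell.
#'
#' @param x A `fusion_experiment` from [run_experiment()].
#' @param ... Unused.
#' @name tidy_fusionlab
NULL

#' @rdname tidy_fusionlab
#' @export
#' @exportS3Method generics::tidy
tidy.fusion_experiment <- function(x, ...) {
  dplyr::select(x$cells, "strategy", "method", "n_features",
                "median_acc", "ci_low", "ci_high", "kuncheva")
}

#' @rdname tidy_fusionlab
#' @export
#' @exportS3Method generics::glance
glance.fusion_experiment <- function(x, ...) {
  cells <- tidy(x)
  best <- cells[order(-cells$median_acc, cells$n_features), ][1, ]
  tibble::tibble(
    n_cells = nrow(cells), B = x$B, n_samples = x$n_samples,
    n_genes = x$n_genes, majority_rate = x$majority_rate,
    best_strategy = best$strategy, best_method = best$method,
    best_n_features = best$n_features, best_median_acc = best$median_acc
  )
}

#' Plot methods for fusionlab result objects
#'
#' @param object A result object.
#' @param ... Unused.
#' @name autoplot_fusionlab
NULL

#' @describeIn autoplot_fusionlab Median accuracy (with percentile ribbon)
#'   against model size, one panel per selection method.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.fusion_experiment <- function(object, ...) {
  cells <- dplyr::filter(tidy(object), .data$strategy != "clinical_only")
  p <- ggplot2::ggplot(cells,
                       ggplot2::aes(x = .data$n_features, y = .data$median_acc,
                                    colour = .data$strategy,
                                    fill = .data$strategy)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "number of selected features",
                  y = "median out-of-bag accuracy", colour = "strategy",
                  fill = "strategy") +
    ggplot2::theme_minimal()
  clin <- dplyr::filter(tidy(object), .data$strategy == "clinical_only")
  if (nrow(clin) > 0) {
    p <- p + ggplot2::geom_hline(yintercept = clin$median_acc[1],
                                 linetype = "dashed", colour = "grey40")
  }
  p
}
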