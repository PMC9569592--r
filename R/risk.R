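#' Extract a cross-fitted malignancy-risk feature from clinical data
#'
#' The single continuous clinical feature used downstream in data fusion.
#' Samples are split into `k` label-stratified folds; for each fold a
#' Bayesian network over the clinical variables plus the histopathology
#' label (as the `risk` node) is learned ([learn_structure()]) and fitted
#' ([estimate_parameters()]) on the other `k - 1` folds, and each held-out
#' sample's risk is the network posterior `P(malignant | clinical)` with
#' that sample's values — restricted to the Markov blanket of the risk
#' node — as evidence. No sample's risk is ever computed from a model
#' trained on it.
#'
#' @param data A discretized clinical table ([discretize_clinical()]) with
#'   factor columns `sex`, `age_band`, `size_band`, `bethesda` and `label`.
#' @param k Number of cross-fitting folds (>= 2).
#' @param iss Imaginary sample size for CPT smoothing.
#' @param n_draws Likelihood-weighting particles per query.
#' @param seed Integer seed (fold assignment and particle draws).
#' @param method Inference method per query: `"lw"` or `"exact"`.
#' @return A tibble with columns `sample_id` (if present in `data`),
#'   `malignancy_risk` in `[0, 1]` and `label`, one row per input sample.
#' @examples
#' cfg <- generator_config(n_samples = 60, n_genes = 5, seed = 4)
#' clin <- discretize_clinical(generate_clinical(cfg))
#' risk <- extract_malignancy_risk(clin, k = 3, method = "exact")
#' head(risk)
#' @export
extract_malignancy_risk <- function(data, k = 10, iss = 1, n_draws = 1e4,
                                    seed = 1L, method = c("lw", "exact")) {
  method <- match.arg(method)
  k <- assert_count(k, "k", lower = 2L)
  data <- tibble::as_tibble(data)
  vars <- c("sex", "age_band", "size_band", "bethesda")
  missing_cols <- setdiff(c(vars, "label"), names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("discretized clinical table lacks columns: %s (run discretize_clinical first?)",
                  paste(missing_cols, collapse = ", ")))
  }
  y <- as_label_factor(data$label)
  n <- nrow(data)
  if (k > n) abort("`k` exceeds the number of samples.")

  bn_data <- as_bn_data(dplyr::mutate(data[vars], risk = y))

  folds <- make_stratified_folds(y, k, seed)
  risk <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    test_idx <- which(folds == f)
    train <- bn_data[-test_idx, , drop = FALSE]
    dag <- learn_structure(train, seed = derive_seed(seed, f))
    net <- estimate_parameters(dag, train, iss = iss)
    mb <- intersect(markov_blanket(net$dag, "risk"), vars)

    ev_tab <- bn_data[test_idx, mb, drop = FALSE]
    key <- if (length(mb) == 0) rep("", length(test_idx)) else
      do.call(paste, c(ev_tab, sep = "\r"))
    for (u in unique(key)) {
      rows <- test_idx[key == u]
      ev <- if (length(mb) == 0) list() else
        lapply(bn_data[rows[1], mb, drop = FALSE], as.character)
      risk[rows] <- query_risk(net, ev, n_draws = n_draws,
                               seed = derive_seed(seed, f, match(u, unique(key))),
                               method = method)
    }
  }

  out <- tibble::tibble(malignancy_risk = risk, label = y)
  if ("sample_id" %in% names(data)) {
    out <- dplyr::bind_cols(tibble::tibble(sample_id = data$sample_id), out)
  }
  out
}

# Label-stratified fold assignment; repartitions with a fresh seed (up to 10
# times, with a warning) if some training split would be single-class.
make_stratified_folds <- function(y, k, seed) {
  for (attempt in 0:9) {
    folds <- with_rng(derive_seed(seed, 100L, attempt), {
      f <- integer(length(y))
      for (cl in levels(y)) {
        idx <- which(y == cl)
        f[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
      }
      f
    })
    ok <- all(vapply(seq_len(k), function(f_i) {
      length(unique(y[folds != f_i])) == 2L
    }, logical(1)))
    if (ok) {
      if (attempt > 0) warn("fold partition repartitioned to keep both classes in every training split.")
      return(folds)
    }
  }
  abort("could not build folds with both classes in every training split.")
}
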