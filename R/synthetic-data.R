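# Synthetic cohort generator: a latent binary histopathology class drives
# discrete clinical variables (logistic links) and a class-conditional
# Gaussian expression panel with block covariance. Defaults emulate a
# ~200-sample thyroid FNAB cohort at 77/123 malignant/benign prevalence.

BETHESDA_LEVELS <- c("II", "III", "IV", "V", "VI")
BETHESDA_SCORE <- c(-1, -0.5, 0, 0.5, 1)
# Cohorts are dominated by the indeterminate categories III-V.
BETHESDA_BASE <- c(0.10, 0.30, 0.25, 0.25, 0.10)

AGE_BANDS <- c("<20", "(20,45]", "(45,60]", ">60")
AGE_SCORE <- c(-1, -1 / 3, 1 / 3, 1)
AGE_BASE <- c(0.05, 0.45, 0.30, 0.20)
AGE_RANGES <- list(c(10L, 20L), c(21L, 45L), c(46L, 60L), c(61L, 85L))

SIZE_BANDS <- c("XS", "S", "M", "L", "XL", "XXL")

#' Configuration for the synthetic clinical-genomic generator
#'
#' Bundles and validates every knob of the generator. The defaults describe
#' the study conditions the package targets: 200 fine-needle-biopsy samples
#' at malignant prevalence 77/200, a 163-gene panel with 15 informative
#' genes, and a clinical (Bethesda + age) channel whose large-sample
#' malignancy-risk AUC is 0.90 (`clinical_signal = 3.7`, fixed once by
#' calibrating the generative model at the default complementarity; see the
#' methods vignette).
#'
#' @param n_samples Number of samples.
#' @param prevalence Probability of the malignant class, in (0, 1).
#' @param n_genes Number of genes in the expression panel.
#' @param n_informative Number of genes carrying class signal (first
#'   `n_informative` columns), `<= n_genes`.
#' @param effect_size Standardized between-class mean shift per informative
#'   gene (expression noise has unit variance).
#' @param correlation_regime `"unimodal"` (weak random gene-gene correlations
#'   centred at 0, as in large curated panels) or `"bimodal"` (two gene
#'   blocks with within-block correlation `+block_rho` and between-block
#'   `-block_rho`, as in small co-regulated panels).
#' @param block_rho Within-block correlation magnitude in `[0, 1)`; only used
#'   by the bimodal regime.
#' @param clinical_signal Strength of the Bethesda-label association on the
#'   log-odds scale; the age-band association is 10 times weaker. 0 makes
#'   all clinical variables independent of the label.
#' @param clinical_complementarity Fraction of the clinical channel's class
#'   signal that is carried only by the clinical variables. In
#'   [generate_dataset()] the Bethesda/age tilt driver is
#'   `cc * label + (1 - cc) * gene score`: at 0 the clinical variables
#'   depend on the label only through the informative genes (so the
#'   extracted risk is conditionally independent of the label given the
#'   expression data and fusion cannot help asymptotically); at 1 the
#'   clinical noise channel is fully independent of the genes.
#' @param seed Integer seed; identical configuration + seed gives
#'   bit-identical output.
#'
#' @return An object of class `generator_config` (a validated list).
#' @examples
#' cfg <- generator_config(n_samples = 50, n_genes = 10, seed = 1)
#' clin <- generate_clinical(cfg)
#' table(clin$label)
#' @export
generator_config <- function(n_samples = 200,
                             prevalence = 77 / 200,
                             n_genes = 163,
                             n_informative = 15,
                             effect_size = 0.7,
                             correlation_regime = c("unimodal", "bimodal"),
                             block_rho = 0.5,
                             clinical_signal = 3.7,
                             clinical_complementarity = 0.5,
                             seed = 1L) {
  correlation_regime <- match.arg(correlation_regime)
  n_samples <- assert_count(n_samples, "n_samples")
  assert_scalar_number(prevalence, "prevalence", 0, 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  n_genes <- assert_count(n_genes, "n_genes")
  n_informative <- assert_count(n_informative, "n_informative", lower = 0L)
  if (n_informative > n_genes) {
    abort("`n_informative` must not exceed `n_genes`.")
  }
  assert_scalar_number(effect_size, "effect_size")
  assert_scalar_number(block_rho, "block_rho", 0, 1, strict_upper = TRUE)
  assert_scalar_number(clinical_signal, "clinical_signal")
  assert_scalar_number(clinical_complementarity, "clinical_complementarity", 0, 1)
  seed <- assert_count(seed, "seed", lower = 0L)

  structure(
    list(
      n_samples = n_samples, prevalence = prevalence, n_genes = n_genes,
      n_informative = n_informative, effect_size = effect_size,
      correlation_regime = correlation_regime, block_rho = block_rho,
      clinical_signal = clinical_signal,
      clinical_complementarity = clinical_complementarity, seed = seed
    ),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  for (nm in names(x)) cat(sprintf("  %-25s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Draw one categorical clinical variable per sample: base frequencies tilted
# on the log scale by signal * score * driver, where the driver is the
# centred label (standalone use) or a label/gene-score blend.
draw_tilted_categorical <- function(base, score, signal, driver) {
  logw <- outer(driver, score * signal) + rep(log(base), each = length(driver))
  w <- exp(logw - apply(logw, 1, max))
  p <- w / rowSums(w)
  u <- runif(length(driver))
  cum <- t(apply(p, 1, cumsum))
  idx <- rowSums(u > cum) + 1L
  pmin(idx, length(base))
}

#' Generate a raw synthetic clinical table
#'
#' Draws the binary histopathology label and raw clinical variables. The
#' Bethesda category carries the class signal (`clinical_signal` on the
#' log-odds scale), the age band a 10-times-weaker one; sex and tumour size
#' are independent of the label.
#'
#' @param config A [generator_config()].
#' @param labels Optional pre-drawn per-sample labels; drawn as
#'   Bernoulli(`prevalence`) when NULL.
#' @param gene_score Optional standardized per-sample molecular score. When
#'   supplied (as [generate_dataset()] does), the Bethesda/age tilt driver
#'   is the blend `clinical_complementarity * label +
#'   (1 - clinical_complementarity) * gene score`, so at complementarity 0
#'   the clinical variables depend on the label only through the genes.
#' @return A tibble with columns `sample_id`, `sex` (F/M), `age` (years),
#'   `tumor_size` (cm), `bethesda` (II-VI) and `label` (benign/malignant).
#'   The attribute `"clinical_score"` holds the realized standardized
#'   clinical log-odds score.
#' @export
generate_clinical <- function(config, labels = NULL, gene_score = NULL) {
  stopifnot(inherits(config, "generator_config"))
  with_rng(derive_seed(config$seed, 1L), {
    n <- config$n_samples
    # always consume the label draws so the downstream stream does not
    # depend on whether labels were supplied
    y_drawn <- rbinom(n, 1L, config$prevalence)
    y <- if (is.null(labels)) y_drawn else
      as.integer(as_label_factor(labels) == "malignant")
    if (length(y) != n) abort("`labels` length must equal `n_samples`.")

    driver <- y - 0.5
    if (!is.null(gene_score)) {
      if (length(gene_score) != n) {
        abort("`gene_score` length must equal `n_samples`.")
      }
      cc <- config$clinical_complementarity
      driver <- cc * (y - 0.5) + (1 - cc) * 0.5 * gene_score
    }

    b_idx <- draw_tilted_categorical(BETHESDA_BASE, BETHESDA_SCORE,
                                     config$clinical_signal, driver)
    a_idx <- draw_tilted_categorical(AGE_BASE, AGE_SCORE,
                                     config$clinical_signal / 10, driver)
    age <- vapply(a_idx, function(i) {
      r <- AGE_RANGES[[i]]
      as.integer(r[1] + floor(runif(1) * (r[2] - r[1] + 1)))
    }, integer(1))

    sex <- ifelse(runif(n) < 0.75, "F", "M")
    size <- round(pmax(rlnorm(n, meanlog = log(1.2), sdlog = 0.6), 0.1), 1)

    score <- config$clinical_signal * BETHESDA_SCORE[b_idx] +
      config$clinical_signal / 10 * AGE_SCORE[a_idx]
    score_sd <- sd(score)
    score <- if (is.na(score_sd) || score_sd == 0) score * 0 else
      (score - mean(score)) / score_sd

    out <- tibble::tibble(
      sample_id = sprintf("S%03d", seq_len(n)),
      sex = factor(sex, levels = c("F", "M")),
      age = age,
      tumor_size = size,
      bethesda = factor(BETHESDA_LEVELS[b_idx], levels = BETHESDA_LEVELS),
      label = factor(ifelse(y == 1, "malignant", "benign"),
                     levels = c("benign", "malignant"))
    )
    attr(out, "clinical_score") <- score
    out
  })
}

#' Generate a synthetic expression matrix
#'
#' Class-conditional multivariate normal expression on a log-expression-like
#' scale (per-gene baseline ~ N(7, 1), unit noise variance). The first
#' `n_informative` genes are shifted between classes by `effect_size`.
#' Under the bimodal regime, genes split into two equal blocks with
#' within-block correlation `+block_rho` and between-block `-block_rho`
#' (a sign-split single-factor covariance); the unimodal regime uses three
#' weak random latent factors, giving correlations centred at zero.
#'
#' @param config A [generator_config()].
#' @param labels Per-sample labels (benign/malignant, 0/1 or logical) of
#'   length `n_samples`.
#' @return A tibble: `sample_id` plus `n_genes` numeric columns
#'   `gene_001`, `gene_002`, ... The attribute `"gene_score"` holds the
#'   standardized mean of the informative genes, used by
#'   [generate_dataset()] as the molecular driver of the clinical channel.
#' @export
generate_expression <- function(config, labels) {
  stopifnot(inherits(config, "generator_config"))
  y <- as_label_factor(labels)
  n <- length(y)
  if (n != config$n_samples) {
    abort("`labels` length must equal `config$n_samples`.")
  }
  p <- config$n_genes

  with_rng(derive_seed(config$seed, 2L), {
    baseline <- rnorm(p, mean = 7, sd = 1)
    ysign <- ifelse(y == "malignant", 0.5, -0.5)

    if (config$correlation_regime == "bimodal") {
      rho <- config$block_rho
      v <- rep(c(1, -1), c(ceiling(p / 2), floor(p / 2)))
      z <- rnorm(n)
      x <- sqrt(rho) * tcrossprod(z, v) +
        sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
    } else {
      loadings <- matrix(rnorm(p * 3, sd = 0.35), p, 3)
      z <- matrix(rnorm(n * 3), n, 3)
      x <- tcrossprod(z, loadings) + matrix(rnorm(n * p), n, p)
      x <- sweep(x, 2, sqrt(1 + rowSums(loadings^2)), "/")
    }

    gene_score <- rep(0, n)
    if (config$n_informative > 0) {
      idx <- seq_len(config$n_informative)
      x[, idx] <- x[, idx] + config$effect_size * ysign
      gs <- rowMeans(x[, idx, drop = FALSE])
      gene_score <- (gs - mean(gs)) / sd(gs)
    }
    x <- sweep(x, 2, baseline, "+")
    colnames(x) <- sprintf("gene_%03d", seq_len(p))
    out <- dplyr::bind_cols(
      tibble::tibble(sample_id = sprintf("S%03d", seq_len(n))),
      tibble::as_tibble(x)
    )
    attr(out, "gene_score") <- gene_score
    out
  })
}

#' Generate and write a complete synthetic dataset
#'
#' Draws labels, generates expression conditional on them, and then the
#' clinical variables with the label/gene-score blend that gives
#' `clinical_complementarity` its meaning; writes `clinical.csv`,
#' `expression.csv`, `labels.csv` and a JSON `manifest.json` recording the
#' configuration.
#'
#' @param config A [generator_config()].
#' @param out_dir Directory to write into (created if missing).
#' @return Invisibly, a list with elements `clinical`, `expression`,
#'   `labels` (tibbles) and `paths`.
#' @seealso [read_dataset()]
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "generator_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create directory '%s'.", out_dir))

  labels_only <- generate_clinical(config)$label
  expression <- generate_expression(config, labels_only)
  clinical <- generate_clinical(config, labels = labels_only,
                                gene_score = attr(expression, "gene_score"))
  labels <- tibble::tibble(sample_id = clinical$sample_id,
                           label = clinical$label)

  paths <- list(
    clinical = file.path(out_dir, "clinical.csv"),
    expression = file.path(out_dir, "expression.csv"),
    labels = file.path(out_dir, "labels.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  clin_out <- dplyr::select(clinical, -"label")
  utils::write.csv(clin_out, paths$clinical, row.names = FALSE)
  utils::write.csv(expression, paths$expression, row.names = FALSE)
  utils::write.csv(labels, paths$labels, row.names = FALSE)
  manifest <- list(config = unclass(config), seed = config$seed,
                   files = lapply(paths[1:3], basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(clinical = clinical, expression = expression,
                 labels = labels, paths = paths))
}

#' Read a dataset written by `generate_dataset()`
#'
#' Validates the manifest (the recorded top-level seed must match the
#' embedded configuration's seed) and restores column types.
#'
#' @param dir Directory containing `clinical.csv`, `expression.csv`,
#'   `labels.csv` and `manifest.json`.
#' @return A list with tibbles `clinical` (including the label column),
#'   `expression`, `labels`, and the parsed `config`.
#' @export
read_dataset <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) abort(sprintf("no manifest.json in '%s'.", dir))
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  if (is.null(manifest$seed) || is.null(manifest$config$seed) ||
      manifest$seed != manifest$config$seed) {
    abort("manifest seed does not match the embedded config seed.")
  }
  clinical <- tibble::as_tibble(utils::read.csv(file.path(dir, "clinical.csv")))
  labels <- tibble::as_tibble(utils::read.csv(file.path(dir, "labels.csv")))
  expression <- tibble::as_tibble(utils::read.csv(file.path(dir, "expression.csv")))

  clinical$sex <- factor(clinical$sex, levels = c("F", "M"))
  clinical$bethesda <- factor(clinical$bethesda, levels = BETHESDA_LEVELS)
  labels$label <- factor(labels$label, levels = c("benign", "malignant"))
  clinical <- dplyr::left_join(clinical, labels, by = "sample_id")
  list(clinical = clinical, expression = expression, labels = labels,
       config = manifest$config)
}
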