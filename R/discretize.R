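#' Discretize raw clinical variables into expert bands
#'
#' Maps age to the bands `<20`, `(20,45]`, `(45,60]`, `>60` and tumour size
#' (cm) to the cytology size classes `XS` (<=0.5), `S` (0.5,1], `M` (1,1.5],
#' `L` (1.5,2.5], `XL` (2.5,4], `XXL` (>4). All intervals are left-open,
#' right-closed, with the lowest bin closed at zero, so a size of exactly
#' 0.5 cm is `XS` and an age of exactly 20 falls in `<20`. Sex, Bethesda
#' category and the label pass through unchanged.
#'
#' @param raw A data frame with columns `sex`, `age`, `tumor_size`,
#'   `bethesda`, and optionally `sample_id` and `label`, as produced by
#'   [generate_clinical()].
#' @return A tibble with factor columns `sex`, `age_band`, `size_band`,
#'   `bethesda` (plus any `sample_id`/`label` passed through).
#' @examples
#' cfg <- generator_config(n_samples = 20, n_genes = 5, seed = 1)
#' discretize_clinical(generate_clinical(cfg))
#' @export
discretize_clinical <- function(raw) {
  raw <- tibble::as_tibble(raw)
  need <- c("sex", "age", "tumor_size", "bethesda")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing clinical columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  bad_age <- which(!is.finite(raw$age) | raw$age <= 0)
  if (length(bad_age) > 0) {
    abort(sprintf("non-positive or non-finite age in rows: %s",
                  paste(head(bad_age, 5), collapse = ", ")))
  }
  bad_size <- which(!is.finite(raw$tumor_size) | raw$tumor_size <= 0)
  if (length(bad_size) > 0) {
    abort(sprintf("non-positive or non-finite tumor_size in rows: %s",
                  paste(head(bad_size, 5), collapse = ", ")))
  }

  age_band <- cut(raw$age, breaks = c(0, 20, 45, 60, Inf),
                  labels = AGE_BANDS, right = TRUE)
  size_band <- cut(raw$tumor_size, breaks = c(0, 0.5, 1, 1.5, 2.5, 4, Inf),
                   labels = SIZE_BANDS, right = TRUE)

  out <- tibble::tibble(
    sex = factor(as.character(raw$sex), levels = c("F", "M")),
    age_band = age_band,
    size_band = size_band,
    bethesda = factor(as.character(raw$bethesda), levels = BETHESDA_LEVELS)
  )
  if ("sample_id" %in% names(raw)) {
    out <- dplyr::bind_cols(tibble::tibble(sample_id = raw$sample_id), out)
  }
  if ("label" %in% names(raw)) out$label <- as_label_factor(raw$label)
  out
}
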