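# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Deterministic stream of sub-seeds derived from a master seed; keeps every
# derived seed inside the 32-bit integer range.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) h <- (h * 69069 + as.double(p) + 1) %% 2147483563
  as.integer(h) + 1L
}

assert_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", field))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` = %g is outside its valid range %s%g, %g%s.", field, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ))
  }
  invisible(x)
}

assert_count <- function(x, field, lower = 1L) {
  assert_scalar_number(x, field, lower = lower)
  if (x != as.integer(x)) abort(sprintf("`%s` must be a whole number.", field))
  invisible(as.integer(x))
}

# Coerce a label vector (factor/character/logical/0-1) to a factor with
# levels c("benign", "malignant"); errors if not binary.
as_label_factor <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) labels <- ifelse(labels, "malignant", "benign")
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) abort("numeric labels must be 0/1.")
    labels <- ifelse(labels == 1, "malignant", "benign")
  }
  bad <- setdiff(unique(labels), c("benign", "malignant"))
  if (length(bad) > 0) {
    abort(sprintf("labels must be 'benign'/'malignant'; saw: %s",
                  paste(bad, collapse = ", ")))
  }
  factor(labels, levels = c("benign", "malignant"))
}

# Matrix view of a samples-by-features table: drops a sample_id column if
# present, keeps everything numeric.
as_feature_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  x <- as.data.frame(x)
  if ("sample_id" %in% names(x)) {
    rn <- x$sample_id
    x$sample_id <- NULL
  } else {
    rn <- NULL
  }
  m <- as.matrix(x)
  if (!is.numeric(m)) abort("feature table must be numeric apart from `sample_id`.")
  if (!is.null(rn)) rownames(m) <- rn
  m
}
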