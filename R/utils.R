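# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr under a fixed RNG seed without disturbing the caller's RNG
# state; when seed is NULL the current stream is used as-is.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Derive n child seeds from one master seed (kept within 32-bit range so
# they are valid set.seed() inputs).
derive_seeds <- function(seed, n) {
  with_seed_or_not(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Canonical class factor; labels outside `levels` raise an error.
as_class_factor <- function(labels, levels = NULL) {
  if (is.factor(labels)) {
    if (!is.null(levels)) labels <- factor(as.character(labels), levels = levels)
    return(labels)
  }
  levels <- levels %||% (if (all(labels %in% BONN_CLASSES)) BONN_CLASSES else sort(unique(labels)))
  bad <- setdiff(unique(labels), levels)
  if (length(bad) > 0L) {
    stop("unknown class label(s): ", paste(bad, collapse = ", "))
  }
  factor(labels, levels = levels)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(name, " must be a single positive number")
  }
}
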