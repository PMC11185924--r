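# Internal validators and small helpers shared across modules.

assert_expression_matrix <- function(x, arg = "expr") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix (genes x samples).", arg))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort(sprintf("`%s` must carry gene ids as rownames and sample ids as colnames.", arg))
  }
  if (anyDuplicated(rownames(x))) {
    abort(sprintf("`%s` has duplicated gene ids; collapse duplicates first (read_expression() does this).", arg))
  }
  if (anyDuplicated(colnames(x))) {
    abort(sprintf("`%s` has duplicated sample ids.", arg))
  }
  invisible(x)
}

assert_response_matrix <- function(x, arg = "response") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix (drugs x cell lines).", arg))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort(sprintf("`%s` must carry drug ids as rownames and cell-line ids as colnames.", arg))
  }
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x))) {
    abort(sprintf("`%s` has duplicated drug or cell-line ids.", arg))
  }
  if (any(x[is.finite(x)] < 0)) {
    abort(sprintf("`%s` contains negative AUC values; AUCs are non-negative.", arg))
  }
  invisible(x)
}

# Seed guard: set the RNG state only when the caller supplied a seed, so
# unseeded calls keep consuming the session RNG stream.
maybe_set_seed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      abort("`seed` must be a single finite number.")
    }
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# FNV-1a 32-bit hash of a character scalar, returned as 8 hex digits.
# Used only to stamp a short config fingerprint into provenance headers.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte only touches the low 8 bits; keep h a double (> 2^31)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply by the FNV prime 16777619 via 16-bit split,
    # so intermediates stay below 2^53
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- ((hi * 16777619) %% 65536 * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- rlang::`%||%`
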