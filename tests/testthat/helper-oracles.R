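# Independent oracles, coded from the textbook definitions and kept separate
# from the package's implementation paths.

# Pairwise-complete Pearson correlation, plain-sum formula.
oracle_pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  if (den == 0) return(NA_real_)
  num / den
}

# Step-by-step running-sum enrichment score: walk every position, track the
# whole path, return the signed maximum deviation (positive branch on ties).
oracle_es <- function(ranked, set, weight = 0, metric = NULL) {
  n <- length(ranked)
  hit <- ranked %in% set
  w <- if (weight == 0) rep(1, n) else abs(metric)^weight
  n_hit <- sum(hit)
  s_hit <- sum(w[hit])
  path <- numeric(n)
  run <- 0
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) w[i] / s_hit else -1 / (n - n_hit)
    path[i] <- run
  }
  # positive branch on near-ties, matching the implementation convention
  if (max(path) >= -min(path) - 1e-12) max(path) else min(path)
}

# Spearman footrule objective over the union of candidate and input top-k,
# absent items at position k + 1; double loop, no vectorization tricks.
oracle_footrule <- function(candidate, input_lists, k = length(candidate)) {
  total <- 0
  for (lst in input_lists) {
    top <- lst[seq_len(min(k, length(lst)))]
    union_items <- unique(c(candidate, top))
    d <- 0
    for (it in union_items) {
      pc <- which(candidate == it)
      if (length(pc) == 0L) pc <- k + 1L
      pl <- which(top == it)
      if (length(pl) == 0L) pl <- k + 1L
      d <- d + abs(pc - pl)
    }
    total <- total + d
  }
  total / length(input_lists)
}

# R replica of the permutation-null shuffle (partial Fisher-Yates over a
# persistent pool + cyclic derangement of the selected labels), consuming the
# RNG stream exactly like the compiled kernel so outputs can be compared
# one-to-one.
oracle_null_es <- function(ranked, set, n_perm, n_shuffle, weight = 0, metric = NULL) {
  n <- length(ranked)
  pool <- seq_len(n)
  out <- numeric(n_perm)
  w <- if (weight == 0) rep(1, n) else abs(metric)^weight
  for (t in seq_len(n_perm)) {
    for (i in seq_len(n_shuffle)) {
      # 0-based kernel: j0 = i0 + floor(u * (n - i0)); translate to 1-based
      j <- i + floor(runif(1) * (n - i + 1L))
      if (j > n) j <- n
      tmp <- pool[i]; pool[i] <- pool[j]; pool[j] <- tmp
    }
    sel <- pool[seq_len(n_shuffle)]
    lab <- ranked
    if (n_shuffle > 1L) {
      lab[sel] <- ranked[sel][c(n_shuffle, seq_len(n_shuffle - 1L))]
    }
    hit <- lab %in% set
    s_hit <- sum(w[hit])
    n_hit <- sum(hit)
    run <- 0
    best_max <- -Inf
    best_min <- Inf
    for (i in seq_len(n)) {
      run <- run + if (hit[i]) w[i] / s_hit else -1 / (n - n_hit)
      if (run > best_max) best_max <- run
      if (run < best_min) best_min <- run
    }
    out[t] <- if (best_max >= -best_min - 1e-12) best_max else best_min
  }
  out
}

# Small deterministic expression fixture: genes x samples with dimnames.
make_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples),
         nrow = n_genes,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}
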