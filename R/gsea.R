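# Directional GSEA primitives: profile ranking, running-sum enrichment score,
# partial-label-shuffle permutation nulls and empirical p-values.

#' Rank a tumor expression profile
#'
#' Orders genes from most to least expressed, restricted to a gene universe.
#' Ties are broken by a stable sort on gene id; genes with missing expression
#' are dropped with a warning.
#'
#' @param values Named numeric vector of expression values (names = gene ids),
#'   or a one-column matrix with rownames.
#' @param universe Character vector of allowed gene ids (e.g. a library's
#'   `gene_universe`); genes outside it are dropped. `NULL` keeps all genes.
#' @param sample_id Identifier stored on the result.
#' @param min_overlap Minimum number of usable genes (default 2).
#' @return A `ranked_profile`: tibble with columns `gene`, `value` sorted by
#'   decreasing expression, attribute `sample_id`.
#' @export
rank_profile <- function(values, universe = NULL, sample_id = "sample",
                         min_overlap = 2L) {
  if (is.matrix(values)) {
    stopifnot(ncol(values) == 1L)
    values <- setNames(values[, 1L], rownames(values))
  }
  if (is.null(names(values))) abort("`values` must be named by gene id.")
  if (anyNA(values)) {
    warn(sprintf("Dropping %d gene(s) with missing expression.", sum(is.na(values))))
    values <- values[!is.na(values)]
  }
  if (!is.null(universe)) values <- values[names(values) %in% universe]
  if (length(values) < min_overlap) {
    abort(sprintf("Profile '%s' shares only %d gene(s) with the universe (need >= %d).",
                  sample_id, length(values), min_overlap))
  }
  if (length(unique(values)) == 1L) {
    warn(sprintf("Profile '%s' has constant expression; ranking is lexicographic on gene id.",
                 sample_id))
  }
  ord <- order(-values, names(values), method = "radix")
  out <- tibble::tibble(gene = names(values)[ord], value = unname(values)[ord])
  attr(out, "sample_id") <- sample_id
  class(out) <- c("ranked_profile", class(out))
  out
}

#' Running-sum enrichment score
#'
#' Kolmogorov-Smirnov-style GSEA statistic: walking down the ranked list,
#' genes in the set increment the running sum by \eqn{|r_i|^w / \sum |r_j|^w}
#' over hits (with `weight = 0` this is `1/n_hits`, the classic statistic) and
#' misses decrement by `1/(N - n_hits)`. The ES is the signed maximum
#' deviation from zero and lies in `[-1, 1]`: `+1` when the set occupies
#' exactly the top of the list, `-1` when it occupies the bottom.
#'
#' @param ranked_genes Character vector, the ranked list (best first).
#' @param gene_set Character vector of set members; must intersect the list
#'   and must not cover it entirely.
#' @param weight Exponent on the ranking metric for hit increments
#'   (default 0, classic unweighted statistic).
#' @param metric Numeric vector aligned with `ranked_genes`; required when
#'   `weight > 0`.
#' @return A single enrichment score.
#' @export
enrichment_score <- function(ranked_genes, gene_set, weight = 0, metric = NULL) {
  n <- length(ranked_genes)
  hits <- which(ranked_genes %in% gene_set)
  if (length(hits) == 0L) abort("The gene set does not intersect the ranked list.")
  if (length(hits) == n) abort("The gene set covers the whole ranked list; no misses to walk.")
  w <- if (weight == 0) {
    rep(1, length(hits))
  } else {
    if (is.null(metric) || length(metric) != n) {
      abort("`metric` aligned with `ranked_genes` is required when weight > 0.")
    }
    abs(metric[hits])^weight
  }
  if (sum(w) <= 0) abort("All hit weights are zero; the weighted ES is undefined.")
  .cpp_es(as.integer(hits), as.double(w), as.integer(n))
}

#' Permutation null distribution of enrichment scores
#'
#' For each permutation, a uniformly random subset of
#' `ceiling(shuffle_fraction * N)` positions of the ranking is chosen and the
#' gene labels at those positions are cyclically deranged in a random order
#' (so every selected label actually moves); the ranking values stay attached
#' to positions. The ES of `gene_set` is recomputed on each shuffled ranking.
#' Deterministic given the RNG state (use [set.seed()] or `seed`).
#'
#' @param profile A `ranked_profile` (or any tibble with `gene` and `value`
#'   columns in ranked order).
#' @param gene_set Character vector of set members.
#' @param n_perm Number of permutations (default 10000).
#' @param shuffle_fraction Fraction of gene labels shuffled per permutation,
#'   in (0, 1] (default 0.25).
#' @param weight,seed See [enrichment_score()]; `seed` is optional.
#' @return Numeric vector of `n_perm` null enrichment scores.
#' @export
null_es_distribution <- function(profile, gene_set, n_perm = 10000L,
                                 shuffle_fraction = 0.25, weight = 0,
                                 seed = NULL) {
  stopifnot(is.data.frame(profile), all(c("gene", "value") %in% names(profile)))
  if (!(shuffle_fraction > 0 && shuffle_fraction <= 1)) {
    abort("`shuffle_fraction` must be in (0, 1].")
  }
  if (n_perm < 1L) abort("`n_perm` must be >= 1.")
  maybe_set_seed(seed)
  genes <- profile$gene
  n <- length(genes)
  membership <- matrix(genes %in% gene_set, ncol = 1L)
  # membership is indexed by gene code; here codes are list positions
  labels <- seq_len(n) - 1L
  pos_w <- if (weight == 0) rep(1, n) else abs(profile$value)^weight
  .cpp_gsea_null(labels, membership, pos_w,
                 as.integer(n_perm), as.integer(ceiling(shuffle_fraction * n)))[, 1L]
}

#' Empirical permutation p-value
#'
#' `p = (1 + #null at least as extreme) / (1 + n_perm)`, one-sided; the
#' add-one floor keeps p strictly positive (minimum `1/(n_perm + 1)`).
#'
#' @param es_observed Observed enrichment score.
#' @param null Numeric vector of null scores.
#' @param direction `"greater"` (extreme = `>= es_observed`) or `"less"`.
#' @return A p-value in `(0, 1]`.
#' @export
empirical_p <- function(es_observed, null, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  if (length(null) == 0L) abort("`null` must be non-empty.")
  extreme <- if (direction == "greater") sum(null >= es_observed) else sum(null <= es_observed)
  (1 + extreme) / (1 + length(null))
}
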