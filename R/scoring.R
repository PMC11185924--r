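# Scoring: four directional GSEA tests per (sample, drug), empirical
# permutation p-values, G-score combination and per-sample drug ranking.
#
# The four tests ask, for a drug's DGCP and a tumor profile:
#   (1) do the tumor's most expressed genes sit at the DGCP bottom
#       (sensitivity end)?        ranking = DGCP, ES -> -1, direction "less"
#   (2) do the tumor's least expressed genes sit at the DGCP top
#       (resistance end)?         ranking = DGCP, direction "greater"
#   (3) are the DGCP's sensitivity biomarkers up-regulated in the tumor?
#                                 ranking = tumor, direction "greater"
#   (4) are the DGCP's resistance biomarkers down-regulated in the tumor?
#                                 ranking = tumor, direction "less"
# Tests 1-2 share the DGCP ranking and tests 3-4 the tumor ranking, so each
# permutation shuffles each ranking once and scores both sets on it; the two
# joint ensembles also provide the empirical covariance for Brown's method.

#' Scoring parameters
#'
#' @param set_size Biomarker / expression-extreme set size (default 250).
#' @param n_perm Permutations per null distribution (default 10000).
#' @param shuffle_fraction Fraction of gene labels shuffled per permutation
#'   (default 0.25).
#' @param es_weight Exponent for ES hit increments (default 0, classic
#'   unweighted statistic).
#' @param combine_method `"geometric_mean"` (drug ranking by G-score, the
#'   default) or `"brown"` (ranking by Brown's combined p). Both combined
#'   values are always reported.
#' @param seed Optional integer seed; when set, scoring is bit-reproducible.
#' @return A list of validated parameters, class `scoring_params`.
#' @export
scoring_params <- function(set_size = 250L, n_perm = 10000L,
                           shuffle_fraction = 0.25, es_weight = 0,
                           combine_method = c("geometric_mean", "brown"),
                           seed = NULL) {
  combine_method <- match.arg(combine_method)
  if (set_size < 1L) abort("`set_size` must be >= 1.")
  if (n_perm < 1L) abort("`n_perm` must be >= 1.")
  if (!(shuffle_fraction > 0 && shuffle_fraction <= 1)) {
    abort("`shuffle_fraction` must be in (0, 1].")
  }
  structure(list(set_size = as.integer(set_size), n_perm = as.integer(n_perm),
                 shuffle_fraction = shuffle_fraction, es_weight = es_weight,
                 combine_method = combine_method, seed = seed),
            class = "scoring_params")
}

#' Geometric-mean combination of the four test p-values (G-score)
#'
#' `g = (p1 p2 p3 p4)^(1/4)`; the smaller the G-score, the more the tumor's
#' expression extremes agree with the drug's sensitivity biomarkers, i.e. the
#' more sensitive the tumor is predicted to be.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return The geometric mean.
#' @export
combine_g_score <- function(p) {
  if (any(p <= 0 | p > 1 | !is.finite(p))) {
    abort("All p-values must lie in (0, 1] (the empirical floor rules out 0).")
  }
  exp(mean(log(p)))
}

#' Brown's method for combining dependent p-values
#'
#' Extension of Fisher's method: `X = -2 sum(log p)` is referred to a scaled
#' chi-square with scale `c = var(X) / (2 E[X])` and `df = 2 E[X]^2 / var(X)`,
#' where `E[X] = 2k` and `var(X) = 4k + 2 sum_{i<j} cov_ij` for `k` tests.
#' The covariance of the `-2 log p` statistics is estimated from the shared
#' permutation ensemble (see [four_way_gsea()]). With zero covariance this is
#' exactly Fisher's method; with perfectly dependent tests
#' (`cov_ij = 4`) it collapses to the single-test p-value. A degenerate
#' covariance falls back to Fisher with a warning.
#'
#' @param p Numeric vector of k p-values in (0, 1].
#' @param covariance k x k covariance matrix of the `-2 log p` statistics;
#'   `NULL` means independence (Fisher).
#' @return The combined p-value.
#' @export
combine_brown <- function(p, covariance = NULL) {
  if (any(p <= 0 | p > 1 | !is.finite(p))) abort("All p-values must lie in (0, 1].")
  k <- length(p)
  X <- -2 * sum(log(p))
  if (is.null(covariance)) covariance <- matrix(0, k, k)
  if (!is.matrix(covariance) || !all(dim(covariance) == k) ||
      max(abs(covariance - t(covariance))) > 1e-8) {
    abort("`covariance` must be a symmetric k x k matrix.")
  }
  e_x <- 2 * k
  var_x <- 4 * k + 2 * sum(covariance[upper.tri(covariance)])
  if (!is.finite(var_x) || var_x <= 0) {
    warn("Degenerate covariance; falling back to Fisher's method (independence).")
    var_x <- 4 * k
  }
  scale_c <- var_x / (2 * e_x)
  df <- 2 * e_x^2 / var_x
  stats::pchisq(X / scale_c, df = df, lower.tail = FALSE)
}

# Rank-transform a null ES column to uniform (0,1) p-values in the stated
# direction, for the Brown covariance estimate.
null_to_p <- function(null, direction) {
  r <- rank(null, ties.method = "average")
  n <- length(null)
  if (direction == "greater") (n + 1 - r) / (n + 1) else r / (n + 1)
}

#' Four directional GSEA tests for one (sample, drug) pair
#'
#' Runs the four tests described in the package overview, each with its own
#' one-sided empirical permutation p-value, and estimates the covariance of
#' the `-2 log p` statistics from the joint permutation ensembles for
#' [combine_brown()].
#'
#' @param profile A `ranked_profile` (see [rank_profile()]), already
#'   restricted to genes shared with the DGCP (extra genes are dropped here).
#' @param dgcp A `dgcp`.
#' @param params A [scoring_params()] list. The caller controls the RNG state
#'   (`params$seed` is consumed by [score_sample()], not here).
#' @return A list with `p` (named length-4 vector), `es` (named length-4
#'   vector of observed scores), and `brown_cov` (4 x 4 matrix).
#' @export
four_way_gsea <- function(profile, dgcp, params = scoring_params()) {
  stopifnot(inherits(dgcp, "dgcp"), is.data.frame(profile))
  common <- intersect(profile$gene, dgcp$gene)
  n <- length(common)
  if (n < 2L * params$set_size) {
    abort(sprintf("Profile and DGCP share %d gene(s); need >= %d for set_size %d.",
                  n, 2L * params$set_size, params$set_size))
  }
  code <- setNames(seq_len(n), common)

  keep_e <- profile$gene %in% common
  expr_genes <- profile$gene[keep_e]     # tumor ranking, most expressed first
  expr_vals <- profile$value[keep_e]
  keep_d <- dgcp$gene %in% common
  dgcp_genes <- dgcp$gene[keep_d]        # DGCP ranking, descending PCC
  dgcp_vals <- dgcp$pcc[keep_d]

  s <- params$set_size
  set_top_expr <- expr_genes[seq_len(s)]             # most expressed in tumor
  set_bottom_expr <- expr_genes[seq.int(n - s + 1L, n)]
  set_res <- dgcp_genes[seq_len(s)]                  # DGCP top: resistance
  set_sens <- dgcp_genes[seq.int(n - s + 1L, n)]     # DGCP bottom: sensitivity

  w <- params$es_weight
  w_dgcp <- if (w == 0) rep(1, n) else abs(dgcp_vals)^w
  w_expr <- if (w == 0) rep(1, n) else abs(expr_vals)^w

  membership <- function(sets) {
    m <- matrix(FALSE, n, length(sets))
    for (j in seq_along(sets)) m[code[sets[[j]]], j] <- TRUE
    m
  }
  mem_expr_sets <- membership(list(set_top_expr, set_bottom_expr))
  mem_dgcp_sets <- membership(list(set_sens, set_res))

  es_obs <- function(ranked, set, wpos) {
    hits <- which(ranked %in% set)
    .cpp_es(as.integer(hits), wpos[hits], n)
  }
  es <- c(
    top_expr_vs_sensitivity = es_obs(dgcp_genes, set_top_expr, w_dgcp),
    bottom_expr_vs_resistance = es_obs(dgcp_genes, set_bottom_expr, w_dgcp),
    sens_biomarkers_up = es_obs(expr_genes, set_sens, w_expr),
    res_biomarkers_down = es_obs(expr_genes, set_res, w_expr))

  n_shuffle <- as.integer(ceiling(params$shuffle_fraction * n))
  null_dgcp <- .cpp_gsea_null(code[dgcp_genes] - 1L, mem_expr_sets, w_dgcp,
                              params$n_perm, n_shuffle)
  null_expr <- .cpp_gsea_null(code[expr_genes] - 1L, mem_dgcp_sets, w_expr,
                              params$n_perm, n_shuffle)

  directions <- c("less", "greater", "greater", "less")
  nulls <- cbind(null_dgcp, null_expr)   # columns: tests 1, 2, 3, 4
  p <- vapply(1:4, function(i) empirical_p(es[[i]], nulls[, i], directions[[i]]),
              numeric(1))
  names(p) <- names(es)

  y <- vapply(1:4, function(i) -2 * log(null_to_p(nulls[, i], directions[[i]])),
              numeric(params$n_perm))
  brown_cov <- if (params$n_perm >= 2L) stats::cov(y) else matrix(0, 4, 4)

  list(p = p, es = es, brown_cov = brown_cov)
}

#' Score one tumor profile against every drug in a library
#'
#' Ranks the tumor profile, runs [four_way_gsea()] against each DGCP, combines
#' the four p-values into the G-score (and Brown's p), and ranks drugs in
#' ascending order of the combined value (ties broken by drug id). Smaller
#' G-score = predicted more sensitive.
#'
#' @param values Named numeric expression vector for one sample (or one-column
#'   matrix with rownames).
#' @param library A `dgcp_library`.
#' @param params A [scoring_params()] list; `params$seed` (when non-NULL)
#'   resets the RNG at entry so identical inputs give identical output.
#' @param sample_id Identifier for the output rows.
#' @return A tibble with one row per drug: `sample_id`, `drug_id`,
#'   `p_top_expr_vs_sensitivity`, `p_bottom_expr_vs_resistance`,
#'   `p_sens_biomarkers_up`, `p_res_biomarkers_down`, `g_score`, `brown_p`,
#'   `rank` (1-based permutation of the drugs).
#' @export
score_sample <- function(values, library, params = scoring_params(),
                         sample_id = "sample") {
  stopifnot(inherits(library, "dgcp_library"))
  maybe_set_seed(params$seed)
  profile <- rank_profile(values, universe = library$gene_universe,
                          sample_id = sample_id)
  if (nrow(profile) < 2L * params$set_size) {
    abort(sprintf("Sample '%s' shares only %d gene(s) with the library universe; need >= %d.",
                  sample_id, nrow(profile), 2L * params$set_size))
  }
  rows <- purrr::map_dfr(names(library$dgcps), function(d) {
    res <- four_way_gsea(profile, library$dgcps[[d]], params)
    tibble::tibble(
      sample_id = sample_id, drug_id = d,
      p_top_expr_vs_sensitivity = res$p[[1L]],
      p_bottom_expr_vs_resistance = res$p[[2L]],
      p_sens_biomarkers_up = res$p[[3L]],
      p_res_biomarkers_down = res$p[[4L]],
      g_score = combine_g_score(res$p),
      brown_p = combine_brown(res$p, res$brown_cov))
  })
  key <- if (params$combine_method == "brown") rows$brown_p else rows$g_score
  rows$rank <- as.integer(order(order(key, rows$drug_id, method = "radix")))
  dplyr::arrange(rows, .data$rank)
}

#' Score a cohort of tumor profiles
#'
#' Applies [score_sample()] to each column of a genes x samples matrix. The
#' same `params$seed` is used for every sample, so samples with identical
#' expression receive identical drug rankings.
#'
#' @param expr Numeric genes x samples matrix.
#' @param library A `dgcp_library`.
#' @param params A [scoring_params()] list.
#' @return A tibble of per-(sample, drug) scores (see [score_sample()]).
#' @export
score_cohort <- function(expr, library, params = scoring_params()) {
  assert_expression_matrix(expr, "expr")
  purrr::map_dfr(colnames(expr), function(s) {
    score_sample(expr[, s], library, params = params, sample_id = s)
  })
}

#' Shuffle the gene labels of a DGCP library (negative control)
#'
#' Applies one global random permutation to the library's gene identifiers,
#' destroying every drug-gene association while preserving the PCC profiles.
#' Scoring tumors against the shuffled library measures the no-signal
#' baseline (normalized PPV should hover around 1).
#'
#' @param library A `dgcp_library`.
#' @param seed Optional seed for the permutation.
#' @return A `dgcp_library` with permuted gene labels and a lineage label
#'   suffixed with `" (label-shuffled)"`.
#' @export
shuffle_gene_labels <- function(library, seed = NULL) {
  stopifnot(inherits(library, "dgcp_library"))
  maybe_set_seed(seed)
  relabel <- setNames(sample(library$gene_universe), library$gene_universe)
  dgcps <- lapply(library$dgcps, function(d) {
    new_dgcp(attr(d, "drug_id"), unname(relabel[d$gene]), d$pcc,
             n_cell_lines = attr(d, "n_cell_lines"))
  })
  new_dgcp_library(
    lineage = paste0(library$lineage, " (label-shuffled)"),
    dgcps = dgcps, gene_universe = library$gene_universe,
    provenance = c(library$provenance, list(label_shuffled = TRUE)))
}
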