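# Training: drug-gene correlation profiles (DGCPs) and biomarker diagnostics.
#
# A DGCP ranks every gene by the Pearson correlation (PCC) between its
# expression and a drug's AUC across cell lines, in descending order: genes at
# the top are positively correlated with AUC (resistance biomarkers, more
# expression = more drug needed), genes at the bottom are negatively
# correlated (sensitivity biomarkers).

new_dgcp <- function(drug_id, genes, pcc, n_cell_lines) {
  out <- tibble::tibble(gene = as.character(genes), pcc = as.double(pcc))
  attr(out, "drug_id") <- drug_id
  attr(out, "n_cell_lines") <- as.integer(n_cell_lines)
  class(out) <- c("dgcp", class(out))
  out
}

new_dgcp_library <- function(lineage, dgcps, gene_universe, provenance) {
  structure(
    list(lineage = lineage, dgcps = dgcps,
         gene_universe = as.character(gene_universe),
         provenance = provenance),
    class = "dgcp_library")
}

#' Compute one drug-gene correlation profile
#'
#' For every gene, computes the Pearson correlation between its expression and
#' the drug's AUC across cell lines, using pairwise-complete observations, and
#' returns genes ranked by PCC in descending order (ties broken by gene id,
#' so results are deterministic). Genes with fewer than `min_pairs` complete
#' pairs or zero variance over the complete pairs are dropped with a message.
#'
#' @param expr Numeric genes x cell-lines matrix (dimnames required).
#' @param auc Named numeric vector of AUCs; names are cell-line ids and must
#'   overlap `colnames(expr)`.
#' @param min_pairs Minimum number of complete (expression, AUC) pairs a gene
#'   needs to be retained. Default 10.
#' @param drug_id Identifier stored on the result.
#' @return A `dgcp`: a tibble with columns `gene` and `pcc` (non-increasing),
#'   and attributes `drug_id` and `n_cell_lines`.
#' @export
compute_dgcp <- function(expr, auc, min_pairs = 10L, drug_id = "drug") {
  assert_expression_matrix(expr, "expr")
  if (is.null(names(auc))) abort("`auc` must be a named vector of per-cell-line AUCs.")
  shared <- intersect(colnames(expr), names(auc))
  auc <- auc[shared]
  keep_cl <- is.finite(auc)
  shared <- shared[keep_cl]
  if (length(shared) < min_pairs) {
    warn(sprintf("Drug '%s' skipped: only %d cell line(s) with both expression and finite AUC (min_pairs = %d).",
                 drug_id, length(shared), min_pairs))
    return(NULL)
  }
  x <- expr[, shared, drop = FALSE]
  a <- as.double(auc[shared])
  # pairwise-complete Pearson: one vectorized call against the AUC vector
  pcc <- suppressWarnings(stats::cor(t(x), a, use = "pairwise.complete.obs"))[, 1L]
  n_complete <- as.integer((!is.na(x)) %*% matrix(1, length(a)))
  drop <- !is.finite(pcc) | n_complete < min_pairs
  if (any(drop)) {
    inform(sprintf("Drug '%s': dropped %d gene(s) with < %d complete pairs or zero variance.",
                   drug_id, sum(drop), min_pairs))
  }
  genes <- rownames(x)[!drop]
  pcc <- pcc[!drop]
  ord <- order(-pcc, genes, method = "radix")
  new_dgcp(drug_id, genes[ord], pcc[ord], n_cell_lines = length(shared))
}

#' Train a DGCP library on a cell-line panel
#'
#' Builds one DGCP per drug in `response` against the expression panel.
#' Lineage splitting (e.g. solid vs liquid tumors) is the caller's
#' responsibility: pass the lineage-restricted cell-line subset and record the
#' label in `lineage`. The library's gene universe is the set of genes
#' retained in every per-drug DGCP; each DGCP is restricted to that universe
#' (order preserved).
#'
#' @param expr Numeric genes x cell-lines matrix.
#' @param response Numeric drugs x cell-lines AUC matrix.
#' @param lineage Free-text lineage label stored on the library (e.g.
#'   `"solid"`).
#' @param min_pairs Per-gene and per-drug minimum number of complete pairs
#'   (default 10); drugs measured in fewer cell lines are skipped with a
#'   warning.
#' @return A `dgcp_library`: lineage, named list of `dgcp`s, `gene_universe`,
#'   and a provenance record of the training parameters.
#' @seealso [tidy.dgcp_library()], [write_dgcp_library()]
#' @export
build_library <- function(expr, response, lineage = "unspecified", min_pairs = 10L) {
  assert_expression_matrix(expr, "expr")
  assert_response_matrix(response, "response")
  shared <- intersect(colnames(expr), colnames(response))
  if (length(shared) == 0L) {
    abort(sprintf("No shared cell-line ids between expression (%d ids) and response (%d ids).",
                  ncol(expr), ncol(response)))
  }
  if (length(shared) < min_pairs) {
    abort(sprintf("Only %d shared cell line(s); min_pairs = %d.", length(shared), min_pairs))
  }
  expr <- expr[, shared, drop = FALSE]
  dgcps <- list()
  for (d in rownames(response)) {
    dg <- compute_dgcp(expr, response[d, shared], min_pairs = min_pairs, drug_id = d)
    if (!is.null(dg)) dgcps[[d]] <- dg
  }
  if (length(dgcps) == 0L) abort("No drug passed training; library would be empty.")
  universe <- Reduce(intersect, lapply(dgcps, function(d) d$gene))
  if (length(universe) == 0L) abort("Gene universe is empty after intersecting per-drug DGCPs.")
  dgcps <- lapply(dgcps, function(d) {
    keep <- d$gene %in% universe
    new_dgcp(attr(d, "drug_id"), d$gene[keep], d$pcc[keep],
             n_cell_lines = attr(d, "n_cell_lines"))
  })
  new_dgcp_library(
    lineage = lineage, dgcps = dgcps, gene_universe = universe,
    provenance = list(n_cell_lines = length(shared),
                      n_drugs_in = nrow(response),
                      n_drugs_retained = length(dgcps),
                      min_pairs = as.integer(min_pairs)))
}

#' Extract biomarker sets from a DGCP
#'
#' Resistance biomarkers are the first `size` genes of the DGCP (largest PCC);
#' sensitivity biomarkers are the last `size` genes (most negative PCC),
#' returned most-negative first. If `size` exceeds the available genes it is
#' clamped with a warning.
#'
#' @param dgcp A `dgcp` from [compute_dgcp()].
#' @param direction `"sensitivity"` or `"resistance"`.
#' @param size Number of genes (default 250).
#' @return A character vector of gene ids with attributes `drug_id`,
#'   `direction` and `size`.
#' @export
extract_biomarkers <- function(dgcp, direction = c("sensitivity", "resistance"),
                               size = 250L) {
  direction <- match.arg(direction)
  stopifnot(inherits(dgcp, "dgcp"), size >= 1L)
  n <- nrow(dgcp)
  if (size > n) {
    warn(sprintf("Requested %d biomarkers but the DGCP holds %d genes; clamping.", size, n))
    size <- n
  }
  if (2L * size > n) {
    warn(sprintf("Biomarker sets of size %d overlap in a DGCP of %d genes; the sensitivity/resistance partition is not disjoint.",
                 size, n))
  }
  genes <- if (direction == "resistance") {
    dgcp$gene[seq_len(size)]
  } else {
    rev(dgcp$gene)[seq_len(size)]
  }
  structure(genes, drug_id = attr(dgcp, "drug_id"),
            direction = direction, size = as.integer(size))
}

#' Target-pathway anticorrelation diagnostic
#'
#' Tests whether genes in the drug target's pathway sit lower in the DGCP
#' (more negative PCC, i.e. anticorrelated with AUC) than background genes,
#' with a one-sided Mann-Whitney U test (alternative: target-pathway PCCs are
#' smaller).
#'
#' @param dgcp A `dgcp`.
#' @param target_pathway_genes,background_genes Character vectors; both are
#'   intersected with the DGCP genes and must remain non-empty. The lists are
#'   used as given (overlapping genes appear in both groups).
#' @return A one-row tibble: `statistic` (U), `p_value`, `n_target`,
#'   `n_background`, `direction_tested`.
#' @export
pathway_anticorrelation_check <- function(dgcp, target_pathway_genes, background_genes) {
  stopifnot(inherits(dgcp, "dgcp"))
  target <- intersect(target_pathway_genes, dgcp$gene)
  background <- intersect(background_genes, dgcp$gene)
  if (length(target) == 0L || length(background) == 0L) {
    abort("Target or background gene list is empty after intersection with the DGCP.")
  }
  pcc <- setNames(dgcp$pcc, dgcp$gene)
  ht <- suppressWarnings(
    stats::wilcox.test(pcc[target], pcc[background], alternative = "less"))
  tibble::tibble(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    n_target = length(target),
    n_background = length(background),
    direction_tested = "target-pathway PCCs smaller than background")
}

#' Over-representation of a gene list in gene sets
#'
#' One-sided hypergeometric test of the overlap between a query gene list and
#' each gene set, against a gene universe, with Benjamini-Hochberg adjustment
#' across the tested sets. This is the classical ORA used, e.g., to ask which
#' ontology terms are enriched among shared sensitivity biomarkers of two
#' drugs.
#'
#' @param genes Query gene list (intersected with `universe`).
#' @param sets Named list of gene sets (see [read_gmt()]).
#' @param universe Character vector of background genes.
#' @param q_threshold Significance cutoff on the BH-adjusted q-value
#'   (default 0.05).
#' @return A tibble with one row per set: `set`, `set_size` (within the
#'   universe), `overlap`, `p_value`, `q_value`, `significant`, sorted by
#'   p-value.
#' @export
biomarker_overlap_enrichment <- function(genes, sets, universe, q_threshold = 0.05) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) abort("`universe` is empty.")
  genes <- intersect(unique(as.character(genes)), universe)
  n_query <- length(genes)
  rows <- purrr::map_dfr(names(sets), function(s) {
    set_u <- intersect(unique(sets[[s]]), universe)
    k <- length(intersect(set_u, genes))
    # P(overlap >= k) drawing n_query genes from the universe
    p <- stats::phyper(k - 1L, length(set_u), length(universe) - length(set_u),
                       n_query, lower.tail = FALSE)
    tibble::tibble(set = s, set_size = length(set_u), overlap = k, p_value = p)
  })
  rows$q_value <- stats::p.adjust(rows$p_value, method = "BH")
  rows$significant <- rows$q_value < q_threshold
  dplyr::arrange(rows, .data$p_value, .data$set)
}

#' @export
print.dgcp_library <- function(x, ...) {
  cat(sprintf("<dgcp_library> lineage '%s': %d drugs x %d genes (trained on %s cell lines)\n",
              x$lineage, length(x$dgcps), length(x$gene_universe),
              as.character(x$provenance$n_cell_lines %||% "?")))
  invisible(x)
}

#' Tidy a DGCP library into a long tibble
#'
#' @param x A `dgcp_library`.
#' @param ... Unused.
#' @return A tibble with columns `drug_id`, `rank`, `gene`, `pcc`.
#' @export
tidy.dgcp_library <- function(x, ...) {
  purrr::map_dfr(x$dgcps, function(d) {
    tibble::tibble(drug_id = attr(d, "drug_id"),
                   rank = seq_len(nrow(d)), gene = d$gene, pcc = d$pcc)
  })
}

#' One-row summary of a DGCP library
#'
#' @param x A `dgcp_library`.
#' @param ... Unused.
#' @export
glance.dgcp_library <- function(x, ...) {
  tibble::tibble(
    lineage = x$lineage,
    n_drugs = length(x$dgcps),
    n_genes = length(x$gene_universe),
    n_cell_lines = as.integer(x$provenance$n_cell_lines %||% NA_integer_),
    min_pairs = as.integer(x$provenance$min_pairs %||% NA_integer_))
}

#' Plot a DGCP as a correlation waterfall
#'
#' Genes in DGCP order against their PCC, with the top (resistance) and
#' bottom (sensitivity) biomarker windows shaded.
#'
#' @param object A `dgcp`.
#' @param set_size Biomarker window to highlight (default 250, clamped).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dgcp <- function(object, set_size = 250L, ...) {
  n <- nrow(object)
  set_size <- min(set_size, n %/% 2L)
  df <- tibble::tibble(rank = seq_len(n), pcc = object$pcc)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$pcc)) +
    ggplot2::annotate("rect", xmin = 0.5, xmax = set_size + 0.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "firebrick") +
    ggplot2::annotate("rect", xmin = n - set_size + 0.5, xmax = n + 0.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "DGCP rank (descending PCC)", y = "Pearson correlation with AUC",
                  title = attr(object, "drug_id"),
                  subtitle = "red: resistance window, blue: sensitivity window") +
    ggplot2::theme_minimal()
}
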