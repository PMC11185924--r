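# Validation: sensitivity gold standards and percentile-binned normalized
# positive-predictive-value curves, plus the cross-lineage negative control.

new_gold_standard <- function(pairs, rule_provenance) {
  stopifnot(all(c("sample_id", "drug_id", "label") %in% names(pairs)))
  attr(pairs, "rule_provenance") <- rule_provenance
  class(pairs) <- c("gold_standard", class(pairs))
  pairs
}

#' Call sensitive cell lines from an AUC table
#'
#' Labels each (cell line, drug) pair: with the `per_drug_quantile` rule a
#' pair is sensitive iff its AUC is at or below the `q`-quantile of that
#' drug's AUCs (default `q = 0.05`); with `absolute_threshold`, iff
#' `AUC <= t`. Missing AUCs are labelled unknown. Raising `q` never removes a
#' sensitive label (nested calls).
#'
#' @param response Numeric drugs x cell-lines AUC matrix.
#' @param rule `"per_drug_quantile"` or `"absolute_threshold"`.
#' @param q Quantile in (0, 1) for the quantile rule.
#' @param t Threshold for the absolute rule.
#' @return A `gold_standard` tibble: `sample_id` (cell line), `drug_id`,
#'   `label` in {sensitive, resistant, unknown}; attribute `rule_provenance`.
#' @export
call_sensitive_from_auc <- function(response,
                                    rule = c("per_drug_quantile", "absolute_threshold"),
                                    q = 0.05, t = NULL) {
  rule <- match.arg(rule)
  assert_response_matrix(response, "response")
  if (rule == "per_drug_quantile") {
    if (!(q > 0 && q < 1)) abort("`q` must be in (0, 1).")
    n_per_drug <- rowSums(is.finite(response))
    if (any(n_per_drug < 2L)) {
      abort("The quantile rule needs >= 2 measured cell lines per drug.")
    }
    cutoff <- apply(response, 1L, function(a) stats::quantile(a, q, na.rm = TRUE, names = FALSE))
    provenance <- sprintf("per-drug quantile rule: sensitive iff AUC <= %g-quantile of the drug's AUCs", q)
  } else {
    if (is.null(t)) abort("`t` is required for the absolute_threshold rule.")
    cutoff <- rep(t, nrow(response))
    provenance <- sprintf("absolute rule: sensitive iff AUC <= %g", t)
  }
  pairs <- tibble::tibble(
    sample_id = rep(colnames(response), each = nrow(response)),
    drug_id = rep(rownames(response), times = ncol(response)),
    auc = as.vector(response),
    label = dplyr::case_when(
      !is.finite(as.vector(response)) ~ "unknown",
      as.vector(response) <= rep(cutoff, times = ncol(response)) ~ "sensitive",
      TRUE ~ "resistant"))
  new_gold_standard(pairs[, c("sample_id", "drug_id", "label")], provenance)
}

#' Call sensitive models from categorical response labels
#'
#' Clinical-style calling: complete or partial response (CR/PR) = sensitive,
#' stable or progressive disease (SD/PD) = resistant, anything else = unknown
#' with a warning.
#'
#' @param labels A data frame with columns `model_id` (or `sample_id`),
#'   `drug_id`, `response`.
#' @return A `gold_standard` tibble.
#' @export
call_sensitive_from_labels <- function(labels) {
  labels <- tibble::as_tibble(labels)
  if ("model_id" %in% names(labels) && !"sample_id" %in% names(labels)) {
    labels <- dplyr::rename(labels, sample_id = "model_id")
  }
  stopifnot(all(c("sample_id", "drug_id", "response") %in% names(labels)))
  lab <- dplyr::case_when(
    labels$response %in% c("CR", "PR") ~ "sensitive",
    labels$response %in% c("SD", "PD") ~ "resistant",
    TRUE ~ "unknown")
  if (any(lab == "unknown")) {
    warn(sprintf("%d response label(s) outside CR/PR/SD/PD set to unknown.",
                 sum(lab == "unknown")))
  }
  new_gold_standard(
    tibble::tibble(sample_id = labels$sample_id, drug_id = labels$drug_id, label = lab),
    "categorical rule: CR/PR sensitive, SD/PD resistant")
}

#' Percentile-binned normalized PPV curve
#'
#' Restricts the scored pairs to those with a sensitive/resistant gold label
#' (unknowns are excluded, not counted as false positives), sorts ascending by
#' G-score (ties broken by sample then drug id), and computes the cumulative
#' positive predictive value `PPV = TP / (TP + FP)` at each percentile cutoff.
#' The curve is normalized against the PPV of a random ordering, which equals
#' the prevalence of sensitive pairs; at the 100th percentile the raw PPV
#' equals prevalence, so the normalized curve terminates at 1. The normalized
#' curve is invariant under any strictly monotone transform of the score.
#'
#' @param scores Tibble from [score_cohort()]; must contain `sample_id`,
#'   `drug_id` and the score column.
#' @param gold A `gold_standard`.
#' @param n_bins Number of percentile bins (default 100).
#' @param score_col Column used for ordering (default `"g_score"`).
#' @param cumulative Cumulative PPV (default) or per-bin PPV.
#' @return A `ppv_curve` tibble: `percentile`, `n_pairs`, `ppv`, `random_ppv`,
#'   `normalized_ppv`.
#' @export
ppv_curve <- function(scores, gold, n_bins = 100L, score_col = "g_score",
                      cumulative = TRUE) {
  stopifnot(all(c("sample_id", "drug_id", score_col) %in% names(scores)))
  labeled <- dplyr::inner_join(
    scores, gold[gold$label != "unknown", c("sample_id", "drug_id", "label")],
    by = c("sample_id", "drug_id"))
  if (nrow(labeled) == 0L) abort("No scored pair carries a gold label.")
  if (!any(labeled$label == "sensitive")) {
    abort("No labeled sensitive pair among the scored pairs; PPV is undefined.")
  }
  ord <- order(labeled[[score_col]], labeled$sample_id, labeled$drug_id, method = "radix")
  hit <- as.integer(labeled$label[ord] == "sensitive")
  n <- length(hit)
  prevalence <- mean(hit)
  grid <- (seq_len(n_bins) / n_bins) * 100
  upto <- pmin(pmax(ceiling(grid / 100 * n), 1L), n)
  cum_hits <- cumsum(hit)
  if (cumulative) {
    ppv <- cum_hits[upto] / upto
  } else {
    lower <- c(0L, upto[-n_bins])
    width <- upto - lower
    ppv <- ifelse(width > 0, (cum_hits[upto] - c(0, cum_hits)[lower + 1L]) / width, NA_real_)
  }
  out <- tibble::tibble(percentile = grid, n_pairs = upto, ppv = ppv,
                        random_ppv = prevalence,
                        normalized_ppv = ppv / prevalence)
  class(out) <- c("ppv_curve", class(out))
  out
}

#' Matched vs mismatched library evaluation (negative control)
#'
#' Scores the same samples with a matched library and with a mismatched one
#' (e.g. trained on another lineage, or label-shuffled) and returns both
#' normalized PPV curves for comparison. No thresholding is applied; this is
#' a reporting tool.
#'
#' @param expr Numeric genes x samples matrix.
#' @param library_matched,library_mismatched `dgcp_library` objects sharing
#'   drug coverage with `gold`.
#' @param gold A `gold_standard`.
#' @param params A [scoring_params()] list.
#' @param n_bins Percentile bins for both curves.
#' @return A list with elements `matched` and `mismatched`, each a
#'   `ppv_curve`.
#' @export
cross_control_evaluation <- function(expr, library_matched, library_mismatched,
                                     gold, params = scoring_params(),
                                     n_bins = 100L) {
  gold_drugs <- unique(gold$drug_id)
  for (lbl in c("matched", "mismatched")) {
    lib <- if (lbl == "matched") library_matched else library_mismatched
    if (length(intersect(names(lib$dgcps), gold_drugs)) == 0L) {
      abort(sprintf("The %s library shares no drug with the gold standard.", lbl))
    }
  }
  list(
    matched = ppv_curve(score_cohort(expr, library_matched, params), gold, n_bins = n_bins),
    mismatched = ppv_curve(score_cohort(expr, library_mismatched, params), gold, n_bins = n_bins))
}

#' Plot a normalized PPV curve
#'
#' @param object A `ppv_curve`.
#' @param ... Additional `ppv_curve`s to overlay, named.
#' @return A ggplot object: normalized PPV against score percentile with the
#'   random baseline at 1.
#' @export
autoplot.ppv_curve <- function(object, ...) {
  extra <- list(...)
  curves <- c(list(curve = object), extra[vapply(extra, inherits, logical(1), "ppv_curve")])
  df <- purrr::map_dfr(names(curves) %||% "curve",
                       function(nm) dplyr::mutate(tibble::as_tibble(curves[[nm]]), curve = nm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$percentile, y = .data$normalized_ppv,
                                   color = .data$curve)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "G-score percentile (ascending)", y = "normalized PPV") +
    ggplot2::theme_minimal()
}
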