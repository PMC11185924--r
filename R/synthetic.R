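# Synthetic benchmark: seed-reproducible training panels with planted
# biomarkers and tumor cohorts with subtype structure, so every module is
# exercisable offline.
#
# Generative model: each drug d carries a latent per-cell-line response
# factor u_dc ~ N(0,1) and AUC_dc = 10 + u_dc (clamped at 0; AUCs are
# non-negative). A gene planted as a biomarker gets expression
#   z_gc = (sum_d s_gd * beta * u_dc + sigma * e_gc) / sqrt(k_g beta^2 + sigma^2)
# with s_gd = +1 for resistance, -1 for sensitivity, k_g the number of drugs
# the gene is planted for, and e_gc ~ N(0,1); unplanted genes are plain
# N(0,1). Every gene is marginally standard normal and the per-gene Pearson
# correlation with drug d's AUC is s_gd * beta / sqrt(k_g beta^2 + sigma^2),
# so beta/sigma directly controls biomarker recoverability (0.89 per planted
# gene at beta/sigma = 2 with k_g = 1). Expression is a log-scale surrogate;
# the method is rank/correlation based, so the marginal shape is immaterial.

#' Simulate a training benchmark with planted biomarkers
#'
#' Generates an expression panel, an AUC table whose per-drug response is
#' linearly reflected in the planted sensitivity (negative PCC) and
#' resistance (positive PCC) biomarker genes, the ground-truth biomarker
#' sets, and the gold standard implied by a per-drug AUC quantile rule.
#' Fully reproducible given `seed`.
#'
#' @param n_genes,n_cell_lines,n_drugs Panel dimensions (defaults 2000, 60,
#'   30).
#' @param n_biomarkers_per_direction Planted genes per drug and direction
#'   (default 50). Sensitivity and resistance sets are always disjoint within
#'   a drug.
#' @param effect_beta Biomarker effect size (default 2).
#' @param noise_sd Residual expression noise (default 1); `effect_beta /
#'   noise_sd` is the per-gene signal-to-noise ratio.
#' @param seed Integer seed (default 1).
#' @param disjoint Plant non-overlapping sets across drugs? `NULL` (default)
#'   means "when feasible" (`2 * n_biomarkers * n_drugs <= n_genes`); `TRUE`
#'   errors when infeasible. Overlapping genes get the multi-drug
#'   construction above, which keeps them standard normal.
#' @param q_sensitive Per-drug AUC quantile for the implied gold standard
#'   (default 0.05).
#' @return A `synthetic_benchmark`: list with `expression` (genes x cell
#'   lines), `response` (drugs x cell lines), `truth_biomarkers` (tibble:
#'   `drug_id`, `direction`, `gene`), `truth_sensitivity` (a
#'   `gold_standard`), `params`, `seed`.
#' @export
simulate_benchmark <- function(n_genes = 2000L, n_cell_lines = 60L,
                               n_drugs = 30L, n_biomarkers_per_direction = 50L,
                               effect_beta = 2, noise_sd = 1, seed = 1L,
                               disjoint = NULL, q_sensitive = 0.05) {
  nb <- as.integer(n_biomarkers_per_direction)
  feasible <- 2L * nb * n_drugs <= n_genes
  if (is.null(disjoint)) {
    disjoint <- feasible
    if (!feasible) {
      inform(sprintf("Planting %d biomarker slots into %d genes: sets overlap across drugs.",
                     2L * nb * n_drugs, n_genes))
    }
  } else if (disjoint && !feasible) {
    abort(sprintf("Disjoint planting infeasible: %d slots > %d genes.",
                  2L * nb * n_drugs, n_genes))
  }
  if (2L * nb > n_genes) abort("A single drug's biomarker sets exceed the gene pool.")
  maybe_set_seed(seed)

  genes <- sprintf("g%05d", seq_len(n_genes))
  lines <- sprintf("cl%03d", seq_len(n_cell_lines))
  drugs <- sprintf("drug%03d", seq_len(n_drugs))

  if (disjoint) {
    slots <- matrix(sample.int(n_genes, 2L * nb * n_drugs), ncol = n_drugs)
    sens_idx <- lapply(seq_len(n_drugs), function(d) slots[seq_len(nb), d])
    res_idx <- lapply(seq_len(n_drugs), function(d) slots[nb + seq_len(nb), d])
  } else {
    both <- lapply(seq_len(n_drugs), function(d) sample.int(n_genes, 2L * nb))
    sens_idx <- lapply(both, function(s) s[seq_len(nb)])
    res_idx <- lapply(both, function(s) s[nb + seq_len(nb)])
  }

  u <- matrix(rnorm(n_drugs * n_cell_lines), nrow = n_drugs,
              dimnames = list(drugs, lines))
  auc <- pmax(10 + u, 0)

  # signed effect loadings: signal[g, ] = sum_d s_gd * beta * u_d
  signal <- matrix(0, n_genes, n_cell_lines)
  k_planted <- integer(n_genes)
  for (d in seq_len(n_drugs)) {
    signal[res_idx[[d]], ] <- signal[res_idx[[d]], , drop = FALSE] +
      effect_beta * matrix(u[d, ], length(res_idx[[d]]), n_cell_lines, byrow = TRUE)
    signal[sens_idx[[d]], ] <- signal[sens_idx[[d]], , drop = FALSE] -
      effect_beta * matrix(u[d, ], length(sens_idx[[d]]), n_cell_lines, byrow = TRUE)
    k_planted[res_idx[[d]]] <- k_planted[res_idx[[d]]] + 1L
    k_planted[sens_idx[[d]]] <- k_planted[sens_idx[[d]]] + 1L
  }
  noise <- matrix(rnorm(n_genes * n_cell_lines, sd = noise_sd), n_genes, n_cell_lines)
  denom <- sqrt(k_planted * effect_beta^2 + noise_sd^2)
  expression <- (signal + noise) / denom
  dimnames(expression) <- list(genes, lines)

  truth <- dplyr::bind_rows(
    purrr::map_dfr(seq_len(n_drugs), function(d) {
      tibble::tibble(drug_id = drugs[[d]], direction = "sensitivity",
                     gene = genes[sens_idx[[d]]])
    }),
    purrr::map_dfr(seq_len(n_drugs), function(d) {
      tibble::tibble(drug_id = drugs[[d]], direction = "resistance",
                     gene = genes[res_idx[[d]]])
    }))

  gold <- call_sensitive_from_auc(auc, rule = "per_drug_quantile", q = q_sensitive)

  structure(
    list(expression = expression, response = auc, truth_biomarkers = truth,
         truth_sensitivity = gold,
         params = list(n_genes = n_genes, n_cell_lines = n_cell_lines,
                       n_drugs = n_drugs,
                       n_biomarkers_per_direction = nb,
                       effect_beta = effect_beta, noise_sd = noise_sd,
                       disjoint = disjoint, q_sensitive = q_sensitive),
         seed = seed),
    class = "synthetic_benchmark")
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  p <- x$params
  cat(sprintf("<synthetic_benchmark> %d genes x %d cell lines, %d drugs, %d planted biomarkers/direction (beta = %g, sigma = %g, seed = %s)\n",
              p$n_genes, p$n_cell_lines, p$n_drugs, p$n_biomarkers_per_direction,
              p$effect_beta, p$noise_sd, as.character(x$seed)))
  invisible(x)
}

#' Simulate a tumor cohort with subtype-specific drug sensitivity
#'
#' Each patient's profile is an i.i.d. standard-normal background with
#' `+shift` added to the sensitivity biomarkers and `-shift` to the resistance
#' biomarkers of the drugs designated effective for the patient's subtype, so
#' subtype patients present the transcriptional signature of sensitivity to
#' those drugs.
#'
#' @param benchmark A [simulate_benchmark()] result (supplies gene ids and the
#'   planted biomarker truth).
#' @param n_patients_per_subtype Patients per subtype (default 20).
#' @param drugs_per_subtype Named list: subtype label -> character vector of
#'   designated effective drug ids (must exist in the benchmark). Default:
#'   two subtypes `"C1"` and `"C2"`, each designated 20% of the benchmark
#'   drugs (the first 20% and the next 20% of the panel respectively), a
#'   prevalence at which the normalized-PPV negative-control band is
#'   well-powered (see the methods vignette).
#' @param shift Expression shift applied to the designated drugs' biomarkers
#'   (default 2, i.e. two background standard deviations).
#' @param seed Integer seed (default 1).
#' @return A `synthetic_cohort`: list with `expression` (genes x patients),
#'   `subtype` (named character vector per patient), `truth_effective_drugs`
#'   (the designated list), `gold` (a `gold_standard` labelling each
#'   (patient, drug) pair sensitive iff the drug is designated for the
#'   patient's subtype), `params`, `seed`.
#' @export
simulate_cohort <- function(benchmark, n_patients_per_subtype = 20L,
                            drugs_per_subtype = NULL, shift = 2, seed = 1L) {
  stopifnot(inherits(benchmark, "synthetic_benchmark"))
  all_drugs <- rownames(benchmark$response)
  if (is.null(drugs_per_subtype)) {
    # default designation: two subtypes, each sensitive to 20% of the panel
    n_des <- max(1L, as.integer(round(0.2 * length(all_drugs))))
    if (2L * n_des > length(all_drugs)) {
      abort("Too few benchmark drugs for the default designation; pass `drugs_per_subtype`.")
    }
    drugs_per_subtype <- list(C1 = all_drugs[seq_len(n_des)],
                              C2 = all_drugs[n_des + seq_len(n_des)])
  }
  unknown <- setdiff(unlist(drugs_per_subtype), all_drugs)
  if (length(unknown)) {
    abort(sprintf("Unknown designated drug id(s): %s.", paste(unknown, collapse = ", ")))
  }
  if (any(lengths(drugs_per_subtype) == 0L)) abort("Every subtype needs >= 1 designated drug.")
  maybe_set_seed(seed)

  genes <- rownames(benchmark$expression)
  subtypes <- names(drugs_per_subtype)
  patients <- unlist(lapply(subtypes, function(st) {
    sprintf("%s_p%02d", st, seq_len(n_patients_per_subtype))
  }))
  subtype_of <- setNames(rep(subtypes, each = n_patients_per_subtype), patients)

  expr <- matrix(rnorm(length(genes) * length(patients)),
                 nrow = length(genes), dimnames = list(genes, patients))
  truth <- benchmark$truth_biomarkers
  for (st in subtypes) {
    marks <- truth[truth$drug_id %in% drugs_per_subtype[[st]], ]
    up <- unique(marks$gene[marks$direction == "sensitivity"])
    down <- unique(marks$gene[marks$direction == "resistance"])
    cols <- patients[subtype_of == st]
    expr[up, cols] <- expr[up, cols] + shift
    expr[down, cols] <- expr[down, cols] - shift
  }

  pair_patient <- rep(patients, each = length(all_drugs))
  pair_drug <- rep(all_drugs, times = length(patients))
  designated <- mapply(function(d, p) d %in% drugs_per_subtype[[subtype_of[[p]]]],
                       pair_drug, pair_patient, USE.NAMES = FALSE)
  gold <- new_gold_standard(
    tibble::tibble(sample_id = pair_patient, drug_id = pair_drug,
                   label = ifelse(designated, "sensitive", "resistant")),
    "synthetic cohort truth: sensitive iff the drug is designated for the patient's subtype")

  structure(
    list(expression = expr, subtype = subtype_of,
         truth_effective_drugs = drugs_per_subtype, gold = gold,
         params = list(n_patients_per_subtype = n_patients_per_subtype,
                       shift = shift),
         seed = seed),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients (%s), shift = %g\n",
              ncol(x$expression),
              paste(sprintf("%s: %d", names(table(x$subtype)), table(x$subtype)),
                    collapse = ", "),
              x$params$shift))
  invisible(x)
}
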