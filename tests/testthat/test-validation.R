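test_that("AUC quantile calling marks exactly the most sensitive lines", {
  resp <- matrix(1:20, nrow = 1, dimnames = list("d1", sprintf("c%02d", 1:20)))
  gold <- call_sensitive_from_auc(resp, q = 0.05)
  expect_identical(sum(gold$label == "sensitive"), 1L)
  expect_identical(gold$sample_id[gold$label == "sensitive"], "c01")

  # raising q never removes a sensitive label (nestedness)
  resp2 <- matrix(abs(rnorm(60, 10)), nrow = 3,
                  dimnames = list(paste0("d", 1:3), sprintf("c%02d", 1:20)))
  prev <- character(0)
  for (q in c(0.05, 0.1, 0.25, 0.5)) {
    g <- call_sensitive_from_auc(resp2, q = q)
    now <- paste(g$sample_id, g$drug_id)[g$label == "sensitive"]
    expect_true(all(prev %in% now))
    prev <- now
  }

  # missing AUC -> unknown; absolute rule
  resp2[1, 1] <- NA
  g <- call_sensitive_from_auc(resp2, rule = "absolute_threshold", t = 9)
  expect_identical(g$label[g$sample_id == "c01" & g$drug_id == "d1"], "unknown")
  expect_true(all((g$label == "sensitive") ==
                    (!is.na(resp2[cbind(g$drug_id, g$sample_id)]) &
                       resp2[cbind(g$drug_id, g$sample_id)] <= 9)))
  expect_error(call_sensitive_from_auc(resp, q = 1.5), "0, 1")

  # threshold below every AUC: zero sensitive, PPV errors cleanly downstream
  none <- call_sensitive_from_auc(resp, rule = "absolute_threshold", t = 0.5)
  sc <- tibble::tibble(sample_id = sprintf("c%02d", 1:20), drug_id = "d1",
                       g_score = runif(20))
  expect_error(ppv_curve(sc, none), "sensitive")
})

test_that("categorical response calling follows the CR/PR vs SD/PD rule", {
  labels <- tibble::tibble(model_id = paste0("m", 1:5), drug_id = "d1",
                           response = c("CR", "PR", "SD", "PD", "NE"))
  expect_warning(gold <- call_sensitive_from_labels(labels), "unknown")
  expect_identical(gold$label, c("sensitive", "sensitive", "resistant",
                                 "resistant", "unknown"))
})

test_that("PPV curves match the hand-computed cumulative precision", {
  sc <- tibble::tibble(sample_id = sprintf("s%02d", 1:10), drug_id = "d",
                       g_score = seq(0.05, 0.95, length.out = 10))
  gold <- structure(tibble::tibble(sample_id = sc$sample_id, drug_id = "d",
                                   label = c(rep("sensitive", 3), rep("resistant", 7))),
                    class = c("gold_standard", "tbl_df", "tbl", "data.frame"))
  curve <- ppv_curve(sc, gold, n_bins = 10)
  expect_equal(curve$ppv, c(1, 1, 1, 3 / 4, 3 / 5, 3 / 6, 3 / 7, 3 / 8, 3 / 9, 3 / 10),
               tolerance = 1e-12)
  expect_equal(curve$normalized_ppv[1], 1 / 0.3, tolerance = 1e-12)
  # terminal bin: PPV equals prevalence, normalized PPV equals 1
  expect_equal(curve$ppv[10], 0.3, tolerance = 1e-12)
  expect_equal(curve$normalized_ppv[10], 1, tolerance = 1e-12)

  # all pairs sensitive: PPV and normalized PPV identically 1
  gold_all <- structure(tibble::tibble(sample_id = sc$sample_id, drug_id = "d",
                                       label = "sensitive"),
                        class = c("gold_standard", "tbl_df", "tbl", "data.frame"))
  c_all <- ppv_curve(sc, gold_all, n_bins = 5)
  expect_true(all(c_all$ppv == 1) && all(c_all$normalized_ppv == 1))

  # invariance under strictly monotone transforms of the score
  sc2 <- dplyr::mutate(sc, g_score = exp(5 * g_score) + 2)
  expect_equal(ppv_curve(sc2, gold, n_bins = 10)$normalized_ppv,
               curve$normalized_ppv, tolerance = 1e-12)

  # unknown labels are excluded, not treated as false positives
  gold_u <- gold
  gold_u$label[4:5] <- "unknown"
  cu <- ppv_curve(sc, gold_u, n_bins = 8)
  expect_identical(max(cu$n_pairs), 8)
})

test_that("random scores stay near the random baseline; a perfect scorer peaks", {
  set.seed(61)
  n <- 2000
  sc <- tibble::tibble(sample_id = sprintf("s%04d", 1:n), drug_id = "d",
                       g_score = runif(n))
  lab <- ifelse(runif(n) < 0.2, "sensitive", "resistant")
  gold <- structure(tibble::tibble(sample_id = sc$sample_id, drug_id = "d", label = lab),
                    class = c("gold_standard", "tbl_df", "tbl", "data.frame"))
  curve <- ppv_curve(sc, gold, n_bins = 100)
  expect_true(all(abs(curve$normalized_ppv[curve$percentile >= 10] - 1) <= 0.2))

  # perfect scorer: normalized PPV = 1/prevalence at percentile 100*prevalence
  prevalence <- mean(lab == "sensitive")
  sc_perfect <- dplyr::mutate(sc, g_score = ifelse(lab == "sensitive", 0, 1) + runif(n) * 0.5)
  cp <- ppv_curve(sc_perfect, gold, n_bins = 1000)
  at <- which.min(abs(cp$percentile - 100 * prevalence))
  expect_equal(cp$normalized_ppv[at], 1 / prevalence, tolerance = 0.01)
})

test_that("cross-library evaluation contrasts matched and mismatched curves", {
  bm <- simulate_benchmark(n_genes = 200, n_cell_lines = 30, n_drugs = 4,
                           n_biomarkers_per_direction = 10, seed = 41)
  lib <- suppressMessages(build_library(bm$expression, bm$response))
  params <- scoring_params(set_size = 20, n_perm = 50, seed = 3)
  expr <- bm$expression[, 1:6]
  gold <- bm$truth_sensitivity
  both <- cross_control_evaluation(expr, lib, lib, gold, params, n_bins = 10)
  expect_identical(both$matched, both$mismatched)   # identical libraries
  expect_s3_class(both$matched, "ppv_curve")

  lib_other <- lib
  names(lib_other$dgcps) <- paste0("other_", names(lib_other$dgcps))
  lib_other$dgcps <- lapply(lib_other$dgcps, function(d) {
    attr(d, "drug_id") <- paste0("other_", attr(d, "drug_id")); d
  })
  expect_error(cross_control_evaluation(expr, lib, lib_other, gold, params),
               "shares no drug")
})
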