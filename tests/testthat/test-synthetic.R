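test_that("benchmark generation is bit-reproducible and structurally sound", {
  a <- simulate_benchmark(n_genes = 150, n_cell_lines = 25, n_drugs = 3,
                          n_biomarkers_per_direction = 10, seed = 7)
  b <- simulate_benchmark(n_genes = 150, n_cell_lines = 25, n_drugs = 3,
                          n_biomarkers_per_direction = 10, seed = 7)
  expect_identical(a, b)

  expect_identical(dim(a$expression), c(150L, 25L))
  expect_identical(dim(a$response), c(3L, 25L))
  expect_true(all(a$response >= 0))
  tb <- a$truth_biomarkers
  # within-drug sensitivity and resistance sets are disjoint; sizes honored
  for (d in rownames(a$response)) {
    sens <- tb$gene[tb$drug_id == d & tb$direction == "sensitivity"]
    res <- tb$gene[tb$drug_id == d & tb$direction == "resistance"]
    expect_length(sens, 10L)
    expect_length(res, 10L)
    expect_length(intersect(sens, res), 0L)
  }
  # feasible scale: planting is disjoint across drugs too
  expect_identical(anyDuplicated(tb$gene), 0L)

  # implied gold standard matches the per-drug 5% quantile rule
  g <- a$truth_sensitivity
  for (d in rownames(a$response)) {
    cut <- stats::quantile(a$response[d, ], 0.05, names = FALSE)
    expect_identical(g$sample_id[g$drug_id == d & g$label == "sensitive"],
                     colnames(a$response)[a$response[d, ] <= cut])
  }

  expect_error(simulate_benchmark(n_genes = 50, n_drugs = 10,
                                  n_biomarkers_per_direction = 10,
                                  disjoint = TRUE), "infeasible")
  # infeasible disjoint planting falls back to overlap with a message
  expect_message(ov <- simulate_benchmark(n_genes = 60, n_cell_lines = 10,
                                          n_drugs = 10,
                                          n_biomarkers_per_direction = 10,
                                          seed = 2), "overlap")
  expect_false(ov$params$disjoint)
})

test_that("a null benchmark (zero effect) plants no recoverable signal", {
  bm <- simulate_benchmark(n_genes = 500, n_cell_lines = 60, n_drugs = 2,
                           n_biomarkers_per_direction = 25, effect_beta = 0,
                           seed = 19)
  d <- compute_dgcp(bm$expression, bm$response[1, ], min_pairs = 10)
  # ~5% of null PCCs exceed 2/sqrt(n) in absolute value
  frac <- mean(abs(d$pcc) > 2 / sqrt(60))
  expect_lt(abs(frac - 0.05), 0.03)
  sens <- bm$truth_biomarkers$gene[bm$truth_biomarkers$drug_id == "drug001" &
                                     bm$truth_biomarkers$direction == "sensitivity"]
  recall <- mean(sens %in% extract_biomarkers(d, "sensitivity", 100))
  expect_lt(recall, 0.6)   # nothing beyond chance-level enrichment
})

test_that("planted per-gene correlations match the analytic value", {
  # large panel so the sample PCC concentrates: expected value for a gene
  # planted for one drug is +/- beta / sqrt(beta^2 + sigma^2)
  beta <- 2
  sigma <- 1
  bm <- simulate_benchmark(n_genes = 300, n_cell_lines = 400, n_drugs = 2,
                           n_biomarkers_per_direction = 20, effect_beta = beta,
                           noise_sd = sigma, seed = 33)
  d <- compute_dgcp(bm$expression, bm$response[1, ], min_pairs = 10)
  pcc <- setNames(d$pcc, d$gene)
  tb <- bm$truth_biomarkers
  sens <- tb$gene[tb$drug_id == "drug001" & tb$direction == "sensitivity"]
  res <- tb$gene[tb$drug_id == "drug001" & tb$direction == "resistance"]
  analytic <- beta / sqrt(beta^2 + sigma^2)
  expect_lt(abs(mean(pcc[sens]) + analytic), 0.05)
  expect_lt(abs(mean(pcc[res]) - analytic), 0.05)
  expect_lt(abs(mean(pcc[setdiff(names(pcc), c(sens, res))])), 0.02)
})

test_that("cohorts encode subtype-specific sensitivity and exchangeability", {
  bm <- simulate_benchmark(n_genes = 200, n_cell_lines = 30, n_drugs = 6,
                           n_biomarkers_per_direction = 10, seed = 13)
  co <- simulate_cohort(bm, n_patients_per_subtype = 4,
                        drugs_per_subtype = list(C1 = "drug001", C2 = "drug004"),
                        shift = 3, seed = 14)
  expect_identical(ncol(co$expression), 8L)
  expect_identical(as.integer(table(co$subtype)[c("C1", "C2")]), c(4L, 4L))
  # designated sensitivity biomarkers are up-shifted in their subtype only
  tb <- bm$truth_biomarkers
  up <- tb$gene[tb$drug_id == "drug001" & tb$direction == "sensitivity"]
  c1 <- names(co$subtype)[co$subtype == "C1"]
  c2 <- names(co$subtype)[co$subtype == "C2"]
  expect_gt(mean(co$expression[up, c1]) - mean(co$expression[up, c2]), 2)
  # gold standard labels exactly the designated pairs sensitive
  g <- co$gold
  expect_identical(sort(unique(g$sample_id[g$label == "sensitive" & g$drug_id == "drug001"])),
                   sort(c1))
  expect_error(simulate_cohort(bm, drugs_per_subtype = list(C1 = "nope")), "Unknown")

  # shift = 0: subtypes are exchangeable, consensus lists overlap heavily
  co0 <- simulate_cohort(bm, n_patients_per_subtype = 6,
                         drugs_per_subtype = list(C1 = "drug001", C2 = "drug004"),
                         shift = 0, seed = 15)
  lib <- suppressMessages(build_library(bm$expression, bm$response))
  sc <- score_cohort(co0$expression, lib, scoring_params(set_size = 20, n_perm = 50, seed = 6))
  ls <- ranked_lists_from_scores(sc)
  cons1 <- ce_aggregate(ls[co0$subtype == "C1"], k = 3, seed = 5)
  cons2 <- ce_aggregate(ls[co0$subtype == "C2"], k = 3, seed = 5)
  # no planted difference: designated drugs do not dominate their own subtype
  expect_false(identical(cons1$items[1], "drug001") &&
                 identical(cons2$items[1], "drug004"))

  # permuting patient order leaves the consensus unchanged (fixed seed)
  perm <- rev(names(ls[co0$subtype == "C1"]))
  cons1b <- ce_aggregate(ls[perm], k = 3, seed = 5)
  expect_identical(cons1b$items, cons1$items)
})

test_that("generator output survives the io round trip", {
  bm <- simulate_benchmark(n_genes = 80, n_cell_lines = 12, n_drugs = 2,
                           n_biomarkers_per_direction = 5, seed = 3)
  fe <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::as_tibble(bm$expression, rownames = "gene"), fe)
  back <- read_expression(fe)
  expect_identical(dimnames(back), dimnames(bm$expression))
  expect_equal(back, bm$expression, tolerance = 1e-12)

  fr <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::as_tibble(bm$response, rownames = "drug"), fr)
  back_r <- read_response(fr)
  expect_equal(back_r, bm$response, tolerance = 1e-12)
})
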