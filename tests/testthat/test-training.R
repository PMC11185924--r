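test_that("a gene tracking the AUC perfectly tops the DGCP with PCC = 1", {
  set.seed(1)
  auc <- setNames(runif(10, 5, 15), sprintf("s%02d", 1:10))
  expr <- make_expr(5, 10, seed = 2)
  expr["g001", ] <- auc                      # identical to the AUC vector
  expr["g002", ] <- 7                        # constant: undefined correlation
  d <- suppressMessages(compute_dgcp(expr, auc, min_pairs = 5))
  expect_identical(d$gene[1], "g001")
  expect_equal(d$pcc[1], 1, tolerance = 1e-12)
  expect_false("g002" %in% d$gene)           # zero-variance gene dropped
  expect_true(all(diff(d$pcc) <= 0))         # descending order contract
})

test_that("DGCP correlations match the brute-force pairwise-complete oracle", {
  # small deterministic case first: 5 genes x 4 lines, integer-ish values
  expr <- matrix(c(1, 2, 3, 4,
                   4, 3, 2, 1,
                   1, 3, 2, 4,
                   2, 2, 3, 5,
                   5, 1, 4, 2), nrow = 5, byrow = TRUE,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  auc <- setNames(c(1, 2, 3, 4), paste0("s", 1:4))
  d <- compute_dgcp(expr, auc, min_pairs = 4)
  expected <- vapply(rownames(expr), function(g) oracle_pearson(expr[g, ], auc), numeric(1))
  expected <- sort(expected, decreasing = TRUE)
  expect_equal(setNames(d$pcc, d$gene), expected, tolerance = 1e-12)

  # randomized property: 25 matrices with 10% missingness
  for (rep in 1:25) {
    expr <- make_expr(30, 15, seed = 100 + rep)
    expr[sample(length(expr), length(expr) %/% 10)] <- NA
    auc <- setNames(abs(rnorm(15, 10)), colnames(expr))
    d <- suppressMessages(compute_dgcp(expr, auc, min_pairs = 5))
    ora <- vapply(d$gene, function(g) oracle_pearson(expr[g, names(auc)], auc), numeric(1))
    expect_lt(max(abs(d$pcc - ora)), 1e-12)
  }
})

test_that("DGCPs respond to AUC negation and ignore cell-line order", {
  expr <- make_expr(40, 20, seed = 5)
  auc <- setNames(rnorm(20, 10), colnames(expr))
  d <- compute_dgcp(expr, auc, min_pairs = 10)
  # negating the AUC vector negates every PCC and reverses the profile
  auc_neg <- -(auc - 10) + 10
  d_neg <- compute_dgcp(expr, auc_neg, min_pairs = 10)
  expect_equal(setNames(d_neg$pcc, d_neg$gene),
               setNames(-d$pcc, d$gene)[d_neg$gene], tolerance = 1e-12)
  expect_identical(d_neg$gene, rev(d$gene))
  # permuting cell-line order changes nothing
  perm <- sample(colnames(expr))
  d_perm <- compute_dgcp(expr[, perm], auc[perm], min_pairs = 10)
  expect_equal(d_perm$pcc, d$pcc, tolerance = 1e-12)
  expect_identical(d_perm$gene, d$gene)
})

test_that("library training filters underpowered drugs and is deterministic", {
  bm <- simulate_benchmark(n_genes = 120, n_cell_lines = 30, n_drugs = 5,
                           n_biomarkers_per_direction = 10, seed = 21)
  lib <- suppressMessages(build_library(bm$expression, bm$response, lineage = "solid"))
  expect_length(lib$dgcps, 5L)                     # complete panel: all retained
  expect_identical(length(lib$gene_universe), 120L)

  # a drug measured in 2 cell lines only is skipped with a warning
  resp <- bm$response
  resp["drug002", -(1:2)] <- NA
  expect_warning(
    lib2 <- suppressMessages(build_library(bm$expression, resp, min_pairs = 10)),
    "drug002")
  expect_false("drug002" %in% names(lib2$dgcps))

  lib3 <- suppressMessages(build_library(bm$expression, bm$response, lineage = "solid"))
  expect_identical(lib3, lib)                      # bit-identical retraining

  expect_error(
    build_library(bm$expression,
                  matrix(1, 1, 2, dimnames = list("d", c("x1", "x2")))),
    "shared cell-line")
})

test_that("biomarker extraction takes the DGCP ends with clamping", {
  d <- compute_dgcp(make_expr(100, 20, seed = 9),
                                setNames(rnorm(20, 10), sprintf("s%02d", 1:20)),
                                min_pairs = 10)
  sens <- extract_biomarkers(d, "sensitivity", 25)
  res <- extract_biomarkers(d, "resistance", 25)
  expect_identical(res, structure(d$gene[1:25], drug_id = "drug",
                                  direction = "resistance", size = 25L))
  expect_identical(as.character(sens), rev(d$gene)[1:25])  # most negative first
  expect_identical(sens[[1]], d$gene[[100]])
  expect_length(intersect(sens, res), 0L)

  expect_identical(as.character(extract_biomarkers(d, "sensitivity", 1)), d$gene[[100]])
  expect_warning(
    expect_warning(all_of_it <- extract_biomarkers(d, "sensitivity", 150), "clamp"),
    "partition")
  expect_length(all_of_it, 100L)
  expect_warning(extract_biomarkers(d, "resistance", 60), "partition")
})

test_that("pathway anticorrelation check matches exact U enumeration", {
  d <- structure(tibble::tibble(gene = c("t1", "t2", "b1", "b2", "b3"),
                                pcc = c(-0.9, -0.8, 0.1, 0.2, 0.3)),
                 drug_id = "d", n_cell_lines = 10L,
                 class = c("dgcp", "tbl_df", "tbl", "data.frame"))
  res <- pathway_anticorrelation_check(d, c("t1", "t2"), c("b1", "b2", "b3"))
  # U = 0 (every target PCC below every background PCC); exact one-sided
  # p = P(U <= 0) = 1 / choose(5, 2)
  expect_identical(unname(res$statistic), 0)
  expect_equal(res$p_value, 1 / choose(5, 2), tolerance = 1e-12)

  # target group == background group: U centered, p ~ 0.5
  same <- suppressWarnings(
    pathway_anticorrelation_check(d, d$gene, d$gene))
  expect_equal(unname(same$statistic), 25 / 2, tolerance = 1e-12)
  expect_equal(same$p_value, 0.5, tolerance = 0.1)  # continuity correction

  expect_error(pathway_anticorrelation_check(d, "absent", d$gene), "empty")
})

test_that("null-calibrated pathway check yields roughly uniform p-values", {
  set.seed(31)
  p <- replicate(200, {
    d <- structure(tibble::tibble(gene = sprintf("g%02d", 1:40),
                                  pcc = sort(rnorm(40), decreasing = TRUE)),
                   drug_id = "d", n_cell_lines = 10L,
                   class = c("dgcp", "tbl_df", "tbl", "data.frame"))
    pick <- sample(40, 8)
    pathway_anticorrelation_check(d, d$gene[pick], d$gene[-pick])$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.01)
})

test_that("over-representation matches the closed-form hypergeometric tail", {
  universe <- sprintf("g%02d", 1:20)
  sets <- list(hit = universe[1:5], miss = universe[16:20], half = universe[3:8])
  res <- biomarker_overlap_enrichment(universe[1:5], sets, universe)
  expect_equal(res$p_value[res$set == "hit"], 1 / choose(20, 5), tolerance = 1e-12)
  expect_identical(res$overlap[res$set == "miss"], 0L)
  expect_equal(res$p_value[res$set == "miss"], 1, tolerance = 1e-12)
  expect_equal(res$q_value, stats::p.adjust(res$p_value, "BH"), tolerance = 1e-12)
  expect_identical(res$significant, res$q_value < 0.05)
  expect_error(biomarker_overlap_enrichment(universe[1:2], sets, character()), "empty")
})
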