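test_that("generators are pure functions of parameters and seed", {
  a1 <- generate_annotation(12, seed = 3, n_short_genes = 1)
  a2 <- generate_annotation(12, seed = 3, n_short_genes = 1)
  expect_identical(a1, a2)
  l1 <- simulate_chip_library(a1$genes, 2, depth = 1e4,
                              chrom_length = a1$chrom_length, seed = 4)
  l2 <- simulate_chip_library(a1$genes, 2, depth = 1e4,
                              chrom_length = a1$chrom_length, seed = 4)
  expect_identical(l1, l2)
  e1 <- simulate_expression(a1$genes$gene_id, "bulk", seed = 5)
  e2 <- simulate_expression(a1$genes$gene_id, "bulk", seed = 5)
  expect_identical(e1, e2)
  # a different seed changes the draw
  expect_false(identical(e1, simulate_expression(a1$genes$gene_id, "bulk",
                                                 seed = 6)))
})

test_that("planted eligibility violations are truth-labelled and detected", {
  ann <- generate_annotation(10, n_overlapping_pairs = 2, n_close_pairs = 1,
                             n_short_genes = 1, seed = 8)
  truth <- ann$truth
  expect_equal(sum(!truth$eligible_truth), 2 * 2 + 2 + 1)
  kept <- eligible_genes(ann$genes)
  expect_setequal(kept$gene_id, truth$gene_id[truth$eligible_truth])
})

test_that("annotation layout respects an explicit chromosome length", {
  ann <- generate_annotation(5, seed = 1)
  expect_error(generate_annotation(5, seed = 1,
                                   chrom_length = ann$chrom_length / 10),
               "too short")
  expect_error(generate_annotation(0), "n_genes")
})

test_that("promoters hit their GC targets and carry planted k-mers", {
  proms <- generate_promoters(40, gc = rep(c(0.3, 0.7), 20),
                              planted_kmer = "GCGCGC",
                              kmer_counts = rep(c(0L, 3L), 20), seed = 2)
  gc <- gc_content(proms)
  expect_lt(mean(abs(gc - rep(c(0.3, 0.7), 20))), 0.05)
  n_hit <- vapply(proms, function(s) {
    sum(gregexpr("GCGCGC", s, fixed = TRUE)[[1L]] > 0)
  }, 0, USE.NAMES = FALSE)
  expect_true(all(n_hit[seq(2, 40, by = 2)] >= 3))
})

test_that("unit planted PI yields symmetric TSSR/gene-body densities", {
  ann <- generate_annotation(40, seed = 14)
  libs <- simulate_chip_library(ann$genes, 1, depth = 1e6,
                                chrom_length = ann$chrom_length, seed = 15)
  pt <- pause_index(ann$genes, libs$chip, libs$input, filter = FALSE)
  expect_lt(abs(median(log2(pt$pi), na.rm = TRUE)), 0.15)
})

test_that("injected duplicates create collapsible positions", {
  ann <- generate_annotation(10, seed = 16)
  libs <- simulate_chip_library(ann$genes, 2, depth = 2e4,
                                duplication_rate = 0.5,
                                chrom_length = ann$chrom_length, seed = 17)
  r <- libs$chip$reads
  pos <- five_prime_positions(r)
  n_dup <- sum(duplicated(paste(r$chrom, pos, r$strand)))
  expect_gt(n_dup, 0.3 * nrow(r) / 1.5)
  tr <- tssr_region(ann$genes)
  expect_true(all(count_in_regions(libs$chip, tr, dedup = TRUE) <=
                    count_in_regions(libs$chip, tr, dedup = FALSE)))
})

test_that("invalid simulation parameters are rejected", {
  ann <- generate_annotation(5, seed = 1)
  expect_error(simulate_chip_library(ann$genes, -1, depth = 1e4), "planted_pi")
  expect_error(simulate_chip_library(ann$genes, 1, depth = 10), "depth")
  expect_error(simulate_expression(c("a", "b"), "single_cell", n_cells = 1),
               "n_cells")
  expect_error(simulate_expression(c("a", "b"), "time_course",
                                   times = c(1, 2)), "baseline")
})

test_that("single-cell mode plants group-dependent dispersion", {
  ids <- paste0("g", 1:400)
  grp <- rep(c("low", "high"), 200)
  m <- simulate_expression(ids, "single_cell", n_cells = 80, cv_group = grp,
                           dispersion = c(low = 0.05, high = 0.2), seed = 20)
  cv <- apply(m, 1, sd) / rowMeans(m)
  expect_lt(median(cv[grp == "low"]), median(cv[grp == "high"]))
  # zero dispersion: every cell equals the mean, CV = 0
  m0 <- simulate_expression(ids[1:10], "single_cell", n_cells = 10,
                            cv_group = rep("low", 10),
                            dispersion = c(low = 0, high = 0.2), seed = 21)
  expect_equal(unname(apply(m0, 1, sd)), rep(0, 10))
})

test_that("time-course mode plants fold-change classes as labelled", {
  ids <- paste0("g", 1:200)
  resp <- rep(c("early", "late", "down", "none"), 50)
  m <- simulate_expression(ids, "time_course", response = resp, seed = 22)
  fold <- m / m[, 1]
  early <- resp == "early"
  expect_true(all(fold[early, "1"] >= 2))
  late <- resp == "late"
  expect_true(all(fold[late, "1"] < 2))
  expect_true(all(apply(fold[late, c("4", "12")], 1, max) >= 2))
  down <- resp == "down"
  expect_true(all(apply(fold[down, -1], 1, min) <= 0.5))
  none <- resp == "none"
  expect_true(all(fold[none, ] > 0.5 & fold[none, ] < 2))
})

test_that("planted coefficients generate the linear design they claim", {
  sim <- simulate_enrichment_model(500, c(a = 1, b = -0.5), noise_sd = 0,
                                   seed = 3)
  fitted <- as.vector(sim$enrichment %*% sim$betas)
  expect_equal(sim$log2_pi, fitted)
})
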