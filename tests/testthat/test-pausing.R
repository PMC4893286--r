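make_gene <- function(id, start, len, strand = "+", chrom = "c1") {
  gene_models(id, paste0(id, ".1"), chrom, strand,
              tss = if (strand == "+") start else start + len,
              tes = if (strand == "+") start + len else start)
}

test_that("eligibility filter keeps well-spaced long genes only", {
  g <- rbind(make_gene("a", 10000, 5000),
             make_gene("b", 20000, 5000, "-"))  # 5 kb apart
  expect_equal(eligible_genes(g)$gene_id, c("a", "b"))

  short <- rbind(g, make_gene("s", 40000, 900))  # < 1 kb
  expect_false("s" %in% eligible_genes(short)$gene_id)

  # 1 bp span overlap removes both members of the pair
  ov <- rbind(make_gene("x", 10000, 5000), make_gene("y", 14999, 5000),
              make_gene("z", 40000, 5000))
  expect_equal(eligible_genes(ov)$gene_id, "z")

  # within 3 kb removes both
  close_pair <- rbind(make_gene("u", 10000, 5000),
                      make_gene("v", 17000, 5000))  # 2 kb gap
  expect_equal(nrow(eligible_genes(close_pair)), 0L)

  expect_equal(nrow(eligible_genes(g[0, ])), 0L)
})

test_that("genes exactly at the filter boundaries are kept", {
  # exactly 1 kb long, exactly 3 kb gap
  g <- rbind(make_gene("a", 10000, 1000), make_gene("b", 14000, 1000))
  expect_equal(eligible_genes(g)$gene_id, c("a", "b"))
})

test_that("multi-isoform genes are filtered by their union span", {
  g <- rbind(gene_models("m", "m.1", "c1", "+", tss = 10000, tes = 15000),
             gene_models("m", "m.2", "c1", "+", tss = 10000, tes = 18000),
             gene_models("q", "q.1", "c1", "+", tss = 30000, tes = 36000))
  out <- eligible_genes(g)
  expect_equal(nrow(out), 3L)  # isoforms of m overlap only each other
})

test_that("compute_pi follows the density-ratio definition with missingness", {
  expect_equal(compute_pi(0.010, 0.005), 2.0)
  expect_equal(compute_pi(0.02, 0.003), 6.667, tolerance = 1e-3)
  expect_true(is.na(compute_pi(0.02, -0.001)))
  expect_true(is.na(compute_pi(-0.01, 0.003)))
  expect_true(is.na(compute_pi(NA, 0.003)))
})

test_that("paused calls use a strict threshold and treat missing as non-paused", {
  expect_equal(call_paused(c(2.5, 2.0, 1.9, NA)),
               c(TRUE, FALSE, FALSE, FALSE))
  expect_error(call_paused(1, threshold = 0), "threshold")
})

test_that("isoform selection prefers the strongest TSSR then H3K4me3 rescue", {
  iso <- rbind(gene_models("g", "g.1", "c1", "+", tss = 50000, tes = 60000),
               gene_models("g", "g.2", "c1", "+", tss = 52000, tes = 60000))
  # strong signal at isoform 1 TSSR only
  chip <- lib_from_positions(seq(50000, 50290, by = 10),
                             chrom = "c1", mapped_total = 1e6)
  input <- lib_from_positions(200000, chrom = "c1", mapped_total = 1e6)
  sel <- select_primary_isoform(iso, chip, input)
  expect_equal(sel$isoform_id, "g.1")
  expect_equal(sel$route, "rnap2_tssr")

  # no RNAP2 signal anywhere: H3K4me3 rescue at isoform 2's promoter
  chip0 <- lib_from_positions(200000, chrom = "c1", mapped_total = 1e6)
  k4 <- lib_from_positions(seq(51600, 52300, by = 4), chrom = "c1",
                           mapped_total = 1e6)
  k4in <- lib_from_positions(300000, chrom = "c1", mapped_total = 1e6)
  sel2 <- select_primary_isoform(iso, chip0, input, k4, k4in)
  expect_equal(sel2$isoform_id, "g.2")
  expect_equal(sel2$route, "h3k4me3_rescue")

  # neither route: unassigned
  sel3 <- select_primary_isoform(iso, chip0, input, k4in, k4in)
  expect_equal(sel3$route, "unassigned")
  expect_true(is.na(sel3$isoform_id))
})

test_that("isoforms sharing the winning TSS resolve to the longest", {
  iso <- rbind(gene_models("g", "g.short", "c1", "+", tss = 50000, tes = 55000),
               gene_models("g", "g.long", "c1", "+", tss = 50000, tes = 60000))
  chip <- lib_from_positions(seq(50000, 50290, by = 10), chrom = "c1",
                             mapped_total = 1e6)
  input <- lib_from_positions(200000, chrom = "c1", mapped_total = 1e6)
  sel <- select_primary_isoform(iso, chip, input)
  expect_equal(sel$isoform_id, "g.long")
})

test_that("pipeline PI equals the brute-force oracle on synthetic data", {
  ann <- generate_annotation(30, seed = 5)
  set.seed(6)
  pp <- exp(runif(30, log(0.5), log(16)))
  libs <- simulate_chip_library(ann$genes, pp, depth = 5e4,
                                chrom_length = ann$chrom_length, seed = 7)
  pt <- pause_index(ann$genes, libs$chip, libs$input, filter = FALSE)
  oracle <- oracle_pi_table(ann$genes, libs$chip, libs$input)
  expect_identical(is.na(pt$pi), is.na(oracle))
  expect_equal(pt$pi, oracle)
})

test_that("PI is invariant to replicating the library k-fold", {
  ann <- generate_annotation(10, seed = 9)
  libs <- simulate_chip_library(ann$genes, 4, depth = 2e4,
                                chrom_length = ann$chrom_length, seed = 10)
  k <- 3L
  rep_lib <- function(lib) {
    read_library(lib$reads[rep(seq_len(nrow(lib$reads)), k), ],
                 mapped_total = k * lib$mapped_total)
  }
  pt1 <- pause_index(ann$genes, libs$chip, libs$input, filter = FALSE)
  pt2 <- pause_index(ann$genes, rep_lib(libs$chip), rep_lib(libs$input),
                     filter = FALSE)
  expect_equal(pt2$pi, pt1$pi)
  # without dedup the densities themselves are also invariant
  tr <- tssr_region(ann$genes)
  expect_equal(region_density(rep_lib(libs$chip), rep_lib(libs$input), tr,
                              dedup = FALSE),
               region_density(libs$chip, libs$input, tr, dedup = FALSE))
})

test_that("adding TSSR-only chip reads never decreases PI", {
  ann <- generate_annotation(8, seed = 11)
  libs <- simulate_chip_library(ann$genes, 2, depth = 5e4,
                                input_fraction = 0,
                                chrom_length = ann$chrom_length, seed = 12)
  pt0 <- pause_index(ann$genes, libs$chip, libs$input, filter = FALSE)
  tr <- tssr_region(ann$genes)
  set.seed(13)
  for (i in seq_len(nrow(ann$genes))) {
    extra <- lib_from_positions(
      seq(tr$start[i], tr$end[i] - 1, length.out = 25), chrom = "chrS")
    chip2 <- read_library(rbind(libs$chip$reads, extra$reads),
                          libs$chip$mapped_total + 25)
    pt1 <- pause_index(ann$genes, chip2, libs$input, filter = FALSE)
    if (!is.na(pt0$pi[i]) && !is.na(pt1$pi[i])) {
      expect_gte(pt1$pi[i], pt0$pi[i])
    }
  }
})

test_that("PI ranks average ties and put missing values at the bottom", {
  m <- matrix(c(1.5, NA, 3.0, 3.0,
                2.0, 0.5, NA, NA), ncol = 2,
              dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  r <- pi_rank_matrix(m)
  expect_equal(unname(r[, 1]), c(2, 1, 3.5, 3.5))
  expect_equal(unname(r[, 2]), c(4, 3, 1.5, 1.5))
})

test_that("cross-sample sets reproduce a hand-enumerated example", {
  # 4 genes, 2 samples; paused anywhere -> all_paused
  m <- matrix(c(0.5, 2.5, 8.0, NA,
                0.7, 2.2, 1.0, 3.0), ncol = 2,
              dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  sets <- cross_sample_pause_sets(m)
  expect_setequal(sets$all_paused, c("g2", "g3", "g4"))
  # ranks s1: g4=1(NA), g1=2, g2=3, g3=4; s2: g3=2? -> (0.7,2.2,1.0,3.0)
  # gives ranks 1,3,2,4; medians: g1=1.5, g2=3, g3=3, g4=2.5
  expect_equal(unname(sets$median_rank), c(1.5, 3, 3, 2.5))
  # ordered all_paused by median rank: g4 (2.5) < g2 = g3 (3)
  expect_equal(sets$low, "g4")
  expect_setequal(sets$high, c("g2", "g3"))
  expect_error(cross_sample_pause_sets(m[, 1, drop = FALSE]), "2 samples")
})
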