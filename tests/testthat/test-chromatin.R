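test_that("promoter enrichment approximates log2 fold at high counts", {
  gm <- gene_models("g", chrom = "chr1", strand = "+",
                    tss = 50000, tes = 60000)
  prom <- promoter_region(gm)
  # chip density exactly 4x input with large counts -> ~2
  chip <- lib_from_positions(seq(49500, 50499, length.out = 800),
                             mapped_total = 1e6)
  input <- lib_from_positions(seq(49500, 50499, length.out = 200),
                              mapped_total = 1e6)
  expect_equal(promoter_enrichment(chip, input, prom), 2, tolerance = 0.02)
  # chip = input -> exactly 0
  expect_equal(promoter_enrichment(chip, chip, prom), 0)
  # zero input reads: pseudocount keeps the value finite and positive
  none <- lib_from_positions(900000, mapped_total = 1e6)
  v <- promoter_enrichment(chip, none, prom)
  expect_true(is.finite(v) && v > 0)
})

test_that("the linear model recovers planted coefficients and R^2", {
  sim <- simulate_enrichment_model(2000, c(H2AZ = 0.8, H3K4me3 = -0.3),
                                   noise_sd = 0.5, seed = 3)
  fit <- fit_pi_linear_model(sim$enrichment, 2^sim$log2_pi)
  expect_lt(abs(fit$coefficients[["H2AZ"]] - 0.8), 0.1)
  expect_lt(abs(fit$coefficients[["H3K4me3"]] - (-0.3)), 0.1)
  # planted signal fraction: var(Xb) / (var(Xb) + noise^2)
  planted_r2 <- (0.8^2 + 0.3^2) / (0.8^2 + 0.3^2 + 0.25)
  expect_lt(abs(fit$r_squared - planted_r2), 0.05)
  expect_equal(fit$n, 2000)
})

test_that("single centred predictor reduces to the closed form", {
  set.seed(80)
  x <- scale(rnorm(200), scale = FALSE)
  y <- 2^(0.4 * x + rnorm(200, 0, 0.3))
  fit <- fit_pi_linear_model(matrix(x, dimnames = list(NULL, "m")), y)
  beta_hat <- cov(x, log2(y)) / var(x)
  expect_equal(unname(fit$coefficients[["m"]]), unname(beta_hat[1, 1]),
               tolerance = 1e-10)
})

test_that("degenerate designs are rejected or flagged", {
  set.seed(81)
  x <- rnorm(100)
  X <- cbind(a = x, b = x)  # duplicated predictor
  expect_error(fit_pi_linear_model(X, 2^rnorm(100)), "rank-deficient")
  X2 <- cbind(a = x, b = x + rnorm(100, 0, 1e-9))
  expect_warning(fit_pi_linear_model(X2, 2^rnorm(100)), "collinear")
  expect_error(fit_pi_linear_model(matrix(rnorm(30), 15, 2,
                                          dimnames = list(NULL, c("a", "b"))),
                                   2^rnorm(15)), "10x")
})

test_that("expression joins the model when requested", {
  set.seed(82)
  X <- matrix(rnorm(1000), 500, 2, dimnames = list(NULL, c("a", "b")))
  fpkm <- 10^rnorm(500, 1, 0.5)
  y <- 2^(0.5 * X[, 1] + 0.8 * log10(fpkm) + rnorm(500, 0, 0.3))
  fit <- fit_pi_linear_model(X, y, expression = fpkm)
  expect_true("log10_fpkm" %in% names(fit$coefficients))
  expect_lt(abs(fit$coefficients[["log10_fpkm"]] - 0.8), 0.1)
})

test_that("TSS profiles are flat for uniform reads and peak at planted sites", {
  gm <- do.call(rbind, lapply(1:20, function(i) {
    gene_models(paste0("g", i), chrom = "chrS",
                strand = if (i %% 2) "+" else "-",
                tss = if (i %% 2) i * 30000 else i * 30000 + 10000,
                tes = if (i %% 2) i * 30000 + 10000 else i * 30000)
  }))
  set.seed(83)
  uni <- lib_from_positions(sample.int(700000, 1e5, TRUE), chrom = "chrS",
                            strand = sample(c("+", "-"), 1e5, TRUE))
  pr <- tss_profile(uni, gm, window = 2000, bin = 50)
  expect_equal(nrow(pr), 80)
  expect_lt(diff(range(pr$rpm)) / mean(pr$rpm), 1.0)  # Monte-Carlo flat
  expect_lt(diff(range(pr$rpm_smooth)) / mean(pr$rpm_smooth), 0.25)

  # all reads exactly at each TSS: single central-bin peak before smoothing
  tss_pos <- ifelse(gm$strand == "+", gm$tss, gm$tss - 1)
  spike <- lib_from_positions(tss_pos, chrom = "chrS")
  pr2 <- tss_profile(spike, gm, window = 2000, bin = 50)
  expect_equal(pr2$offset[which.max(pr2$rpm)], 0)
  expect_equal(sum(pr2$rpm > 0), 1)
  expect_error(tss_profile(uni, gm, window = 2000, bin = 33), "multiple")
})

test_that("profiles of strand-mirrored genes mirror exactly", {
  L <- 400000
  plus <- gene_models("p", chrom = "chrS", strand = "+",
                      tss = 100000, tes = 110000)
  minus <- gene_models("m", chrom = "chrS", strand = "-",
                       tss = L - 100000, tes = L - 110000)
  set.seed(84)
  pos <- sample.int(30000, 3000, TRUE) + 85000
  libp <- lib_from_positions(pos, chrom = "chrS", strand = "+", width = 1)
  # mirror the 5' positions (width-1 reads keep 5' = start for + strand)
  libm <- lib_from_positions(L - 1 - pos, chrom = "chrS", strand = "-",
                             width = 1)
  prp <- tss_profile(libp, plus, window = 2000, bin = 50)
  prm <- tss_profile(libm, minus, window = 2000, bin = 50)
  expect_equal(prm$rpm, prp$rpm)
})

test_that("doubling a duplicate-free library and its total keeps the profile", {
  gm <- gene_models("g", chrom = "chrS", strand = "+",
                    tss = 50000, tes = 60000)
  pos <- seq(48000, 52000, by = 7)
  lib1 <- lib_from_positions(pos, chrom = "chrS", mapped_total = 1e5)
  lib2 <- read_library(lib1$reads[rep(seq_along(pos), 2), ],
                       mapped_total = 2e5)
  p1 <- tss_profile(lib1, gm)
  p2 <- tss_profile(lib2, gm)
  expect_equal(p2$rpm, p1$rpm)
})

test_that("density-change classification follows the fold rules", {
  before <- data.frame(gene_id = paste0("g", 1:5),
                       tssr_density = c(1, 1, 1, 1, -0.2),
                       gb_density = c(1, 1, 1, 1, 1))
  after <- data.frame(gene_id = paste0("g", 1:5),
                      tssr_density = c(2.5, 1.1, 2.6, 1.0, 1),
                      gb_density = c(1.0, 0.3, 0.3, 0.9, 1))
  res <- classify_density_change(before, after)
  expect_equal(res$label, c("tssr_up", "gb_down", "both", "none"))
  expect_equal(attr(res, "n_excluded"), 1)  # negative density excluded
  # before = after: everything is "none"
  same <- classify_density_change(before[1:4, ], before[1:4, ])
  expect_true(all(same$label == "none"))
  # symmetric mode counts changes in either direction
  sym <- classify_density_change(before[1:4, ], after[1:4, ],
                                 symmetric = TRUE)
  expect_equal(sym$label[1], "tssr_up")
})
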