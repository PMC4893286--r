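test_that("expressed/paused overlap partitions the gene universe", {
  pi <- c(3, 1, 5, NA, 2.5, 0.4, 8, NA, 1.2, 4)
  fpkm <- c(2, 3, 0.5, 4, 1, 9, 2, 0.2, 5, 1.5)
  ov <- expressed_paused_overlap(pi, fpkm)
  expect_equal(ov$all, 10)
  expect_equal(ov$expressed, 8)       # fpkm >= 1
  expect_equal(ov$expressed_paused, 4)  # pi > 2 among those
  ov2 <- expressed_paused_overlap(pi, fpkm, fpkm_min = Inf)
  expect_equal(ov2$expressed, 0)
  expect_equal(ov2$expressed_paused, 0)
})

test_that("the PI-expression trend recovers a planted hill", {
  set.seed(60)
  pi <- 10^runif(1500, -1.5, 1.5)
  fpkm <- 10^(2 - 1.3 * (log10(pi) - 0.7)^2 + rnorm(1500, 0, 0.3))
  tr <- pi_expression_trend(pi, fpkm)
  peak <- tr$grid$x[which.max(tr$grid$fit)]
  expect_lt(abs(peak - 0.7), 0.15)
  # bands clipped to the mean curve
  expect_true(all(tr$grid$lower <= tr$grid$fit + 1e-9))
  expect_true(all(tr$grid$upper >= tr$grid$fit - 1e-9))
  expect_error(pi_expression_trend(pi[1:30], fpkm[1:30]), ">= 50")
})

test_that("constant expression gives a flat trend with collapsed bands", {
  set.seed(61)
  pi <- 10^runif(300, -1, 1)
  fpkm <- rep(5, 300)
  tr <- pi_expression_trend(pi, fpkm)
  expect_lt(diff(range(tr$grid$fit)), 1e-6)
  expect_lt(max(abs(tr$grid$lower - log10(5))), 1e-6)
  expect_lt(max(abs(tr$grid$upper - log10(5))), 1e-6)
})

test_that("a monotone relation yields a monotone interior fit", {
  set.seed(62)
  pi <- 10^runif(1000, -1, 1)
  fpkm <- 10^(0.8 * log10(pi) + rnorm(1000, 0, 0.2))
  tr <- pi_expression_trend(pi, fpkm)
  qs <- quantile(log10(pi), c(0.05, 0.95))
  inner <- tr$grid$fit[tr$grid$x >= qs[1] & tr$grid$x <= qs[2]]
  expect_true(all(diff(inner) > -1e-6))
})

test_that("single-cell CV analysis is scale invariant and detects dispersion", {
  ids <- paste0("g", 1:600)
  paused <- rep(c(TRUE, FALSE), 300)
  cells <- simulate_expression(ids, "single_cell", n_cells = 60,
                               mean_fpkm = rep(10, 600),
                               cv_group = ifelse(paused, "low", "high"),
                               dispersion = c(low = 0.05, high = 0.2),
                               seed = 63)
  res <- single_cell_cv(cells, paused)
  expect_true(all(res$p_value < 0.01, na.rm = TRUE))
  expect_true(all(res$median_cv_paused < res$median_cv_nonpaused))
  # constant gene: CV exactly 0
  cells2 <- rbind(cells, matrix(7, 1, 60,
                                dimnames = list("const", colnames(cells))))
  cv <- attr(single_cell_cv(cells2, c(paused, TRUE)), "cv")
  expect_equal(unname(cv["const"]), 0)
  # global rescaling leaves all CVs unchanged
  res3 <- single_cell_cv(cells * 3, paused)
  expect_equal(res3$p_value, res$p_value)
  expect_equal(attr(res3, "cv"), attr(single_cell_cv(cells, paused), "cv"))
  expect_error(single_cell_cv(cells[, 1, drop = FALSE], paused), "2 cells")
})

test_that("bins with too few genes in either group give missing p", {
  ids <- paste0("g", 1:100)
  paused <- c(TRUE, rep(FALSE, 99))  # almost no paused genes anywhere
  cells <- simulate_expression(ids, "single_cell", n_cells = 20, seed = 64,
                               cv_group = rep("high", 100))
  res <- single_cell_cv(cells, paused)
  expect_true(all(is.na(res$p_value)))
})

test_that("response classification reproduces hand-derived labels", {
  tc <- rbind(
    early1 = c(2, 5, 4, 3),      # 2.5x at 1 h
    late1 = c(3, 3.2, 7, 6),     # 2x only after 1 h
    down1 = c(4, 3.5, 1.5, 3),   # 2.7x decrease at 4 h
    flat1 = c(3, 3.2, 3.5, 2.9), # expressed, never 2-fold
    off1 = c(0.4, 0.5, 0.3, 0.2),# never reaches FPKM 1
    zero1 = c(0, 0, 5, 4)        # zero baseline, later signal: up, late
  )
  colnames(tc) <- c("0", "1", "4", "12")
  lab <- classify_response(tc)
  expect_equal(lab$label,
               c("early", "late", "down", "non_responsive", "excluded",
                 "late"))
  # scaling the whole course leaves labels unchanged
  lab2 <- classify_response(tc * 5)
  expect_equal(lab2$label[1:4], lab$label[1:4])
  expect_error(classify_response(tc[, c(2, 1, 3, 4)]), "baseline")
})

test_that("a gene down early and up late is labelled by its first event", {
  tc <- rbind(g1 = c(4, 1.5, 10, 10),  # halves at 1 h before rising
              g2 = c(4, 9, 1.5, 4))    # doubles at 1 h before falling
  colnames(tc) <- c("0", "1", "4", "12")
  lab <- classify_response(tc)
  expect_equal(lab$label, c("down", "early"))
})

test_that("PI shift tests are seed-deterministic and detect planted shifts", {
  set.seed(65)
  n <- 400
  labels <- data.frame(gene_id = paste0("g", 1:n),
                       label = c(rep("early", 60), rep("late", 40),
                                 rep("down", 20), rep("non_responsive", 280)))
  base_pi <- 2^rnorm(n, 1, 0.8)
  pi_mat <- cbind(`0` = base_pi, `1` = base_pi, `4` = base_pi)
  # plant a halving of PI for early genes at 1 h (pause release)
  pi_mat[1:60, "1"] <- pi_mat[1:60, "1"] * 0.5
  rownames(pi_mat) <- labels$gene_id
  res1 <- pi_shift_test(pi_mat, labels, seed = 9)
  res2 <- pi_shift_test(pi_mat, labels, seed = 9)
  expect_identical(res1, res2)
  early_1h <- res1[res1$class == "early" & res1$time == 1, ]
  expect_lt(early_1h$p_value, 0.001)
  # non-responsive genes were subsampled to the responsive count
  expect_equal(res1$n2[1], 120)
  # unchanged classes show no strong shift at unshifted time points
  late_rows <- res1[res1$class == "late", ]
  expect_true(all(late_rows$p_value > 0.05))
})

test_that("small classes give missing p-values", {
  labels <- data.frame(gene_id = paste0("g", 1:10),
                       label = c("early", "early",
                                 rep("non_responsive", 8)))
  pi_mat <- matrix(2^rnorm(20), 10, 2, dimnames = list(labels$gene_id,
                                                       c("0", "1")))
  res <- pi_shift_test(pi_mat, labels, seed = 1)
  expect_true(is.na(res$p_value[res$class == "early"]))
})
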