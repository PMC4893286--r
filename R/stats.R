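## Shared statistics: Mann-Whitney U, signed -log10 scoring, Fisher
## gene-set enrichment, Bonferroni FWER gating, Storey q-values.

P_FLOOR <- 1e-300

#' Mann-Whitney U test
#'
#' Two-sample rank test. Uses the exact null distribution when the groups
#' are small (n1 + n2 <= 20) and tie-free, otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return A list of class \code{pk_test}: \code{statistic} (U of the
#'   first group), \code{p_value}, \code{n1}, \code{n2}, \code{method}
#'   ("mwu_exact" or "mwu_normal").
#' @export
mann_whitney <- function(x, y, alternative = "two.sided") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 20L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                            exact = exact, correct = TRUE))
  structure(list(statistic = unname(wt$statistic),
                 p_value = max(wt$p.value, P_FLOOR),
                 n1 = length(x), n2 = length(y),
                 method = if (exact) "mwu_exact" else "mwu_normal"),
            class = "pk_test")
}

#' @export
print.pk_test <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic),
      ", p = ", format(x$p_value, digits = 4),
      " (n1 = ", x$n1, ", n2 = ", x$n2, ")\n", sep = "")
  if (!is.null(x$odds_ratio)) {
    cat("  odds ratio =", format(x$odds_ratio, digits = 4), "\n")
  }
  invisible(x)
}

#' Signed -log10(p) enrichment score
#'
#' Mann-Whitney score with a sign: positive when the first group is
#' stochastically greater (its rank sum meets or exceeds the null
#' expectation, so "no difference" also gets the positive sign), negative
#' otherwise. P-values are floored at 1e-300 so no infinities are emitted.
#'
#' @param x,y Numeric vectors; \code{x} is the focal (e.g. paused) group.
#' @return Signed numeric score; \code{abs(score) == -log10(p)}.
#' @export
signed_log10_score <- function(x, y) {
  tst <- mann_whitney(x, y, alternative = "two.sided")
  n1 <- tst$n1
  r <- rank(c(x[!is.na(x)], y[!is.na(y)]))
  r1 <- sum(r[seq_len(n1)])
  expected <- n1 * (n1 + tst$n2 + 1) / 2
  sgn <- if (r1 >= expected) 1 else -1
  sgn * abs(log10(tst$p_value))
}

#' Fisher's exact gene-set enrichment
#'
#' One-sided (enrichment) hypergeometric test of the overlap between a
#' test gene set and an annotation set within a universe.
#'
#' @param test_set,annotation_set Character vectors of gene ids (subsets
#'   of \code{universe}; ids outside the universe are dropped).
#' @param universe Character vector, the gene universe (non-empty).
#' @return \code{pk_test} with \code{p_value}, \code{odds_ratio} (sample
#'   odds ratio of the 2x2 table) and the table counts.
#' @export
fisher_geneset <- function(test_set, annotation_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("universe must be non-empty")
  test_set <- intersect(unique(test_set), universe)
  annotation_set <- intersect(unique(annotation_set), universe)
  a <- length(intersect(test_set, annotation_set))
  b <- length(test_set) - a
  k <- length(annotation_set) - a
  d <- length(universe) - a - b - k
  tab <- matrix(c(a, b, k, d), nrow = 2)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  or <- (a * d) / (b * k)  # sample odds ratio; may be Inf/NaN on zero margins
  structure(list(statistic = a, p_value = max(p, P_FLOOR),
                 n1 = length(test_set), n2 = length(annotation_set),
                 method = "fisher", odds_ratio = or,
                 table = c(overlap = a, test_only = b,
                           annotation_only = k, neither = d)),
            class = "pk_test")
}

#' Multiple-testing correction
#'
#' Either a Bonferroni family-wise error-rate gate (pass iff
#' \code{p <= alpha / m}) or Storey q-values (smoother pi0 estimate over a
#' lambda grid, falling back to Benjamini-Hochberg with pi0 = 1 when the
#' estimate is unstable). The policy used throughout the pipeline is the
#' FWER gate for small families and q-values when more than 10 hypotheses
#' are tested.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @param mode "fwer_gate" or "qvalue".
#' @param alpha FWER alpha (default 0.05).
#' @return data.frame with the input p-values plus, for \code{fwer_gate},
#'   \code{threshold} and \code{passes_fwer}; for \code{qvalue},
#'   \code{q_value} (attributes \code{pi0} and \code{fallback}).
#' @export
multiple_testing <- function(p_values, mode = c("fwer_gate", "qvalue"),
                             alpha = 0.05) {
  mode <- match.arg(mode)
  ok <- is.na(p_values) | (p_values > 0 & p_values <= 1)
  if (!all(ok)) stop("p-values must lie in (0, 1]")
  m <- sum(!is.na(p_values))
  if (m < 1L) stop("need at least one non-missing p-value")
  if (mode == "fwer_gate") {
    thr <- alpha / m
    data.frame(p_value = p_values, threshold = thr,
               passes_fwer = !is.na(p_values) & p_values <= thr)
  } else {
    q <- storey_qvalue(p_values)
    out <- data.frame(p_value = p_values, q_value = as.numeric(q))
    attr(out, "pi0") <- attr(q, "pi0")
    attr(out, "fallback") <- attr(q, "fallback")
    out
  }
}

## Storey q-values: pi0 from the smoother method on lambda = 0.05..0.95,
## q = pi0 * BH-adjusted p (monotone by construction). Unstable pi0
## (non-finite, <= 0 or > 1, e.g. tiny families) falls back to BH (pi0=1).
storey_qvalue <- function(p) {
  obs <- !is.na(p)
  pv <- p[obs]
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0l <- vapply(lambda, function(l) mean(pv > l) / (1 - l), 0)
  pi0 <- tryCatch({
    fit <- stats::smooth.spline(lambda, pi0l, df = 3)
    stats::predict(fit, x = max(lambda))$y
  }, error = function(e) NA_real_)
  fallback <- FALSE
  if (!is.finite(pi0) || pi0 <= 0 || pi0 > 1) {
    pi0 <- 1
    fallback <- TRUE
  }
  q <- rep(NA_real_, length(p))
  q[obs] <- pmin(pi0 * stats::p.adjust(pv, method = "BH"), 1)
  structure(q, pi0 = pi0, fallback = fallback)
}
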