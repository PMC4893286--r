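## Chromatin features: promoter mark enrichment, the multivariate linear
## model on log2 PI, TSS metagene profiles, and the knockdown
## density-change classifier.

#' Log2 promoter enrichment of a chromatin mark
#'
#' log2((chip rpm/bp + eps_chip) / (input rpm/bp + eps_input)) over the
#' promoter (+/-500 bp) of each gene, where each epsilon is one
#' read-equivalent for that library and region (1/length/(mapped/1e6)),
#' so the value is always finite.
#'
#' @param chip,input \code{read_library} objects (mapped_total > 0).
#' @param regions Promoter regions (e.g. \code{\link{promoter_region}}).
#' @param dedup Collapse PCR duplicates before counting (default FALSE:
#'   mark libraries are used as-is).
#' @return Numeric vector of log2 enrichments.
#' @export
promoter_enrichment <- function(chip, input, regions, dedup = FALSE) {
  if (chip$mapped_total <= 0 || input$mapped_total <= 0) {
    stop("mapped_total must be > 0")
  }
  len <- regions$end - regions$start
  cd <- count_in_regions(chip, regions, dedup) / len / (chip$mapped_total / 1e6)
  id <- count_in_regions(input, regions, dedup) / len / (input$mapped_total / 1e6)
  eps_c <- (1 / len) / (chip$mapped_total / 1e6)
  eps_i <- (1 / len) / (input$mapped_total / 1e6)
  log2((cd + eps_c) / (id + eps_i))
}

#' Build a gene x mark enrichment table
#'
#' @param genes Gene-model table (one row per gene: the primary isoform).
#' @param marks Named list; each element \code{list(chip =, input =)} of
#'   \code{read_library} objects.
#' @param flank Promoter half-width (default 500).
#' @param dedup Passed to \code{\link{promoter_enrichment}}.
#' @return Numeric matrix, genes x marks, gene ids as rownames.
#' @export
enrichment_table <- function(genes, marks, flank = 500, dedup = FALSE) {
  prom <- promoter_region(genes, flank)
  m <- vapply(marks, function(mk) {
    promoter_enrichment(mk$chip, mk$input, prom, dedup)
  }, numeric(nrow(genes)))
  rownames(m) <- genes$gene_id
  m
}

#' Linear model of log2 PI on chromatin-mark enrichments
#'
#' Ordinary least squares of log2 PI on per-mark log2 promoter
#' enrichments, optionally including log10 expression as a further
#' predictor. Complete cases only; requires at least 10 genes per
#' predictor. A rank-deficient design is an error naming the offending
#' columns; a near-collinear design (condition number > 1e6) attaches a
#' warning to the fit.
#'
#' @param enrichment Genes x marks numeric matrix.
#' @param pi PI vector (same gene order); log2-transformed internally,
#'   genes without a positive PI are dropped.
#' @param expression Optional FPKM vector; log10(FPKM) joins the
#'   predictors (genes with non-positive FPKM dropped).
#' @return list of class \code{pi_lm}: \code{coefficients} (named, incl.
#'   intercept), \code{r_squared}, \code{n}, \code{fit} (the \code{lm}),
#'   \code{collinearity_warning}.
#' @export
fit_pi_linear_model <- function(enrichment, pi, expression = NULL) {
  enrichment <- as.matrix(enrichment)
  stopifnot(nrow(enrichment) == length(pi))
  df <- data.frame(log2_pi = log2(ifelse(!is.na(pi) & pi > 0, pi, NA)),
                   enrichment, check.names = FALSE)
  if (!is.null(expression)) {
    df$log10_fpkm <- log10(ifelse(!is.na(expression) & expression > 0,
                                  expression, NA))
  }
  df <- df[stats::complete.cases(df) &
             apply(df, 1L, function(r) all(is.finite(r))), , drop = FALSE]
  k <- ncol(df) - 1L
  if (nrow(df) < 10L * k) {
    stop("need at least 10x more genes (", nrow(df),
         ") than predictors (", k, ")")
  }
  X <- stats::model.matrix(log2_pi ~ ., data = df)
  qx <- qr(X, tol = 1e-12)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; offending columns: ",
         paste(bad, collapse = ", "))
  }
  sv <- svd(scale(X[, -1L, drop = FALSE]))$d
  cond <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  coll <- cond > 1e6
  if (coll) warning("near-collinear predictors (condition number ",
                    format(cond, digits = 3), ")")
  fit <- stats::lm(log2_pi ~ ., data = df)
  structure(list(coefficients = stats::coef(fit),
                 r_squared = summary(fit)$r.squared,
                 n = nrow(df), fit = fit,
                 collinearity_warning = coll),
            class = "pi_lm")
}

#' @export
print.pi_lm <- function(x, ...) {
  cat("pi_lm: OLS of log2 PI on", length(x$coefficients) - 1L,
      "predictors; n =", x$n,
      "; R^2 =", format(x$r_squared, digits = 3), "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.pi_lm <- function(object, ...) object$coefficients

#' Mean TSS read-density profile for a gene set
#'
#' Bins strand-adjusted 5' read positions into fixed-width bins around
#' the TSS (strand-aware: upstream on the left), averages per-bin
#' reads-per-million over genes, and smooths with local regression
#' (span 0.1). Typically called per PI or expression quantile.
#'
#' @param lib A \code{read_library}.
#' @param genes Gene-model table (>= 1 gene).
#' @param window Half-window around the TSS in bp (default 2000).
#' @param bin Bin width in bp (default 50; 10 for deeply sequenced MNase
#'   libraries). \code{2 * window} must be a multiple of \code{bin}.
#' @param span Loess span (default 0.1).
#' @param dedup Collapse PCR duplicates (default FALSE).
#' @return data.frame: \code{offset} (bin start relative to TSS),
#'   \code{rpm}, \code{rpm_smooth}.
#' @export
tss_profile <- function(lib, genes, window = 2000, bin = 50, span = 0.1,
                        dedup = FALSE) {
  if (nrow(genes) < 1L) stop("need >= 1 gene")
  if ((2 * window) %% bin != 0) stop("window must be a multiple of bin")
  n_bins <- 2L * window / bin
  idx <- position_index(lib, dedup)
  counts <- numeric(n_bins)
  for (i in seq_len(nrow(genes))) {
    pos <- idx[[genes$chrom[i]]]
    if (is.null(pos) || length(pos) == 0L) next
    if (genes$strand[i] == "+") {
      lo <- genes$tss[i] - window
      sel <- pos[pos >= lo & pos < genes$tss[i] + window]
      off <- sel - genes$tss[i]
    } else {
      tss0 <- genes$tss[i] - 1  # first transcribed base
      sel <- pos[pos > tss0 - window & pos <= tss0 + window]
      off <- tss0 - sel
    }
    if (length(off) == 0L) next
    b <- floor((off + window) / bin) + 1L
    tab <- tabulate(b, nbins = n_bins)
    counts <- counts + tab
  }
  rpm <- counts / nrow(genes) / (lib$mapped_total / 1e6)
  xb <- seq_len(n_bins)
  sm <- stats::loess(rpm ~ xb, span = span)
  data.frame(offset = (xb - 1L) * bin - window,
             rpm = rpm, rpm_smooth = stats::predict(sm, xb))
}

#' Classify per-gene RNAP2 density changes between two conditions
#'
#' Labels each shared gene by whether, after a perturbation, its TSSR
#' density rose more than \code{fold}-fold (\code{tssr_up}), its
#' gene-body density fell more than \code{fold}-fold (\code{gb_down}),
#' \code{both}, or \code{none}. With \code{symmetric = TRUE} a change in
#' either direction beyond \code{fold}-fold counts for each region.
#' Genes with a non-positive density in either condition are excluded
#' (counted in attribute \code{n_excluded}).
#'
#' @param before,after \code{pi_table}s (or data.frames with
#'   \code{gene_id}, \code{tssr_density}, \code{gb_density}).
#' @param fold Fold-change threshold (default 2).
#' @param symmetric Use absolute fold change in both regions.
#' @return data.frame: \code{gene_id}, \code{tssr_fold}, \code{gb_fold},
#'   \code{label}.
#' @export
classify_density_change <- function(before, after, fold = 2,
                                    symmetric = FALSE) {
  shared <- intersect(before$gene_id, after$gene_id)
  b <- before[match(shared, before$gene_id), ]
  a <- after[match(shared, after$gene_id), ]
  okb <- !is.na(b$tssr_density) & b$tssr_density > 0 &
    !is.na(b$gb_density) & b$gb_density > 0
  oka <- !is.na(a$tssr_density) & a$tssr_density > 0 &
    !is.na(a$gb_density) & a$gb_density > 0
  ok <- okb & oka
  tssr_fold <- a$tssr_density[ok] / b$tssr_density[ok]
  gb_fold <- a$gb_density[ok] / b$gb_density[ok]
  if (symmetric) {
    t_up <- pmax(tssr_fold, 1 / tssr_fold) > fold
    g_dn <- pmax(gb_fold, 1 / gb_fold) > fold
  } else {
    t_up <- tssr_fold > fold
    g_dn <- (1 / gb_fold) > fold
  }
  label <- ifelse(t_up & g_dn, "both",
                  ifelse(t_up, "tssr_up",
                         ifelse(g_dn, "gb_down", "none")))
  out <- data.frame(gene_id = shared[ok], tssr_fold = tssr_fold,
                    gb_fold = gb_fold, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(!ok)
  out
}
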