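## Promoter sequence composition: GC content, CpG ratio, GC-correction of
## TSSR densities, and signed k-mer enrichment between promoter sets.

#' GC content of sequences
#'
#' Fraction of G + C among non-N bases; N bases are excluded from both
#' numerator and denominator. All-N (or empty) sequences give NA.
#'
#' @param seqs Character vector of DNA sequences (A/C/G/T/N).
#' @return Numeric vector of fractions in [0, 1].
#' @export
gc_content <- function(seqs) {
  if (any(!nzchar(seqs))) stop("sequences must be non-empty")
  x <- Biostrings::DNAStringSet(seqs)
  freq <- Biostrings::alphabetFrequency(x, baseOnly = TRUE)
  informative <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  gc <- freq[, "C"] + freq[, "G"]
  ifelse(informative > 0, gc / informative, NA_real_)
}

#' CpG ratio of promoter sequences
#'
#' Observed over expected dinucleotide measure on a fixed-length promoter:
#' (count of CG and GC dinucleotides / N) / ((#C/N) * (#G/N)), counting
#' overlapping occurrences of both orientations. Missing when the
#' sequence has no C or no G.
#'
#' @param seqs Character vector of promoter sequences, each of length
#'   \code{n} (default 1000; other lengths are an error).
#' @param n Required promoter length.
#' @return Numeric vector (NA where undefined).
#' @export
cpg_ratio <- function(seqs, n = 1000) {
  if (any(nchar(seqs) != n)) {
    stop("promoter sequences must be exactly ", n, " bp")
  }
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1L]]
    nc <- sum(ch == "C"); ng <- sum(ch == "G")
    if (nc == 0 || ng == 0) return(NA_real_)
    a <- ch[-length(ch)]; b <- ch[-1L]
    dinuc <- sum((a == "C" & b == "G") | (a == "G" & b == "C"))
    (dinuc / n) / ((nc / n) * (ng / n))
  }, 0, USE.NAMES = FALSE)
}

#' Extract the TSSR sub-sequence of a promoter
#'
#' Promoter sequences cover offsets -500..+499 around the TSS on the
#' promoter strand; the TSSR (-50..+300) is therefore positions 451..800.
#'
#' @param promoters Character vector of 1000 bp promoter sequences.
#' @return Character vector of 350 bp TSSR sequences.
#' @export
tssr_subsequence <- function(promoters) {
  if (any(nchar(promoters) != 1000)) {
    stop("promoter sequences must be exactly 1000 bp")
  }
  substr(promoters, 451, 800)
}

#' GC-correct TSSR densities
#'
#' Removes the dependence of log10 TSSR density on TSSR GC content by
#' fitting a smoothing spline of log10 density on GC fraction and keeping
#' the residuals, re-centred at the global mean log10 density (so the
#' corrected values stay on the original scale). Non-positive densities
#' are excluded from the fit and left missing.
#'
#' @param tssr_density Numeric vector of background-subtracted TSSR
#'   densities (rpm/bp).
#' @param tssr_gc GC fraction of each gene's TSSR sequence.
#' @return Numeric vector of corrected densities (NA where the input
#'   density was non-positive or missing).
#' @export
gc_correct_tssr <- function(tssr_density, tssr_gc) {
  ok <- !is.na(tssr_density) & tssr_density > 0 & !is.na(tssr_gc)
  if (sum(ok) < 20L) stop("need >= 20 genes with positive TSSR density")
  logd <- log10(tssr_density[ok])
  fit <- stats::smooth.spline(tssr_gc[ok], logd)
  predicted <- stats::predict(fit, x = tssr_gc[ok])$y
  out <- rep(NA_real_, length(tssr_density))
  out[ok] <- 10^((logd - predicted) + mean(logd))
  out
}

#' Signed k-mer enrichment between paused and other promoters
#'
#' Counts overlapping occurrences of every k-mer on the promoter strand of
#' each sequence, compares the per-promoter count distributions between
#' the two groups with a two-sided Mann-Whitney U test, and scores each
#' k-mer as sign * -log10(p): positive when counts are greater in the
#' paused group (or when no difference is detected), negative otherwise.
#'
#' @param paused_promoters,other_promoters Character vectors of promoter
#'   sequences (both non-empty).
#' @param k K-mer length, 5 or 6.
#' @return data.frame of class \code{kmer_scores}, ordered by decreasing
#'   score: \code{kmer}, \code{score}, \code{p_value}, \code{gc_fraction},
#'   \code{has_cpg} (contains "CG"), \code{has_tata} (contains "TATA").
#' @export
kmer_enrichment <- function(paused_promoters, other_promoters, k = 6) {
  if (!k %in% c(5L, 6L)) stop("k must be 5 or 6")
  if (length(paused_promoters) == 0L || length(other_promoters) == 0L) {
    stop("both promoter groups must be non-empty")
  }
  cnt_p <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(paused_promoters), width = k)
  cnt_o <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(other_promoters), width = k)
  kmers <- colnames(cnt_p)
  n1 <- nrow(cnt_p); n2 <- nrow(cnt_o)
  use_normal <- n1 > 50L && n2 > 50L
  score <- numeric(length(kmers))
  pval <- numeric(length(kmers))
  for (j in seq_along(kmers)) {
    x <- cnt_p[, j]; y <- cnt_o[, j]
    if (use_normal) {
      res <- mwu_normal_vec(x, y)
      p <- res$p; r1 <- res$r1; expected <- res$expected
    } else {
      tst <- mann_whitney(x, y)
      p <- tst$p_value
      r <- rank(c(x, y))
      r1 <- sum(r[seq_len(n1)])
      expected <- n1 * (n1 + n2 + 1) / 2
    }
    p <- max(p, P_FLOOR)
    pval[j] <- p
    score[j] <- (if (r1 >= expected) 1 else -1) * abs(log10(p))
  }
  kg <- vapply(kmers, function(s) {
    ch <- strsplit(s, "")[[1L]]
    mean(ch %in% c("G", "C"))
  }, 0, USE.NAMES = FALSE)
  out <- data.frame(kmer = kmers, score = score, p_value = pval,
                    gc_fraction = kg,
                    has_cpg = grepl("CG", kmers, fixed = TRUE),
                    has_tata = grepl("TATA", kmers, fixed = TRUE),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$kmer), ]
  rownames(out) <- NULL
  class(out) <- c("kmer_scores", "data.frame")
  out
}

## Normal-approximation MWU (tie + continuity corrected), matching
## stats::wilcox.test's large-sample branch; used for the 4^k-way k-mer
## scan where per-call overhead matters.
mwu_normal_vec <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  r1 <- sum(r[seq_len(n1)])
  u <- r1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  nties <- table(r)
  sigma <- sqrt((n1 * n2 / 12) *
                  ((n1 + n2 + 1) -
                     sum(nties^3 - nties) / ((n1 + n2) * (n1 + n2 - 1))))
  z <- u - mu
  corr <- sign(z) * 0.5
  z <- (z - corr) / sigma
  p <- if (sigma == 0) 1 else 2 * min(stats::pnorm(z),
                                      stats::pnorm(z, lower.tail = FALSE))
  list(p = min(p, 1), r1 = r1, expected = n1 * (n1 + n2 + 1) / 2)
}
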