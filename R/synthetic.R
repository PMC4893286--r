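## Synthetic-data generators. Every generator is a pure function of its
## parameters and seed; truth labels ride along so each pipeline stage can
## be checked against planted ground truth without external data.

#' Generate a synthetic gene annotation with promoter sequences
#'
#' Lays \code{n_genes} genes on one synthetic chromosome with alternating
#' strands and generous spacing, then optionally injects eligibility
#' violations: overlapping gene pairs, pairs closer than 3 kb, and genes
#' shorter than 1 kb. Promoter sequences (+/-500 bp of the TSS, promoter
#' strand) are drawn per position at a per-gene GC target, with optional
#' k-mers planted on top.
#'
#' @param n_genes Number of clean (eligible-by-construction) genes.
#' @param min_length,max_length Gene length range in bp.
#' @param min_spacing Gap between consecutive gene spans (bp); the default
#'   comfortably exceeds the 3 kb eligibility distance.
#' @param n_overlapping_pairs,n_close_pairs,n_short_genes Planted
#'   violations (ineligible by construction; truth-labelled).
#' @param gc_range Per-gene promoter GC targets are drawn uniformly from
#'   this range.
#' @param planted_kmer Optional k-mer string to plant into promoters.
#' @param kmer_counts Integer vector (length \code{n_genes}) of planted
#'   occurrences per clean gene; ignored unless \code{planted_kmer} set.
#' @param chrom_length Optional chromosome length; error if too short for
#'   the layout. Default: computed from the layout.
#' @param seed Integer RNG seed; recorded in the output.
#' @return list with \code{genes} (gene-model table), \code{promoters}
#'   (named character vector, 1000 bp each), \code{truth} (per-gene
#'   \code{eligible_truth}, \code{gc_target}, \code{kmer_count}),
#'   \code{chrom_length}, \code{seed}.
#' @export
generate_annotation <- function(n_genes, min_length = 2000, max_length = 10000,
                                min_spacing = 10000,
                                n_overlapping_pairs = 0, n_close_pairs = 0,
                                n_short_genes = 0,
                                gc_range = c(0.35, 0.65),
                                planted_kmer = NULL, kmer_counts = NULL,
                                chrom_length = NULL, seed = 1) {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  set.seed(seed)
  lens <- round(stats::runif(n_genes, min_length, max_length))
  gaps <- round(stats::runif(n_genes, min_spacing, min_spacing * 1.5))
  # leave headroom at chromosome start for promoter/TSSR/3kb extensions
  starts <- 5000 + cumsum(c(0, lens[-n_genes] + gaps[-n_genes]))
  ends <- starts + lens
  strand <- rep(c("+", "-"), length.out = n_genes)
  ids <- sprintf("g%04d", seq_len(n_genes))
  df <- data.frame(gene_id = ids, isoform_id = paste0(ids, ".1"),
                   chrom = "chrS", strand = strand,
                   start = starts, end = ends, stringsAsFactors = FALSE)
  truth_eligible <- rep(TRUE, n_genes)

  cursor <- max(ends) + min_spacing
  add_gene <- function(df, start, len, strand, tag) {
    id <- sprintf("g%s%02d", tag, sum(grepl(paste0("^g", tag), df$gene_id)) + 1L)
    rbind(df, data.frame(gene_id = id, isoform_id = paste0(id, ".1"),
                         chrom = "chrS", strand = strand,
                         start = start, end = start + len,
                         stringsAsFactors = FALSE))
  }
  for (i in seq_len(n_overlapping_pairs)) {
    len <- round(stats::runif(1, min_length, max_length))
    df <- add_gene(df, cursor, len, "+", "ov")
    df <- add_gene(df, cursor + round(len / 2), len, "-", "ov")
    cursor <- cursor + round(len / 2) + len + min_spacing
  }
  for (i in seq_len(n_close_pairs)) {
    len <- round(stats::runif(1, min_length, max_length))
    df <- add_gene(df, cursor, len, "+", "cl")
    df <- add_gene(df, cursor + len + 1500, len, "-", "cl")  # 1.5 kb < 3 kb
    cursor <- cursor + 2 * len + 1500 + min_spacing
  }
  for (i in seq_len(n_short_genes)) {
    df <- add_gene(df, cursor, 900, "+", "sh")
    cursor <- cursor + 900 + min_spacing
  }
  truth_eligible <- c(truth_eligible,
                      rep(FALSE, 2 * n_overlapping_pairs + 2 * n_close_pairs +
                            n_short_genes))
  needed <- cursor + 5000
  if (is.null(chrom_length)) {
    chrom_length <- needed
  } else if (chrom_length < needed) {
    stop("chromosome too short for requested layout (need ", needed, " bp)")
  }
  genes <- gene_models(gene_id = df$gene_id, isoform_id = df$isoform_id,
                       chrom = df$chrom, strand = df$strand,
                       tss = ifelse(df$strand == "+", df$start, df$end),
                       tes = ifelse(df$strand == "+", df$end, df$start))
  n_all <- nrow(genes)
  gc_target <- stats::runif(n_all, gc_range[1], gc_range[2])
  kc <- integer(n_all)
  if (!is.null(planted_kmer)) {
    if (is.null(kmer_counts)) kmer_counts <- rep(1L, n_genes)
    kc[seq_len(n_genes)] <- kmer_counts
  }
  promoters <- generate_promoters(n_all, gc = gc_target,
                                  planted_kmer = planted_kmer,
                                  kmer_counts = kc,
                                  seed = seed + 101L)
  names(promoters) <- genes$gene_id
  truth <- data.frame(gene_id = genes$gene_id,
                      eligible_truth = truth_eligible,
                      gc_target = gc_target, kmer_count = kc,
                      stringsAsFactors = FALSE)
  list(genes = genes, promoters = promoters, truth = truth,
       chrom_length = chrom_length, seed = seed)
}

#' Generate promoter sequences with a GC target and planted k-mers
#'
#' Per-position independent base draws at the target GC (G and C equally
#' likely, likewise A and T), then each planted k-mer occurrence
#' overwrites the sequence at a random position.
#'
#' @param n Number of sequences.
#' @param length Sequence length (default 1000).
#' @param gc GC target, recycled to length \code{n}.
#' @param planted_kmer Optional k-mer to plant.
#' @param kmer_counts Integer occurrences per sequence (recycled).
#' @param seed RNG seed.
#' @return Character vector of sequences.
#' @export
generate_promoters <- function(n, length = 1000, gc = 0.5,
                               planted_kmer = NULL, kmer_counts = 0L,
                               seed = 1) {
  set.seed(seed)
  gc <- rep_len(gc, n)
  kmer_counts <- rep_len(as.integer(kmer_counts), n)
  bases <- c("A", "C", "G", "T")
  out <- character(n)
  for (i in seq_len(n)) {
    p <- c((1 - gc[i]) / 2, gc[i] / 2, gc[i] / 2, (1 - gc[i]) / 2)
    s <- sample(bases, length, replace = TRUE, prob = p)
    if (!is.null(planted_kmer) && kmer_counts[i] > 0L) {
      k <- nchar(planted_kmer)
      kchars <- strsplit(planted_kmer, "")[[1L]]
      # greedy non-overlapping placement so every planted copy survives
      cand <- sample.int(length - k + 1L)
      sel <- integer(0)
      for (p0 in cand) {
        if (all(abs(p0 - sel) >= k)) sel <- c(sel, p0)
        if (base::length(sel) == kmer_counts[i]) break
      }
      for (p0 in sel) s[p0:(p0 + k - 1L)] <- kchars
    }
    out[i] <- paste(s, collapse = "")
  }
  out
}

#' Simulate RNAP2 ChIP and input read libraries with planted pausing
#'
#' Per gene, the expected per-bp read rate in the TSSR is
#' \code{planted_pi} times the (uniform) rate in the gene body, so the
#' background-subtracted density ratio recovers the planted PI. The
#' simulated chromosome is treated as a subset of a larger genome:
#' background ChIP reads and all input reads are uniform genome-wide, so
#' only the fraction \code{chrom_length / genome_size} of them is stored,
#' while \code{mapped_total} records the full library size (the
#' chromosome-subset convention of \code{\link{read_library}}). Signal
#' reads occupy distinct (5' position, strand) slots within their region
#' (drawn without replacement, as distinct crosslinked fragments), so the
#' PCR-duplicate collapse removes only the duplicates injected at
#' \code{duplication_rate}, not signal; read strands are otherwise
#' random, as for sonicated ChIP fragments.
#'
#' @param genes Gene-model table (one isoform per gene).
#' @param planted_pi Positive per-gene pausing index (recycled).
#' @param depth Total ChIP reads, genome-wide (>= 1000).
#' @param input_depth Input-library reads, genome-wide (default = depth).
#' @param input_fraction Fraction of ChIP reads that are uniform
#'   background rather than gene signal (default 0.8, a typical ChIP
#'   background share).
#' @param duplication_rate Extra duplicate reads as a fraction of the
#'   stored read count (default 0).
#' @param read_length Read width in bp (default 36); only the 5' point
#'   matters for counting.
#' @param chrom_length Length of the simulated chromosome; default max
#'   gene end + 5 kb.
#' @param genome_size Size of the notional genome the libraries were
#'   mapped to (default 20 x \code{chrom_length}, i.e. genes occupy a
#'   small share of the genome as in real data).
#' @param seed RNG seed.
#' @return list(chip, input) of \code{read_library} objects, with
#'   \code{planted_pi} and \code{seed} attached as attributes.
#' @export
simulate_chip_library <- function(genes, planted_pi, depth = 2e6,
                                  input_depth = depth, input_fraction = 0.8,
                                  duplication_rate = 0, read_length = 36,
                                  chrom_length = NULL, genome_size = NULL,
                                  seed = 1) {
  if (depth < 1000) stop("depth must be >= 1000")
  planted_pi <- rep_len(planted_pi, nrow(genes))
  if (any(planted_pi <= 0)) stop("planted_pi must be > 0")
  set.seed(seed)
  tssr <- tssr_region(genes)
  gb <- gene_body_region(genes)
  if (is.null(chrom_length)) {
    chrom_length <- max(pmax(genes$tss, genes$tes)) + 5000
  }
  if (is.null(genome_size)) genome_size <- 20 * chrom_length
  l1 <- tssr$end - tssr$start
  l2 <- gb$end - gb$start
  mass <- planted_pi * l1 + l2          # per-gene signal mass (gb rate = 1)
  n_bg_total <- stats::rbinom(1L, depth, input_fraction)
  n_signal <- depth - n_bg_total
  n_bg_here <- stats::rbinom(1L, n_bg_total, chrom_length / genome_size)
  per_gene <- as.vector(stats::rmultinom(1L, n_signal, mass))
  pos_list <- vector("list", 2L * nrow(genes) + 1L)
  strand_list <- vector("list", 2L * nrow(genes) + 1L)
  for (i in seq_len(nrow(genes))) {
    n_t <- stats::rbinom(1L, per_gene[i], planted_pi[i] * l1[i] / mass[i])
    n_g <- per_gene[i] - n_t
    st <- sample_region_slots(tssr$start[i], l1[i], n_t)
    sg <- sample_region_slots(gb$start[i], l2[i], n_g)
    pos_list[[2L * i - 1L]] <- st$pos
    strand_list[[2L * i - 1L]] <- st$strand
    pos_list[[2L * i]] <- sg$pos
    strand_list[[2L * i]] <- sg$strand
  }
  if (n_bg_here > 0) {
    pos_list[[2L * nrow(genes) + 1L]] <- sample.int(chrom_length, n_bg_here,
                                                    replace = TRUE) - 1L
    strand_list[[2L * nrow(genes) + 1L]] <- sample(c("+", "-"), n_bg_here,
                                                   replace = TRUE)
  }
  chip <- reads_from_5prime(unlist(pos_list), unlist(strand_list),
                            read_length, chrom_length)
  if (duplication_rate > 0) {
    n_dup <- round(duplication_rate * nrow(chip))
    chip <- rbind(chip, chip[sample.int(nrow(chip), n_dup, replace = TRUE), ])
  }
  n_in_here <- stats::rbinom(1L, input_depth, chrom_length / genome_size)
  ipos <- sample.int(chrom_length, n_in_here, replace = TRUE) - 1L
  istr <- sample(c("+", "-"), n_in_here, replace = TRUE)
  input <- reads_from_5prime(ipos, istr, read_length, chrom_length)
  out <- list(chip = read_library(chip, mapped_total = depth +
                                    round(duplication_rate * depth)),
              input = read_library(input, mapped_total = input_depth))
  attr(out, "planted_pi") <- stats::setNames(planted_pi, genes$gene_id)
  attr(out, "seed") <- seed
  out
}

#' Simulate a promoter-mark ChIP library (e.g. H3K4me3) with input
#'
#' Signal reads pile up in promoter windows (+/-500 bp of each TSS) with
#' per-gene weights, on top of uniform genome-wide background; the input
#' library is uniform. Same chromosome-subset convention as
#' \code{\link{simulate_chip_library}}.
#'
#' @param genes Gene-model table.
#' @param weight Per-gene promoter signal weight (recycled; 0 silences a
#'   promoter).
#' @param depth,input_depth Genome-wide library sizes.
#' @param signal_fraction Fraction of ChIP reads that are promoter signal
#'   (default 0.5; promoter marks are sharply enriched).
#' @param read_length,chrom_length,genome_size,seed As in
#'   \code{\link{simulate_chip_library}}.
#' @return list(chip, input) of \code{read_library} objects.
#' @export
simulate_mark_library <- function(genes, weight = 1, depth = 5e5,
                                  input_depth = depth, signal_fraction = 0.5,
                                  read_length = 36, chrom_length = NULL,
                                  genome_size = NULL, seed = 1) {
  weight <- rep_len(weight, nrow(genes))
  set.seed(seed)
  prom <- promoter_region(genes)
  if (is.null(chrom_length)) {
    chrom_length <- max(pmax(genes$tss, genes$tes)) + 5000
  }
  if (is.null(genome_size)) genome_size <- 20 * chrom_length
  n_signal <- stats::rbinom(1L, depth, signal_fraction)
  n_bg_here <- stats::rbinom(1L, depth - n_signal, chrom_length / genome_size)
  per_gene <- if (sum(weight) > 0) {
    as.vector(stats::rmultinom(1L, n_signal, weight))
  } else {
    integer(nrow(genes))
  }
  width <- prom$end - prom$start
  pos <- unlist(lapply(seq_len(nrow(genes)), function(i) {
    if (per_gene[i] == 0L) return(integer(0))
    prom$start[i] + sample.int(width[i], per_gene[i], replace = TRUE) - 1L
  }))
  pos <- c(pos, sample.int(chrom_length, n_bg_here, replace = TRUE) - 1L)
  strand <- sample(c("+", "-"), length(pos), replace = TRUE)
  chip <- reads_from_5prime(pos, strand, read_length, chrom_length)
  n_in_here <- stats::rbinom(1L, input_depth, chrom_length / genome_size)
  ipos <- sample.int(chrom_length, n_in_here, replace = TRUE) - 1L
  istr <- sample(c("+", "-"), n_in_here, replace = TRUE)
  input <- reads_from_5prime(ipos, istr, read_length, chrom_length)
  list(chip = read_library(chip, mapped_total = depth),
       input = read_library(input, mapped_total = input_depth))
}

## Draw n read 5' ends in a region, sampling (position, strand) slots
## without replacement so distinct sampled reads occupy distinct
## deduplication slots; only injected PCR duplicates (duplication_rate)
## collide. Requests beyond the 2 * length slot capacity wrap to
## with-replacement draws (true saturation).
sample_region_slots <- function(start, len, n) {
  if (n <= 0L) return(list(pos = integer(0), strand = character(0)))
  slots <- 2L * len
  idx <- if (n <= slots) {
    sample.int(slots, n)
  } else {
    c(sample.int(slots), sample.int(slots, n - slots, replace = TRUE))
  }
  list(pos = start + (idx - 1L) %/% 2L,
       strand = c("+", "-")[(idx %% 2L) + 1L])
}

## Fixed-width read intervals from 5' positions (start for +, end-1 for -),
## clipped to the chromosome.
reads_from_5prime <- function(pos, strand, read_length, chrom_length) {
  start <- ifelse(strand == "-", pos - read_length + 1, pos)
  start <- pmax(start, 0)
  end <- pmin(start + read_length, chrom_length)
  # preserve the 5' position exactly even at the chromosome edge
  end <- pmax(end, pos + 1)
  data.frame(chrom = "chrS", start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Simulate expression tables (bulk, single-cell, or time course)
#'
#' \describe{
#'   \item{bulk}{Log-normal FPKM per gene and sample.}
#'   \item{single_cell}{Per-cell FPKM = gene mean times multiplicative
#'     gamma noise with group-dependent dispersion, so CV =
#'     sqrt(dispersion) independent of the mean (a gamma-mixed,
#'     negative-binomial-like noise model); zero dispersion gives exactly
#'     the mean in every cell.}
#'   \item{time_course}{Fold-change-driven profiles per planted response
#'     class: early genes at least double by the 1 h point, late genes
#'     only at later points, down genes halve at some point,
#'     non-responsive genes stay strictly within (0.5, 2)-fold.}
#' }
#'
#' @param gene_ids Character vector of gene ids.
#' @param mode "bulk", "single_cell" or "time_course".
#' @param n_samples Bulk: number of samples (default 1).
#' @param meanlog,sdlog Bulk/time-course baseline log-normal parameters.
#' @param n_cells Single-cell: number of cells (>= 2).
#' @param mean_fpkm Single-cell: per-gene mean FPKM (default log-normal).
#' @param cv_group Single-cell: "low"/"high" per gene (default: split in
#'   half).
#' @param dispersion Named numeric c(low=, high=): squared CV per group.
#' @param times Time-course: numeric time points in hours, first = 0.
#' @param response Time-course: per-gene class "early", "late", "down" or
#'   "none" (default: recycled over the four classes).
#' @param seed RNG seed.
#' @return Numeric matrix (genes x columns) with a \code{truth} attribute
#'   (per-gene planted labels) and a \code{seed} attribute.
#' @export
simulate_expression <- function(gene_ids,
                                mode = c("bulk", "single_cell", "time_course"),
                                n_samples = 1L, meanlog = 1, sdlog = 1,
                                n_cells = 100L, mean_fpkm = NULL,
                                cv_group = NULL,
                                dispersion = c(low = 0.1, high = 0.4),
                                times = c(0, 1, 4, 12), response = NULL,
                                seed = 1) {
  mode <- match.arg(mode)
  n <- length(gene_ids)
  set.seed(seed)
  if (mode == "bulk") {
    m <- matrix(stats::rlnorm(n * n_samples, meanlog, sdlog), nrow = n,
                dimnames = list(gene_ids, paste0("sample_", seq_len(n_samples))))
    attr(m, "truth") <- data.frame(gene_id = gene_ids,
                                   meanlog = meanlog, stringsAsFactors = FALSE)
  } else if (mode == "single_cell") {
    if (n_cells < 2L) stop("n_cells must be >= 2 for single_cell mode")
    if (is.null(mean_fpkm)) mean_fpkm <- stats::rlnorm(n, meanlog, sdlog)
    if (is.null(cv_group)) {
      cv_group <- rep(c("low", "high"), length.out = n)
    }
    phi <- unname(dispersion[cv_group])
    m <- matrix(NA_real_, n, n_cells,
                dimnames = list(gene_ids, paste0("cell_", seq_len(n_cells))))
    for (i in seq_len(n)) {
      m[i, ] <- if (phi[i] <= 0) {
        rep(mean_fpkm[i], n_cells)
      } else {
        mean_fpkm[i] * stats::rgamma(n_cells, shape = 1 / phi[i],
                                     rate = 1 / phi[i])
      }
    }
    attr(m, "truth") <- data.frame(gene_id = gene_ids, cv_group = cv_group,
                                   mean_fpkm = mean_fpkm, dispersion = phi,
                                   stringsAsFactors = FALSE)
  } else {
    if (length(times) < 2L || times[1L] != 0) {
      stop("time_course needs >= 2 time points with baseline 0 first")
    }
    if (is.null(response)) {
      response <- rep(c("early", "late", "down", "none"), length.out = n)
    }
    baseline <- stats::rlnorm(n, meanlog, sdlog)
    nt <- length(times)
    m <- matrix(NA_real_, n, nt, dimnames = list(gene_ids, as.character(times)))
    m[, 1L] <- baseline
    late_idx <- which(times > 1)
    early_idx <- which(times > 0 & times <= 1)
    for (i in seq_len(n)) {
      fold <- stats::runif(nt, 0.85, 1.18)  # within (0.5, 2): null wobble
      fold[1L] <- 1
      if (response[i] == "early") {
        fold[early_idx] <- stats::runif(length(early_idx), 2.2, 6)
        fold[late_idx] <- stats::runif(length(late_idx), 1.2, 3)
      } else if (response[i] == "late") {
        peak <- sample(late_idx, 1L)
        fold[peak] <- stats::runif(1, 2.2, 6)
      } else if (response[i] == "down") {
        trough <- sample(c(early_idx, late_idx), 1L)
        fold[trough] <- stats::runif(1, 0.1, 0.45)
      }
      m[i, ] <- baseline[i] * fold
    }
    attr(m, "truth") <- data.frame(gene_id = gene_ids, response = response,
                                   baseline = baseline,
                                   stringsAsFactors = FALSE)
  }
  attr(m, "seed") <- seed
  m
}

#' Simulate a chromatin-enrichment design with planted coefficients
#'
#' Draws per-gene log2 mark enrichments and generates
#' \code{log2_pi = intercept + X beta + noise}; used to exercise the
#' linear-model fit with known ground truth.
#'
#' @param n_genes Number of genes.
#' @param betas Named numeric vector of planted coefficients.
#' @param intercept Planted intercept (default 0).
#' @param noise_sd Gaussian noise sd on log2 PI (default 0.5).
#' @param seed RNG seed.
#' @return list(enrichment = genes x marks matrix, log2_pi = vector,
#'   betas, intercept, seed).
#' @export
simulate_enrichment_model <- function(n_genes, betas, intercept = 0,
                                      noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  k <- length(betas)
  marks <- names(betas)
  if (is.null(marks)) marks <- paste0("mark", seq_len(k))
  X <- matrix(stats::rnorm(n_genes * k), n_genes, k,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)), marks))
  y <- intercept + as.vector(X %*% betas) + stats::rnorm(n_genes, 0, noise_sd)
  list(enrichment = X, log2_pi = y, betas = betas, intercept = intercept,
       seed = seed)
}
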