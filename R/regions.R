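## Region arithmetic and read counting.
##
## All coordinates are 0-based half-open (BED). Promoter-relative offsets
## are strand-aware: for a plus-strand gene with tss = t the offset-o base
## sits at genomic t + o; for a minus-strand gene (tss stored as the BED
## end coordinate, so the first transcribed base is tss - 1) it sits at
## tss - 1 - o.

#' TSS-region (TSSR) coordinates for a gene table
#'
#' The TSSR spans promoter offsets -50 to +300 (350 bp). In genomic
#' coordinates that is \code{[tss-50, tss+300)} on the plus strand and
#' \code{[tss-300, tss+50)} on the minus strand.
#'
#' @param models Gene-model table.
#' @return data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{strand}, one row per input isoform (length always 350).
#' @export
tssr_region <- function(models) {
  plus <- models$strand == "+"
  data.frame(chrom = models$chrom,
             start = ifelse(plus, models$tss - 50, models$tss - 300),
             end = ifelse(plus, models$tss + 300, models$tss + 50),
             strand = models$strand, stringsAsFactors = FALSE)
}

#' Gene-body region coordinates
#'
#' From promoter offset +300 through 3 kb past the TES, so the length is
#' always gene length + 2700 bp.
#'
#' @param models Gene-model table.
#' @return data.frame of regions, one row per isoform.
#' @export
gene_body_region <- function(models) {
  plus <- models$strand == "+"
  data.frame(chrom = models$chrom,
             start = ifelse(plus, models$tss + 300, models$tes - 3000),
             end = ifelse(plus, models$tes + 3000, models$tss - 300),
             strand = models$strand, stringsAsFactors = FALSE)
}

#' Promoter region coordinates (+/- flank around the TSS)
#'
#' For both strands the +/-500 bp window is \code{[tss-500, tss+500)}: the
#' strand-aware offset arithmetic lands on the same genomic interval.
#'
#' @param models Gene-model table.
#' @param flank Half-width in bp (default 500).
#' @return data.frame of regions, one row per isoform.
#' @export
promoter_region <- function(models, flank = 500) {
  data.frame(chrom = models$chrom,
             start = models$tss - flank, end = models$tss + flank,
             strand = models$strand, stringsAsFactors = FALSE)
}

#' Strand-adjusted 5' positions of reads
#'
#' A read's location for counting is the 5' end of the sequenced fragment:
#' \code{start} for plus-strand reads, \code{end - 1} for minus-strand.
#'
#' @param reads data.frame with \code{start}, \code{end}, \code{strand}.
#' @return Numeric vector of positions.
#' @export
five_prime_positions <- function(reads) {
  ifelse(reads$strand == "-", reads$end - 1, reads$start)
}

## Per-chromosome sorted 5' position index, optionally deduplicated on
## (chrom, position, strand) -- the PCR-duplicate collapse rule.
position_index <- function(lib, dedup = TRUE) {
  r <- lib$reads
  pos <- five_prime_positions(r)
  if (dedup && length(pos) > 0L) {
    keep <- !duplicated(paste(r$chrom, pos, r$strand))
    chrom <- r$chrom[keep]
    pos <- pos[keep]
  } else {
    chrom <- r$chrom
  }
  idx <- lapply(split(pos, chrom), sort)
  idx
}

#' Count reads with 5' position inside each region
#'
#' @param lib A \code{read_library}.
#' @param regions data.frame with \code{chrom}, \code{start}, \code{end}.
#' @param dedup Collapse reads sharing (chrom, 5' position, strand) into
#'   one before counting (default TRUE).
#' @return Integer vector of counts, one per region.
#' @export
count_in_regions <- function(lib, regions, dedup = TRUE) {
  idx <- position_index(lib, dedup)
  n <- nrow(regions)
  counts <- integer(n)
  for (chr in unique(regions$chrom)) {
    sel <- which(regions$chrom == chr)
    pos <- idx[[chr]]
    if (is.null(pos) || length(pos) == 0L) next
    counts[sel] <- findInterval(regions$end[sel] - 1, pos) -
      findInterval(regions$start[sel] - 1, pos)
  }
  counts
}

#' Background-subtracted read density (rpm/bp)
#'
#' Per region: deduplicated ChIP count divided by the region length and the
#' mapped-read total over one million, minus the same quantity for the
#' input library. May be negative where the input exceeds the ChIP signal.
#'
#' @param chip,input \code{read_library} objects (input may be NULL to skip
#'   background subtraction).
#' @param regions Region data.frame.
#' @param dedup Collapse PCR duplicates before counting (default TRUE).
#' @return Numeric vector, reads per million mapped per bp.
#' @export
region_density <- function(chip, input, regions, dedup = TRUE) {
  len <- regions$end - regions$start
  if (any(len <= 0)) stop("region length must be > 0")
  if (chip$mapped_total <= 0) stop("chip mapped_total must be > 0")
  d <- count_in_regions(chip, regions, dedup) / len / (chip$mapped_total / 1e6)
  if (!is.null(input)) {
    if (input$mapped_total <= 0) stop("input mapped_total must be > 0")
    d <- d - count_in_regions(input, regions, dedup) / len /
      (input$mapped_total / 1e6)
  }
  d
}
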