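## Pausing-index core: eligibility filtering, per-isoform densities,
## isoform consolidation, PI computation, paused calls, cross-sample sets.

#' Filter gene models to PI-eligible genes
#'
#' Removes genes whose spans overlap another gene, lie within a minimum
#' distance (default 3 kb) of another gene, or are shorter than a minimum
#' length (default 1 kb). Spans are per gene (the union of its isoform
#' spans, TSS..TES); distances are strand-blind and per chromosome.
#'
#' @param models Gene-model table (may contain several isoforms per gene).
#' @param min_length Minimum gene-span length in bp (default 1000).
#' @param min_spacing Minimum distance to any other gene span (default 3000).
#' @return The rows of \code{models} belonging to surviving genes.
#' @export
eligible_genes <- function(models, min_length = 1000, min_spacing = 3000) {
  if (nrow(models) == 0L) return(models)
  span_start <- pmin(models$tss, models$tes)
  span_end <- pmax(models$tss, models$tes)
  genes <- unique(models$gene_id)
  gs <- vapply(genes, function(g) min(span_start[models$gene_id == g]), 0)
  ge <- vapply(genes, function(g) max(span_end[models$gene_id == g]), 0)
  gchr <- vapply(genes, function(g) models$chrom[models$gene_id == g][1L], "")
  keep <- (ge - gs) >= min_length
  for (i in seq_along(genes)) {
    if (!keep[i] && (ge[i] - gs[i]) < min_length) next
    same <- which(gchr == gchr[i])
    same <- setdiff(same, i)
    if (length(same) == 0L) next
    # gap between half-open spans; negative means overlap
    gap <- pmax(gs[same] - ge[i], gs[i] - ge[same])
    if (any(gap < min_spacing)) keep[i] <- FALSE
  }
  models[models$gene_id %in% genes[keep], , drop = FALSE]
}

#' Pausing index from densities
#'
#' PI = TSSR density / gene-body density, defined only when both
#' background-subtracted densities are positive; otherwise missing.
#'
#' @param tssr_density,gb_density Numeric vectors (rpm/bp, may be negative
#'   after background subtraction).
#' @return Numeric vector of PI values with NA where undefined.
#' @export
compute_pi <- function(tssr_density, gb_density) {
  ifelse(!is.na(tssr_density) & !is.na(gb_density) &
           tssr_density > 0 & gb_density > 0,
         tssr_density / gb_density, NA_real_)
}

#' Call paused genes
#'
#' A gene is paused iff its PI is assigned and strictly exceeds the
#' threshold; genes with PI at or below the threshold, or with no assigned
#' PI, are non-paused.
#'
#' @param pi Numeric vector of PI values (NA allowed).
#' @param threshold Pausing threshold (default 2).
#' @return Logical vector.
#' @export
call_paused <- function(pi, threshold = 2) {
  if (threshold <= 0) stop("threshold must be > 0")
  !is.na(pi) & pi > threshold
}

## H3K4me3 promoter enrichment ratio (raw rpm ratio, input floored at one
## read-equivalent so the ratio is defined at zero input).
h3k4me3_ratio <- function(chip, input, regions, dedup = TRUE) {
  len <- regions$end - regions$start
  cd <- count_in_regions(chip, regions, dedup) / len / (chip$mapped_total / 1e6)
  id <- count_in_regions(input, regions, dedup) / len / (input$mapped_total / 1e6)
  floor_d <- (1 / len) / (input$mapped_total / 1e6)
  cd / pmax(id, floor_d)
}

#' Select the primary isoform of one gene
#'
#' The isoform whose TSSR has the strongest background-subtracted RNAP2
#' density wins, provided that density reaches the floor (default 0.001
#' rpm/bp). Failing that, isoforms are rescued by promoter (+/-500 bp)
#' H3K4me3 ChIP/input enrichment of at least \code{h3k4me3_fold}
#' (strongest ratio wins). If neither criterion is met the gene gets no
#' PI. Among isoforms sharing the winning TSS the longest is chosen.
#'
#' @param isoforms Gene-model rows for one gene.
#' @param chip,input RNAP2 ChIP and input \code{read_library} objects.
#' @param h3k4me3,h3k4me3_input Optional H3K4me3 libraries for the rescue
#'   route.
#' @param tssr_floor Minimum TSSR density, rpm/bp (default 0.001).
#' @param h3k4me3_fold Minimum promoter enrichment for rescue (default 4).
#' @param dedup Collapse PCR duplicates (default TRUE).
#' @return list(isoform_id = character or NA, route = one of
#'   "rnap2_tssr", "h3k4me3_rescue", "unassigned").
#' @export
select_primary_isoform <- function(isoforms, chip, input,
                                   h3k4me3 = NULL, h3k4me3_input = NULL,
                                   tssr_floor = 0.001, h3k4me3_fold = 4,
                                   dedup = TRUE) {
  td <- region_density(chip, input, tssr_region(isoforms), dedup)
  k4 <- if (!is.null(h3k4me3) && !is.null(h3k4me3_input)) {
    h3k4me3_ratio(h3k4me3, h3k4me3_input, promoter_region(isoforms), dedup)
  } else {
    rep(NA_real_, nrow(isoforms))
  }
  pick <- pick_isoform(isoforms, td, k4, tssr_floor, h3k4me3_fold)
  list(isoform_id = if (is.na(pick$row)) NA_character_ else
         isoforms$isoform_id[pick$row],
       route = pick$route)
}

## Shared isoform-selection rule given precomputed per-isoform TSSR
## densities and H3K4me3 ratios. Returns the chosen row index and route.
pick_isoform <- function(isoforms, tssr_density, k4_ratio,
                         tssr_floor, h3k4me3_fold) {
  choose_at <- function(score) {
    best <- max(score, na.rm = TRUE)
    cand <- which(!is.na(score) & score == best)
    # isoforms sharing the winning TSS: take the longest
    tss0 <- isoforms$tss[cand[1L]]
    same_tss <- cand[isoforms$tss[cand] == tss0 &
                       isoforms$chrom[cand] == isoforms$chrom[cand[1L]]]
    same_tss[which.max(isoforms$length[same_tss])]
  }
  if (any(!is.na(tssr_density) & tssr_density >= tssr_floor)) {
    sc <- ifelse(!is.na(tssr_density) & tssr_density >= tssr_floor,
                 tssr_density, NA_real_)
    return(list(row = choose_at(sc), route = "rnap2_tssr"))
  }
  if (any(!is.na(k4_ratio) & k4_ratio >= h3k4me3_fold)) {
    sc <- ifelse(!is.na(k4_ratio) & k4_ratio >= h3k4me3_fold,
                 k4_ratio, NA_real_)
    return(list(row = choose_at(sc), route = "h3k4me3_rescue"))
  }
  list(row = NA_integer_, route = "unassigned")
}

#' Per-gene pausing-index table
#'
#' The core driver: applies the eligibility filter (optional), computes
#' background-subtracted TSSR and gene-body densities for every isoform,
#' consolidates isoforms per gene (strongest TSSR signal, with H3K4me3
#' rescue), computes PI and the paused call.
#'
#' @param models Gene-model table.
#' @param chip,input RNAP2 ChIP and input \code{read_library} objects.
#' @param h3k4me3,h3k4me3_input Optional H3K4me3 ChIP and input libraries.
#' @param filter Apply \code{\link{eligible_genes}} first (default TRUE).
#' @param pi_threshold Paused-call threshold (default 2).
#' @param tssr_floor,h3k4me3_fold Isoform-selection thresholds.
#' @param dedup Collapse PCR duplicates (default TRUE).
#' @return data.frame of class \code{pi_table}: \code{gene_id},
#'   \code{isoform_id}, \code{tssr_density}, \code{gb_density}, \code{L1}
#'   (350), \code{L2}, \code{pi}, \code{paused}, \code{route}.
#' @export
pause_index <- function(models, chip, input,
                        h3k4me3 = NULL, h3k4me3_input = NULL,
                        filter = TRUE, pi_threshold = 2,
                        tssr_floor = 0.001, h3k4me3_fold = 4, dedup = TRUE) {
  if (filter) models <- eligible_genes(models)
  if (nrow(models) == 0L) stop("no eligible genes")
  td <- region_density(chip, input, tssr_region(models), dedup)
  gbr <- gene_body_region(models)
  gd <- region_density(chip, input, gbr, dedup)
  k4 <- if (!is.null(h3k4me3) && !is.null(h3k4me3_input)) {
    h3k4me3_ratio(h3k4me3, h3k4me3_input, promoter_region(models), dedup)
  } else {
    rep(NA_real_, nrow(models))
  }
  genes <- unique(models$gene_id)
  rows <- integer(length(genes))
  route <- character(length(genes))
  for (i in seq_along(genes)) {
    sel <- which(models$gene_id == genes[i])
    pick <- pick_isoform(models[sel, , drop = FALSE], td[sel], k4[sel],
                         tssr_floor, h3k4me3_fold)
    rows[i] <- if (is.na(pick$row)) sel[1L] else sel[pick$row]
    route[i] <- pick$route
  }
  assigned <- route != "unassigned"
  out <- data.frame(
    gene_id = genes,
    isoform_id = ifelse(assigned, models$isoform_id[rows], NA_character_),
    tssr_density = ifelse(assigned, td[rows], NA_real_),
    gb_density = ifelse(assigned, gd[rows], NA_real_),
    L1 = 350,
    L2 = ifelse(assigned, gbr$end[rows] - gbr$start[rows], NA_real_),
    route = route, stringsAsFactors = FALSE)
  out$pi <- compute_pi(out$tssr_density, out$gb_density)
  out$paused <- call_paused(out$pi, pi_threshold)
  class(out) <- c("pi_table", "data.frame")
  attr(out, "pi_threshold") <- pi_threshold
  out
}

#' @export
print.pi_table <- function(x, ...) {
  cat("pi_table:", nrow(x), "genes;",
      sum(!is.na(x$pi)), "with assigned PI;",
      sum(x$paused), "paused (PI >",
      attr(x, "pi_threshold") %||% 2, ")\n")
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' @export
summary.pi_table <- function(object, ...) {
  pi <- object$pi
  cat("Genes:", nrow(object), "\n")
  cat("Assigned PI:", sum(!is.na(pi)),
      sprintf("(%.1f%%)", 100 * mean(!is.na(pi))), "\n")
  cat("Paused:", sum(object$paused),
      sprintf("(%.1f%% of assigned)",
              100 * sum(object$paused) / max(sum(!is.na(pi)), 1L)), "\n")
  cat("Selection routes:\n")
  print(table(object$route))
  if (any(!is.na(pi))) {
    cat("PI quartiles:\n")
    print(stats::quantile(pi, na.rm = TRUE))
  }
  invisible(object)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-sample PI ranks with missing values at the bottom
#'
#' Within each sample genes are ranked by PI ascending with ties averaged;
#' genes with no assigned PI share the lowest rank (they are treated as
#' ties below every assigned value).
#'
#' @param pimat Genes x samples numeric matrix of PI values (NA allowed).
#' @return Matrix of ranks, same shape.
#' @export
pi_rank_matrix <- function(pimat) {
  apply(pimat, 2L, function(col) {
    col[is.na(col)] <- -Inf
    rank(col, ties.method = "average")
  })
}

#' Cross-sample paused gene sets
#'
#' Builds the all-paused set (paused in at least one sample) and splits it
#' into highly and lowly paused halves by the per-gene median of the
#' per-sample PI ranks.
#'
#' @param pimat Genes x samples PI matrix (rownames = gene ids).
#' @param threshold Paused threshold (default 2).
#' @return list with \code{all_paused}, \code{high}, \code{low} (character
#'   vectors of gene ids) and \code{median_rank} (named numeric).
#' @export
cross_sample_pause_sets <- function(pimat, threshold = 2) {
  if (ncol(pimat) < 2L) stop("need at least 2 samples")
  ranks <- pi_rank_matrix(pimat)
  med <- apply(ranks, 1L, stats::median)
  paused_any <- apply(pimat, 1L, function(p) any(call_paused(p, threshold)))
  all_paused <- rownames(pimat)[paused_any]
  ord <- all_paused[order(med[all_paused])]
  n <- length(ord)
  low <- ord[seq_len(floor(n / 2))]
  high <- setdiff(ord, low)
  list(all_paused = all_paused, high = high, low = low, median_rank = med)
}
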