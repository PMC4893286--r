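# Independent brute-force oracles, deliberately free of the package's
# indexing shortcuts: per-read loops, exhaustive enumeration, closed
# forms. Used to pin the implementation to first principles.

# Per-read brute-force region count: dedup on the (chrom, 5' position,
# strand) key, then a full linear scan of every read per region -- no
# sorting, no interval index.
oracle_count <- function(lib, region, dedup = TRUE) {
  r <- lib$reads
  pos <- ifelse(r$strand == "-", r$end - 1, r$start)
  keep <- if (dedup) !duplicated(paste(r$chrom, pos, r$strand)) else TRUE
  sum(keep & r$chrom == region$chrom &
        pos >= region$start & pos < region$end)
}

oracle_density <- function(chip, input, region, dedup = TRUE) {
  len <- region$end - region$start
  d <- oracle_count(chip, region, dedup) / len / (chip$mapped_total / 1e6)
  if (!is.null(input)) {
    d <- d - oracle_count(input, region, dedup) / len /
      (input$mapped_total / 1e6)
  }
  d
}

# Brute-force per-gene PI for single-isoform gene tables (no isoform
# consolidation, no H3K4me3 rescue; TSSR floor applied as in the
# pipeline).
oracle_pi_table <- function(genes, chip, input, tssr_floor = 0.001) {
  vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, , drop = FALSE]
    tr <- as.list(tssr_region(g))
    gb <- as.list(gene_body_region(g))
    td <- oracle_density(chip, input, tr)
    gd <- oracle_density(chip, input, gb)
    if (is.na(td) || td < tssr_floor) return(NA_real_)
    if (td > 0 && gd > 0) td / gd else NA_real_
  }, 0)
}

# Exact two-sided Mann-Whitney p by full enumeration of all C(n1+n2, n1)
# group assignments of the pooled values.
oracle_mwu_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  n <- length(pooled)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combos <- utils::combn(n, n1)
  u_all <- apply(combos, 2L, u_of)
  pl <- mean(u_all <= u_obs)
  pg <- mean(u_all >= u_obs)
  min(1, 2 * min(pl, pg))
}

# Hypergeometric enrichment tail by direct pmf summation.
oracle_hyper_tail <- function(overlap, n_test, n_anno, n_universe) {
  ks <- overlap:min(n_test, n_anno)
  sum(vapply(ks, function(k) {
    choose(n_anno, k) * choose(n_universe - n_anno, n_test - k) /
      choose(n_universe, n_test)
  }, 0))
}

# Brute-force hex assignment: enumerate every lattice centre over an
# enlarged bounding box and take the nearest (y compressed by the row
# spacing ratio), then group-by means.
oracle_hexbin <- function(x, y, z, n_bins) {
  xr <- range(x); yr <- range(y)
  w <- if (diff(xr) > 0) diff(xr) / n_bins else 1
  h <- w * sqrt(3) / 2
  cols <- seq(-2, n_bins + 2, by = 0.5)
  rows <- -4:ceiling((yr[2] - yr[1]) / h + 4)
  centres <- expand.grid(col = cols, row = rows)
  # hex lattice: row and col parity must match (integer col on even rows)
  keep <- (centres$col %% 1 == 0) == (centres$row %% 2 == 0)
  centres <- centres[keep, ]
  assign_one <- function(xi, yi) {
    sx <- (xi - xr[1]) / w
    sy <- (yi - yr[1]) / h
    d <- (sx - centres$col)^2 + ((sy - centres$row) * sqrt(3) / 2)^2
    i <- which.min(d)
    paste(centres$col[i], centres$row[i])
  }
  key <- mapply(assign_one, x, y)
  out <- lapply(split(seq_along(x), key), function(idx) {
    c(n = length(idx), mean_z = mean(z[idx]))
  })
  out
}

# Small deterministic read library builder for hand-computed fixtures.
lib_from_positions <- function(pos, strand = "+", chrom = "chr1",
                               width = 36, mapped_total = NULL) {
  strand <- rep_len(strand, length(pos))
  start <- ifelse(strand == "-", pos - width + 1, pos)
  reads <- data.frame(chrom = chrom, start = start, end = start + width,
                      strand = strand, stringsAsFactors = FALSE)
  if (is.null(mapped_total)) mapped_total <- length(pos)
  read_library(reads, mapped_total)
}
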