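#' Read gene models from BED12 or refFlat
#'
#' Parses transcript isoform annotations into the gene-model table used
#' throughout the package. Coordinates are kept in the BED convention
#' (0-based, half-open). The TSS is strand-aware: for a minus-strand
#' transcript the TSS is the BED end coordinate and the TES the BED start.
#'
#' @param path Path to the annotation file.
#' @param format Either \code{"bed12"} (also accepts plain BED6) or
#'   \code{"refflat"} (geneName, name, chrom, strand, txStart, txEnd, ...).
#' @return A data.frame with columns \code{gene_id}, \code{isoform_id},
#'   \code{chrom}, \code{strand}, \code{tss}, \code{tes}, \code{length}.
#'   For BED input the gene id is the transcript name with a trailing
#'   \code{.<n>} isoform suffix removed (if present).
#' @export
read_gene_models <- function(path, format = c("bed12", "refflat")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(empty_gene_models())
  }
  fields <- strsplit(lines, "\t")
  if (format == "bed12") {
    nf <- lengths(fields)
    bad <- which(nf < 6L)
    if (length(bad) > 0L) {
      stop("malformed BED line ", bad[1L], ": expected >= 6 tab-separated fields")
    }
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    name <- vapply(fields, `[[`, "", 4L)
    strand <- vapply(fields, `[[`, "", 6L)
    gene_id <- sub("\\.[0-9]+$", "", name)
    isoform_id <- name
  } else {
    nf <- lengths(fields)
    bad <- which(nf < 6L)
    if (length(bad) > 0L) {
      stop("malformed refFlat line ", bad[1L], ": expected >= 6 tab-separated fields")
    }
    gene_id <- vapply(fields, `[[`, "", 1L)
    isoform_id <- vapply(fields, `[[`, "", 2L)
    chrom <- vapply(fields, `[[`, "", 3L)
    strand <- vapply(fields, `[[`, "", 4L)
    start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 6L)))
  }
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    stop("malformed line ", bad[1L], ": non-numeric coordinates")
  }
  bad <- which(!(strand %in% c("+", "-")))
  if (length(bad) > 0L) {
    stop("line ", bad[1L], ": unknown strand '", strand[bad[1L]],
         "' (must be + or -)")
  }
  bad <- which(end <= start)
  if (length(bad) > 0L) {
    stop("line ", bad[1L], ": end <= start")
  }
  gene_models(gene_id = gene_id, isoform_id = isoform_id, chrom = chrom,
              strand = strand,
              tss = ifelse(strand == "+", start, end),
              tes = ifelse(strand == "+", end, start))
}

#' Construct a gene-model table
#'
#' @param gene_id,isoform_id,chrom,strand,tss,tes Per-isoform fields;
#'   \code{tss}/\code{tes} are strand-aware 0-based coordinates (for a
#'   minus-strand isoform the TSS is the larger coordinate).
#' @return Gene-model data.frame (see \code{\link{read_gene_models}}).
#' @export
gene_models <- function(gene_id, isoform_id = gene_id, chrom, strand, tss, tes) {
  if (any(!strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  len <- ifelse(strand == "+", tes - tss, tss - tes)
  if (any(len <= 0)) stop("gene length must be > 0 (tss == tes or wrong orientation)")
  data.frame(gene_id = as.character(gene_id),
             isoform_id = as.character(isoform_id),
             chrom = as.character(chrom), strand = as.character(strand),
             tss = as.numeric(tss), tes = as.numeric(tes),
             length = as.numeric(len), stringsAsFactors = FALSE)
}

empty_gene_models <- function() {
  data.frame(gene_id = character(), isoform_id = character(),
             chrom = character(), strand = character(),
             tss = numeric(), tes = numeric(), length = numeric(),
             stringsAsFactors = FALSE)
}

#' Write gene models as BED6
#'
#' @param models Gene-model table.
#' @param path Output path.
#' @export
write_gene_models <- function(models, path) {
  start <- pmin(models$tss, models$tes)
  end <- pmax(models$tss, models$tes)
  df <- data.frame(models$chrom, format_coord(start), format_coord(end),
                   models$isoform_id, 0L, models$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read aligned reads from BED6
#'
#' Returns a read library: the read intervals plus the mapped-read total
#' used for reads-per-million normalization. The total defaults to the
#' number of lines in the file but can be overridden (or supplied through a
#' sidecar \code{<path>.total} file) when the BED holds a chromosome subset
#' of a larger library.
#'
#' @param path BED6 path (name/score columns optional).
#' @param mapped_total Mapped filtered read count for normalization;
#'   \code{NULL} means use the sidecar file if present, else the line count.
#' @return An object of class \code{read_library}.
#' @export
read_alignments <- function(path, mapped_total = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    reads <- data.frame(chrom = character(), start = numeric(),
                        end = numeric(), strand = character(),
                        stringsAsFactors = FALSE)
  } else {
    fields <- strsplit(lines, "\t")
    nf <- lengths(fields)
    if (any(nf < 3L)) {
      stop("malformed BED line ", which(nf < 3L)[1L], ": expected >= 3 fields")
    }
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
    end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    strand <- ifelse(nf >= 6L, vapply(fields, function(f) f[min(6L, length(f))], ""), "+")
    strand[!strand %in% c("+", "-")] <- "+"
    bad <- which(is.na(start) | is.na(end) | end <= start)
    if (length(bad) > 0L) {
      stop("line ", bad[1L], ": invalid interval (need numeric end > start)")
    }
    reads <- data.frame(chrom = chrom, start = start, end = end,
                        strand = strand, stringsAsFactors = FALSE)
  }
  if (is.null(mapped_total)) {
    sidecar <- paste0(path, ".total")
    mapped_total <- if (file.exists(sidecar)) {
      as.numeric(readLines(sidecar, n = 1L))
    } else {
      nrow(reads)
    }
  }
  read_library(reads, mapped_total)
}

#' Construct a read library
#'
#' @param reads data.frame with columns \code{chrom}, \code{start},
#'   \code{end} and optionally \code{strand} (default \code{"+"}).
#' @param mapped_total Mapped filtered read total for rpm normalization;
#'   defaults to \code{nrow(reads)}.
#' @return Object of class \code{read_library}: a list with elements
#'   \code{reads} and \code{mapped_total}.
#' @export
read_library <- function(reads, mapped_total = nrow(reads)) {
  if (is.null(reads$strand)) reads$strand <- rep("+", nrow(reads))
  if (nrow(reads) > 0L && any(reads$end <= reads$start)) {
    stop("every read must have end > start")
  }
  structure(list(reads = reads, mapped_total = as.numeric(mapped_total)),
            class = "read_library")
}

#' @export
print.read_library <- function(x, ...) {
  cat("read_library:", nrow(x$reads), "stored reads;",
      format(x$mapped_total, big.mark = ","), "mapped total\n")
  invisible(x)
}

#' Write a read library as BED6 (plus a .total sidecar)
#'
#' @param lib A \code{read_library}.
#' @param path Output BED path.
#' @export
write_alignments <- function(lib, path) {
  r <- lib$reads
  df <- data.frame(r$chrom, format_coord(r$start), format_coord(r$end),
                   ".", 0L, r$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(format_coord(lib$mapped_total), paste0(path, ".total"))
  invisible(path)
}

#' Read an expression table (genes x samples, FPKM)
#'
#' Expects a tab-separated file with a header row of sample/cell/time
#' labels and gene ids in the first column. \code{NA} cells are preserved
#' as missing values, never coerced to zero.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene ids as rownames.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate gene_id in expression table: ",
         ids[duplicated(ids)][1L])
  }
  vals <- df[, -1L, drop = FALSE]
  m <- matrix(NA_real_, nrow = nrow(vals), ncol = ncol(vals),
              dimnames = list(ids, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    col <- vals[[j]]
    if (is.character(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- !is.na(col) & col != "NA" & is.na(num)
      if (any(bad)) {
        stop("non-numeric cell in column '", colnames(vals)[j], "': '",
             col[bad][1L], "'")
      }
      col <- num
    }
    m[, j] <- as.numeric(col)
  }
  m
}

#' Write an expression table
#'
#' @param mat Numeric matrix, gene ids as rownames.
#' @param path Output TSV path.
#' @param header_comment Optional comment line(s) written before the header
#'   (each prefixed with \code{#}).
#' @export
write_expression_table <- function(mat, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  writeLines(paste(c("gene_id", colnames(mat)), collapse = "\t"), con)
  # 17 significant digits: doubles survive the round trip bit-exactly
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  body <- apply(mat, 1L, function(row) paste(fmt(row), collapse = "\t"))
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

#' Write promoter sequences as FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output FASTA path.
#' @export
write_promoter_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read promoter sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_promoter_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
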