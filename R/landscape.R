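## The TSSR vs gene-body density plane: hexagonal binning with a
## third-variable overlay, the log-scale trend spline, and inflection
## detection by maximum second derivative.

#' Hexagonal binning with a third-variable overlay
#'
#' Assigns each (x, y) point to the nearest centre of a hexagonal lattice
#' spanning the bounding box (\code{n_bins} hexagons across x) and
#' summarises each occupied bin: gene count and the mean of a third
#' variable. Genes with missing z contribute to the count but not the
#' mean; genes with non-finite x or y are excluded and counted in the
#' \code{n_excluded} attribute.
#'
#' @param x,y Coordinates (e.g. log10 TSSR and gene-body densities).
#' @param z Optional third variable (e.g. log10 FPKM).
#' @param n_bins Number of hexagons across the x range (>= 2).
#' @return data.frame: \code{bin_id}, \code{x_center}, \code{y_center},
#'   \code{n_genes}, \code{mean_z}.
#' @export
hexbin_summary <- function(x, y, z = NULL, n_bins = 50L) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  stopifnot(length(x) == length(y))
  if (is.null(z)) z <- rep(NA_real_, length(x))
  ok <- is.finite(x) & is.finite(y)
  n_excluded <- sum(!ok)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  cell <- hex_assign(x, y, n_bins)
  key <- paste(cell$col, cell$row)
  groups <- split(seq_along(x), key)
  rows <- lapply(groups, function(idx) {
    data.frame(col = cell$col[idx[1L]], row = cell$row[idx[1L]],
               x_center = cell$cx[idx[1L]], y_center = cell$cy[idx[1L]],
               n_genes = length(idx),
               mean_z = if (all(is.na(z[idx]))) NA_real_
                        else mean(z[idx], na.rm = TRUE))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$row, out$col), ]
  out <- data.frame(bin_id = seq_len(nrow(out)),
                    out[, c("x_center", "y_center", "n_genes", "mean_z")])
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

## Nearest-centre assignment on a hexagonal lattice: two offset
## rectangular grids (even rows at integer columns, odd rows shifted by
## half a cell), row spacing sqrt(3)/2 of the cell width in scaled units.
hex_assign <- function(x, y, n_bins) {
  xr <- range(x); yr <- range(y)
  w <- if (diff(xr) > 0) diff(xr) / n_bins else 1
  h <- w * sqrt(3) / 2
  sx <- (x - xr[1]) / w
  sy <- (y - yr[1]) / h
  # candidate A: even-row lattice (centres at integer col, even row)
  rowA <- 2 * round(sy / 2)
  colA <- round(sx)
  # candidate B: odd-row lattice (centres offset half a column)
  rowB <- 2 * floor(sy / 2) + 1
  colB <- floor(sx) + 0.5
  # distances in x units: dy scaled back by h/w = sqrt(3)/2
  dA <- (sx - colA)^2 + ((sy - rowA) * sqrt(3) / 2)^2
  dB <- (sx - colB)^2 + ((sy - rowB) * sqrt(3) / 2)^2
  useB <- dB < dA
  col <- ifelse(useB, colB, colA)
  row <- ifelse(useB, rowB, rowA)
  list(col = col, row = row,
       cx = xr[1] + col * w, cy = yr[1] + row * h)
}

#' Fit the TSSR to gene-body density trend
#'
#' Cubic smoothing spline (automatic smoothness) of log10 gene-body
#' density on log10 TSSR density, over genes where both
#' background-subtracted densities are positive.
#'
#' @param tssr_density,gb_density Numeric vectors (rpm/bp).
#' @param min_genes Minimum usable genes (default 100).
#' @return A \code{trend_curve} fitted on the log10 scale.
#' @export
fit_density_trend <- function(tssr_density, gb_density, min_genes = 100L) {
  ok <- !is.na(tssr_density) & !is.na(gb_density) &
    tssr_density > 0 & gb_density > 0
  if (sum(ok) < min_genes) {
    stop("need >= ", min_genes, " genes with positive densities")
  }
  fit_trend(log10(tssr_density[ok]), log10(gb_density[ok]))
}

#' Locate the inflection of a density trend
#'
#' Evaluates the second derivative of the fitted trend on a fine grid
#' over the interior of the x range (5th-95th percentile of the fitted x
#' data by default, avoiding spline boundary artifacts) and reports the
#' x of maximum curvature; ties take the smallest x. When the maximum
#' curvature is below \code{min_curvature} the result is flagged so
#' callers can treat the trend as having no inflection.
#'
#' @param trend A \code{trend_curve}.
#' @param n_grid Grid size (default 512).
#' @param interior Quantile range of x to scan (default c(0.05, 0.95)).
#' @param min_curvature Curvature floor below which
#'   \code{low_curvature} is set (default 0.1; fitted lines sit orders
#'   of magnitude below it, genuine breakpoints well above).
#' @return list of class \code{inflection_result}: \code{x_star},
#'   \code{curvature}, \code{low_curvature}, \code{grid} (x, d2),
#'   \code{trend}.
#' @export
find_inflection <- function(trend, n_grid = 512L,
                            interior = c(0.05, 0.95),
                            min_curvature = 0.1) {
  qs <- stats::quantile(trend$x, probs = interior, names = FALSE)
  grid <- seq(qs[1], qs[2], length.out = n_grid)
  d2 <- predict(trend, x = grid, deriv = 2)$y
  i <- which.max(d2)  # first maximum = smallest x on ties
  structure(list(x_star = grid[i], curvature = d2[i],
                 low_curvature = d2[i] < min_curvature,
                 grid = data.frame(x = grid, d2 = d2),
                 trend = trend),
            class = "inflection_result")
}

#' @export
print.inflection_result <- function(x, ...) {
  cat("inflection_result: x_star =", format(x$x_star, digits = 4),
      "(curvature", format(x$curvature, digits = 3),
      if (x$low_curvature) "; LOW curvature - no clear inflection)" else ")",
      "\n")
  invisible(x)
}

#' Enrichment of genes past the inflection point
#'
#' Genes with log10 TSSR density above \code{x_star} form the right set;
#' reports the fraction of highly expressed genes (FPKM above
#' \code{fpkm_high}) in the right set versus the background, a Fisher
#' test of that contrast, and Fisher gene-set tests for any user-supplied
#' annotation sets. All statistics are missing when the right set is
#' empty.
#'
#' @param gene_ids Character vector of gene ids.
#' @param log10_tssr log10 TSSR density per gene.
#' @param x_star Inflection location from \code{\link{find_inflection}}.
#' @param fpkm FPKM per gene.
#' @param fpkm_high High-expression threshold (default 1000).
#' @param annotations Optional named list of gene-id sets.
#' @return list: \code{right_set}, \code{frac_high_right},
#'   \code{frac_high_background}, \code{fisher_high} (\code{pk_test}),
#'   \code{annotation_results} (data.frame with p, odds ratio, q-values
#'   when > 10 sets are tested).
#' @export
past_inflection_enrichment <- function(gene_ids, log10_tssr, x_star, fpkm,
                                       fpkm_high = 1000,
                                       annotations = NULL) {
  right <- !is.na(log10_tssr) & log10_tssr > x_star
  right_set <- gene_ids[right]
  if (length(right_set) == 0L) {
    return(list(right_set = character(), frac_high_right = NA_real_,
                frac_high_background = NA_real_, fisher_high = NULL,
                annotation_results = NULL))
  }
  high <- !is.na(fpkm) & fpkm > fpkm_high
  frac_right <- mean(high[right])
  frac_bg <- mean(high[!right])
  fisher_high <- fisher_geneset(right_set, gene_ids[high], gene_ids)
  ann <- NULL
  if (!is.null(annotations) && length(annotations) > 0L) {
    res <- lapply(annotations, function(set) {
      fisher_geneset(right_set, set, gene_ids)
    })
    ann <- data.frame(annotation = names(annotations),
                      overlap = vapply(res, `[[`, 0, "statistic"),
                      odds_ratio = vapply(res, `[[`, 0, "odds_ratio"),
                      p_value = vapply(res, `[[`, 0, "p_value"),
                      stringsAsFactors = FALSE)
    if (nrow(ann) > 10L) {
      ann$q_value <- multiple_testing(ann$p_value, mode = "qvalue")$q_value
    }
    rownames(ann) <- NULL
  }
  list(right_set = right_set, frac_high_right = frac_right,
       frac_high_background = frac_bg, fisher_high = fisher_high,
       annotation_results = ann)
}
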