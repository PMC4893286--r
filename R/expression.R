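## Expression coupling: paused/expressed overlap, the hill-shaped
## PI-expression trend, single-cell CV analysis, and stimulus-response
## classification with PI-shift testing.

#' Overlap of expressed and paused genes
#'
#' @param pi Numeric PI vector (NA = no assigned PI).
#' @param fpkm FPKM vector on the same gene universe.
#' @param fpkm_min Expression threshold (genes with FPKM >= this are
#'   expressed; default 1).
#' @param pi_threshold Paused threshold (default 2).
#' @return list: \code{expressed}, \code{expressed_paused}, \code{all},
#'   and the full 2x2 \code{table} (expressed x paused).
#' @export
expressed_paused_overlap <- function(pi, fpkm, fpkm_min = 1,
                                     pi_threshold = 2) {
  stopifnot(length(pi) == length(fpkm))
  expressed <- !is.na(fpkm) & fpkm >= fpkm_min
  paused <- call_paused(pi, pi_threshold)
  list(expressed = sum(expressed),
       expressed_paused = sum(expressed & paused),
       all = length(pi),
       table = table(expressed = expressed, paused = paused))
}

## Sliding-window sample quantiles over a numeric vector (values assumed
## already ordered by the covariate); linear-interpolation quantiles,
## window centred with edge shrinkage.
running_quantile <- function(y, window, probs) {
  n <- length(y)
  half <- window %/% 2L
  out <- matrix(NA_real_, n, length(probs))
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i, ] <- stats::quantile(y[lo:hi], probs = probs, na.rm = TRUE,
                                names = FALSE)
  }
  out
}

#' PI-expression trend with running quantile bands
#'
#' Fits a cubic smoothing spline of log10 FPKM on log10 PI (automatic
#' smoothness, or a fixed low df for aggregate curves), plus smoothed
#' running 25%/75% quantile bands computed in a sliding window over
#' PI-ordered genes. Bands are clipped so the lower band never exceeds
#' the mean curve and the upper band never falls below it.
#'
#' @param pi,fpkm Numeric vectors; only genes with both values positive
#'   enter the fit (>= 50 required).
#' @param df Spline degrees of freedom (NULL = automatic; use 4 for
#'   aggregate curves).
#' @param window Running-quantile window in genes; default
#'   \code{max(51, round(0.05 n))}, forced odd.
#' @param n_grid Evaluation grid size (default 200).
#' @return list of class \code{pi_trend}: \code{curve} (a
#'   \code{trend_curve}), \code{grid} (x, fit, lower, upper), \code{n},
#'   \code{window}.
#' @export
pi_expression_trend <- function(pi, fpkm, df = NULL, window = NULL,
                                n_grid = 200L) {
  ok <- !is.na(pi) & !is.na(fpkm) & pi > 0 & fpkm > 0
  if (sum(ok) < 50L) stop("need >= 50 genes with positive PI and FPKM")
  x <- log10(pi[ok]); y <- log10(fpkm[ok])
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  n <- length(x)
  if (is.null(window)) window <- max(51L, round(0.05 * n))
  if (window %% 2L == 0L) window <- window + 1L
  curve <- fit_trend(x, y, df = df)
  bands <- running_quantile(y, window, c(0.25, 0.75))
  # smooth the raw running quantiles, then clip at the mean trend
  grid_x <- seq(min(x), max(x), length.out = n_grid)
  lower <- stats::predict(stats::smooth.spline(x, bands[, 1L]), x = grid_x)$y
  upper <- stats::predict(stats::smooth.spline(x, bands[, 2L]), x = grid_x)$y
  fit <- predict(curve, x = grid_x)$y
  grid <- data.frame(x = grid_x, fit = fit,
                     lower = pmin(lower, fit), upper = pmax(upper, fit))
  structure(list(curve = curve, grid = grid, n = n, window = window),
            class = "pi_trend")
}

#' @export
print.pi_trend <- function(x, ...) {
  peak <- x$grid$x[which.max(x$grid$fit)]
  cat("pi_trend:", x$n, "genes; spline df =",
      format(x$curve$df, digits = 4),
      "; fitted peak at log10 PI =", format(peak, digits = 3), "\n")
  invisible(x)
}

#' Single-cell expression variability by pausing state
#'
#' Computes the coefficient of variation (sample SD over mean) of each
#' expressed gene across cells, bins expressed genes into mean-expression
#' quantiles, and compares paused versus non-paused CV distributions per
#' bin with a two-sided Mann-Whitney U test.
#'
#' @param cells Genes x cells FPKM matrix (>= 2 cells).
#' @param paused Logical vector (same gene order) of paused calls.
#' @param n_quantiles Number of expression bins (default 5, i.e. 20\%
#'   quantiles).
#' @param fpkm_min Expressed = mean FPKM across cells >= this (default 1).
#' @return data.frame: per bin, gene counts, median CVs and the MWU p
#'   (NA when either group has < 2 genes in the bin). The per-gene CVs
#'   are attached as attribute \code{cv}.
#' @export
single_cell_cv <- function(cells, paused, n_quantiles = 5L, fpkm_min = 1) {
  if (ncol(cells) < 2L) stop("need >= 2 cells")
  stopifnot(nrow(cells) == length(paused))
  mu <- rowMeans(cells, na.rm = TRUE)
  expressed <- !is.na(mu) & mu >= fpkm_min
  cv <- apply(cells, 1L, stats::sd, na.rm = TRUE) / mu
  idx <- which(expressed)
  # quantile bin edges by mean FPKM (linear-interpolation sample quantiles)
  edges <- stats::quantile(mu[idx], probs = seq(0, 1, length.out = n_quantiles + 1L))
  bin <- cut(mu[idx], breaks = unique(edges), include.lowest = TRUE,
             labels = FALSE)
  res <- lapply(sort(unique(bin)), function(b) {
    sel <- idx[bin == b]
    cvp <- cv[sel][paused[sel]]
    cvn <- cv[sel][!paused[sel]]
    p <- if (length(cvp) >= 2L && length(cvn) >= 2L) {
      mann_whitney(cvp, cvn)$p_value
    } else {
      NA_real_
    }
    med <- function(v) if (length(v)) stats::median(v) else NA_real_
    data.frame(bin = b, n_paused = length(cvp), n_nonpaused = length(cvn),
               median_cv_paused = med(cvp),
               median_cv_nonpaused = med(cvn),
               p_value = p)
  })
  out <- do.call(rbind, res)
  attr(out, "cv") <- cv
  attr(out, "expressed") <- expressed
  out
}

#' Classify stimulus-response from a time course
#'
#' Fold changes are relative to the baseline (first) column. Labels:
#' \describe{
#'   \item{excluded}{FPKM below \code{fpkm_min} at every time point, or
#'     not expressed throughout while never responsive.}
#'   \item{early}{>= \code{fold}-fold increase at a time point within
#'     \code{early_window} hours.}
#'   \item{late}{>= \code{fold}-fold increase only at later time points.}
#'   \item{down}{>= \code{fold}-fold decrease at any time point.}
#'   \item{non_responsive}{expressed (>= \code{fpkm_min}) at every time
#'     point with all fold changes strictly inside (1/fold, fold).}
#' }
#' A gene qualifying both up and down is labelled by its first qualifying
#' event in time (ties go to the up event). A zero baseline with a later
#' positive value counts as an up event.
#'
#' @param tc Genes x time points FPKM matrix; column names are numeric
#'   times in hours, first column the unstimulated baseline (time 0).
#' @param early_window Hours defining "early" (default 1).
#' @param fold Fold-change threshold (default 2).
#' @param fpkm_min Expression floor (default 1).
#' @return data.frame: \code{gene_id}, \code{label}.
#' @export
classify_response <- function(tc, early_window = 1, fold = 2, fpkm_min = 1) {
  times <- as.numeric(colnames(tc))
  if (length(times) < 2L || anyNA(times)) {
    stop("columns must be numeric time labels with >= 2 time points")
  }
  if (times[1L] != 0) stop("first column must be the baseline (time 0)")
  labels <- character(nrow(tc))
  for (i in seq_len(nrow(tc))) {
    v <- tc[i, ]
    if (all(is.na(v)) || all(v[!is.na(v)] < fpkm_min)) {
      labels[i] <- "excluded"
      next
    }
    base <- v[1L]
    fc <- v[-1L] / base
    fc[base == 0 & v[-1L] > 0] <- Inf  # zero baseline, later signal: up
    t_later <- times[-1L]
    up_times <- t_later[!is.na(fc) & fc >= fold]
    down_times <- t_later[!is.na(fc) & fc <= 1 / fold]
    first_up <- if (length(up_times)) min(up_times) else Inf
    first_down <- if (length(down_times)) min(down_times) else Inf
    if (is.finite(first_up) && first_up <= first_down) {
      labels[i] <- if (first_up <= early_window) "early" else "late"
    } else if (is.finite(first_down)) {
      labels[i] <- "down"
    } else if (all(!is.na(v) & v >= fpkm_min) &&
               all(!is.na(fc) & fc > 1 / fold & fc < fold)) {
      labels[i] <- "non_responsive"
    } else {
      labels[i] <- "excluded"
    }
  }
  data.frame(gene_id = rownames(tc), label = labels,
             stringsAsFactors = FALSE)
}

#' PI-shift tests across a stimulation time course
#'
#' Two families of two-sided Mann-Whitney U tests: (1) baseline PI of
#' responsive (early + late + down) versus non-responsive genes, with the
#' non-responsive group subsampled without replacement to the responsive
#' count; (2) for each response class and each non-baseline time point,
#' the class's PI at that time versus baseline (the non-responsive class
#' is subsampled the same way). All p-values pass through the Bonferroni
#' FWER gate.
#'
#' @param pi_by_time Genes x time points PI matrix (column names numeric
#'   times, first = baseline).
#' @param labels data.frame from \code{\link{classify_response}}.
#' @param seed Integer seed for the subsampling.
#' @param alpha FWER alpha (default 0.05).
#' @return data.frame: \code{comparison}, \code{class}, \code{time},
#'   \code{n1}, \code{n2}, \code{p_value}, \code{passes_fwer} (p missing
#'   for classes with < 3 genes).
#' @export
pi_shift_test <- function(pi_by_time, labels, seed = 1, alpha = 0.05) {
  times <- as.numeric(colnames(pi_by_time))
  stopifnot(nrow(pi_by_time) == nrow(labels))
  set.seed(seed)
  lab <- labels$label
  responsive <- lab %in% c("early", "late", "down")
  nonresp <- lab == "non_responsive"
  n_resp <- sum(responsive)
  sub_nonresp <- which(nonresp)
  if (length(sub_nonresp) > n_resp && n_resp > 0L) {
    sub_nonresp <- sort(sample(sub_nonresp, n_resp))
  }
  rows <- list()
  run_test <- function(x, y) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 3L || length(y) < 3L) return(NA_real_)
    mann_whitney(x, y)$p_value
  }
  rows[[1L]] <- data.frame(
    comparison = "baseline_responsive_vs_nonresponsive",
    class = "responsive", time = times[1L],
    n1 = n_resp, n2 = length(sub_nonresp),
    p_value = run_test(pi_by_time[responsive, 1L],
                       pi_by_time[sub_nonresp, 1L]),
    stringsAsFactors = FALSE)
  classes <- list(early = which(lab == "early"),
                  late = which(lab == "late"),
                  down = which(lab == "down"),
                  non_responsive = sub_nonresp)
  for (cl in names(classes)) {
    sel <- classes[[cl]]
    for (j in seq_along(times)[-1L]) {
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = "time_vs_baseline", class = cl, time = times[j],
        n1 = length(sel), n2 = length(sel),
        p_value = run_test(pi_by_time[sel, j], pi_by_time[sel, 1L]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (all(is.na(out$p_value))) {
    out$passes_fwer <- NA
  } else {
    out$passes_fwer <- multiple_testing(out$p_value, mode = "fwer_gate",
                                        alpha = alpha)$passes_fwer
  }
  out
}
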