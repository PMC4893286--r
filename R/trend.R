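## trend_curve: a thin S3 wrapper around stats::smooth.spline keeping the
## fitted x data so derivative grids and interior ranges are reproducible.

#' Fit a cubic smoothing-spline trend
#'
#' @param x,y Numeric vectors (finite pairs are used).
#' @param df Degrees of freedom; NULL (default) lets generalized
#'   cross-validation choose the smoothness.
#' @return Object of class \code{trend_curve}.
#' @export
fit_trend <- function(x, y, df = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  fit <- if (is.null(df)) {
    stats::smooth.spline(x, y)
  } else {
    stats::smooth.spline(x, y, df = df)
  }
  structure(list(fit = fit, x = x, y = y, df = fit$df,
                 range = range(x)), class = "trend_curve")
}

#' Evaluate a trend curve or its derivatives
#'
#' @param object A \code{trend_curve}.
#' @param x Evaluation points (default: 200-point grid over the fitted
#'   range).
#' @param deriv Derivative order 0, 1 or 2.
#' @param ... Unused.
#' @return data.frame with \code{x} and \code{y}.
#' @export
predict.trend_curve <- function(object, x = NULL, deriv = 0, ...) {
  if (is.null(x)) x <- seq(object$range[1], object$range[2], length.out = 200L)
  p <- stats::predict(object$fit, x = x, deriv = deriv)
  data.frame(x = p$x, y = p$y)
}

#' @export
print.trend_curve <- function(x, ...) {
  cat("trend_curve: cubic smoothing spline, df =", format(x$df, digits = 4),
      "on", length(x$x), "points over [",
      format(x$range[1], digits = 4), ",",
      format(x$range[2], digits = 4), "]\n")
  invisible(x)
}

#' @export
plot.trend_curve <- function(x, ..., n_grid = 200L) {
  grid <- predict(x)
  graphics::plot(x$x, x$y, pch = 16, cex = 0.4, col = "grey50",
                 xlab = "x", ylab = "y", ...)
  graphics::lines(grid$x, grid$y, col = "firebrick", lwd = 2)
  invisible(x)
}
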