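#' Gaussian-kernel (Nadaraya-Watson) smoothing of a dose trace
#'
#' Each fitted value is a weighted average of all observed fold changes,
#' with weights given by the standard normal density of the
#' bandwidth-scaled distance between ordinal dose positions:
#' \deqn{d_k = (x_k - x_i)/b, \quad
#'       wt_k = \frac{1}{\sqrt{2\pi}} e^{-d_k^2/2}, \quad
#'       \hat y_i = \sum_k wt_k y_k / \sum_k wt_k.}
#' The evaluation point participates in its own average (d = 0), so the
#' fitted curve is a convex combination of the data and always lies within
#' their range.
#'
#' @param x Strictly increasing numeric positions (ordinal dose indices).
#' @param y Observed fold changes, same length as \code{x}, no NAs.
#' @param bandwidth Kernel bandwidth \code{b > 0} on the position scale.
#' @return Numeric vector of fitted values, same length as \code{y}.
#' @examples
#' gaussian_kernel_smooth(1:3, c(0, 1, 0), bandwidth = 1)
#' @export
gaussian_kernel_smooth <- function(x, y, bandwidth = 1) {
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0)
    stop("parameter error: bandwidth must be a single positive number")
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("input error: x and y lengths differ")
  if (length(y) < 3L)
    stop("input error: need at least 3 points to smooth")
  if (anyNA(y) || anyNA(x))
    stop("input error: NA in trace")
  if (any(diff(x) <= 0))
    stop("input error: x must be strictly increasing")
  w <- stats::dnorm(outer(x, x, "-") / bandwidth)  # w[i, k] = phi((x_k - x_i)/b)
  # centering leaves the weighted mean unchanged but keeps a constant
  # trace exactly constant in floating point (no spurious runs)
  m <- mean(y)
  as.vector(m + (w %*% (y - m)) / rowSums(w))
}

# Smooth every row of a fold-change matrix that shares positions x.
# Linearity of the weighted mean makes this a single matrix product.
smooth_matrix <- function(y, x, bandwidth) {
  w <- stats::dnorm(outer(x, x, "-") / bandwidth)
  s <- w / rowSums(w)            # s[i, k]: weight of point k in fit at i
  m <- rowMeans(y)
  m + (y - m) %*% t(s)           # centered, as in gaussian_kernel_smooth
}

#' Average slope of a fitted dose-response curve
#'
#' The mean of the slopes (tangents) between every pair of adjacent fitted
#' points; the single-number summary of an entity's dose response. On
#' equally spaced positions it telescopes to
#' \code{(last - first) / (n - 1)}.
#'
#' @param y_hat Fitted values (length >= 2).
#' @param x Positions, same length.
#' @return The average slope in fold change per ordinal dose unit.
#' @export
average_slope <- function(y_hat, x = seq_along(y_hat)) {
  if (length(y_hat) < 2L)
    stop("degenerate error: need at least 2 fitted points for a slope")
  if (length(x) != length(y_hat))
    stop("input error: x and y_hat lengths differ")
  mean(diff(y_hat) / diff(x))
}

#' Longest upward and downward runs of a fitted curve
#'
#' Counts the longest streak of consecutive adjacent pairs that strictly
#' increase, and the longest that strictly decrease. Equal adjacent fitted
#' values terminate both kinds of run.
#'
#' @param y_hat Fitted values (length >= 2).
#' @return Named integer vector \code{c(max_up_run, max_down_run)}.
#' @examples
#' run_statistics(c(1, 1.2, 1.4, 1.5, 1.45, 1.3, 1.15, 1.05, 1.0))
#' @export
run_statistics <- function(y_hat) {
  if (length(y_hat) < 2L)
    stop("degenerate error: need at least 2 points for run statistics")
  d <- diff(y_hat)
  c(max_up_run = longest_run(d > 0), max_down_run = longest_run(d < 0))
}

longest_run <- function(flag) {
  if (!any(flag)) return(0L)
  r <- rle(flag)
  as.integer(max(r$lengths[r$values]))
}

#' Fit a smoothed dose-response curve
#'
#' The central model fit of the package: smooths a first-dose-normalized
#' dose trace with the Gaussian kernel estimator and derives the statistics
#' that drive response classification and hit calling — the average slope,
#' the fitted range, the longest upward/downward runs, and the absolute
#' difference between the curve ends.
#'
#' @param trace A normalized \code{\link{dose_trace}}, or a numeric vector
#'   of fold changes (taken at positions \code{1..n}).
#' @param config A \code{\link{run_config}} supplying the bandwidth and the
#'   excluded positions; alternatively pass \code{bandwidth} directly.
#' @param bandwidth Kernel bandwidth, overriding \code{config}.
#' @return An object of class \code{"dose_curve"}: a list with \code{x},
#'   \code{y}, \code{fitted}, \code{bandwidth}, \code{average_slope},
#'   \code{range_fitted}, \code{max_up_run}, \code{max_down_run},
#'   \code{end_diff} and the entity identifiers, with methods
#'   \code{print}, \code{summary}, \code{coef}, \code{fitted},
#'   \code{residuals}, \code{predict} and \code{plot}.
#' @examples
#' tr <- dose_trace(c(100, 110, 130, 160, 200, 240, 270, 285, 290))
#' fit <- fit_dose_curve(normalize_first_dose(tr), bandwidth = 1)
#' coef(fit)
#' summary(fit)
#' @export
fit_dose_curve <- function(trace, config = NULL, bandwidth = NULL) {
  if (is.numeric(trace)) {
    n <- length(trace)
    design <- if (!is.null(config)) config$design else
      dose_design(doses = seq(0, 1, length.out = n))
    trace <- structure(list(entity_id = NA_character_,
                            replicate_id = NA_integer_,
                            temperature = NA_real_,
                            x = seq_len(n), y = as.numeric(trace),
                            normalized = TRUE),
                       class = "dose_trace")
  }
  stopifnot(inherits(trace, "dose_trace"))
  if (!isTRUE(trace$normalized))
    stop("input error: trace must be first-dose normalized before fitting")
  if (!is.null(config)) {
    stopifnot(inherits(config, "run_config"))
    if (length(config$excluded_positions))
      trace <- drop_excluded_positions(trace, config$excluded_positions)
    if (is.null(bandwidth)) bandwidth <- config$bandwidth
  }
  if (is.null(bandwidth)) bandwidth <- 1
  y_hat <- gaussian_kernel_smooth(trace$x, trace$y, bandwidth)
  runs <- run_statistics(y_hat)
  structure(list(entity_id = trace$entity_id,
                 replicate_id = trace$replicate_id,
                 temperature = trace$temperature,
                 x = trace$x, y = trace$y, fitted = y_hat,
                 bandwidth = bandwidth,
                 average_slope = average_slope(y_hat, trace$x),
                 range_fitted = max(y_hat) - min(y_hat),
                 max_up_run = runs[["max_up_run"]],
                 max_down_run = runs[["max_down_run"]],
                 end_diff = abs(y_hat[length(y_hat)] - y_hat[1L])),
            class = "dose_curve")
}

#' @export
print.dose_curve <- function(x, digits = 4, ...) {
  cat("Gaussian-kernel dose-response fit")
  if (!is.na(x$entity_id)) cat(" for", x$entity_id)
  cat("\n")
  cat(sprintf("  %d dose positions, bandwidth b = %g\n", length(x$x), x$bandwidth))
  cat(sprintf("  average slope: %s (fold change per dose position)\n",
              format(x$average_slope, digits = digits)))
  cat(sprintf("  fitted range: %s; end difference: %s\n",
              format(x$range_fitted, digits = digits),
              format(x$end_diff, digits = digits)))
  cat(sprintf("  longest runs: %d up, %d down\n", x$max_up_run, x$max_down_run))
  invisible(x)
}

#' @export
coef.dose_curve <- function(object, ...) {
  c(average_slope = object$average_slope)
}

#' @export
fitted.dose_curve <- function(object, ...) object$fitted

#' @export
residuals.dose_curve <- function(object, ...) object$y - object$fitted

#' Predict fitted fold changes at new dose positions
#'
#' Evaluates the Nadaraya-Watson estimator (anchored on the observed
#' points) at arbitrary positions.
#'
#' @param object A \code{"dose_curve"}.
#' @param newdata Numeric positions; defaults to the observed positions.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.dose_curve <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  x0 <- as.numeric(newdata)
  w <- stats::dnorm(outer(x0, object$x, "-") / object$bandwidth)
  as.vector((w %*% object$y) / rowSums(w))
}

#' @export
summary.dose_curve <- function(object, config = NULL, ...) {
  s <- object[c("entity_id", "replicate_id", "temperature", "bandwidth",
                "average_slope", "range_fitted", "max_up_run",
                "max_down_run", "end_diff")]
  s$n <- length(object$x)
  s$category <- if (!is.null(config)) classify_curve(object, config) else NA_character_
  class(s) <- "summary.dose_curve"
  s
}

#' @export
print.summary.dose_curve <- function(x, digits = 4, ...) {
  cat("Dose-response curve summary\n")
  cat(sprintf("  n = %d, bandwidth = %g\n", x$n, x$bandwidth))
  cat(sprintf("  average slope  %s\n", format(x$average_slope, digits = digits)))
  cat(sprintf("  fitted range   %s\n", format(x$range_fitted, digits = digits)))
  cat(sprintf("  end difference %s\n", format(x$end_diff, digits = digits)))
  cat(sprintf("  runs           %d up / %d down\n", x$max_up_run, x$max_down_run))
  if (!is.na(x$category)) cat("  category      ", x$category, "\n")
  invisible(x)
}

#' Plot a fitted dose-response curve
#'
#' Observed fold changes as points, the kernel-smoothed curve as a line, on
#' ordinal dose positions.
#'
#' @param x A \code{"dose_curve"}.
#' @param main Plot title; defaults to the entity id.
#' @param ... Passed to \code{plot.default}.
#' @export
plot.dose_curve <- function(x, main = NULL, ...) {
  if (is.null(main))
    main <- if (!is.na(x$entity_id)) x$entity_id else "Dose-response curve"
  graphics::plot(x$x, x$y, pch = 19, xlab = "Dose position (ordinal)",
                 ylab = "Fold change vs. untreated", main = main, ...)
  xx <- seq(min(x$x), max(x$x), length.out = 101)
  graphics::lines(xx, predict(x, xx), col = "#2166AC", lwd = 2)
  invisible(x)
}

# Vectorized curve statistics for a fitted matrix (rows = traces).
curve_stats_matrix <- function(y_hat, x) {
  nd <- ncol(y_hat) - 1L
  d <- y_hat[, -1L, drop = FALSE] - y_hat[, -ncol(y_hat), drop = FALSE]
  slopes <- sweep(d, 2L, diff(x), "/")
  data.frame(
    average_slope = rowMeans(slopes),
    range_fitted = apply(y_hat, 1L, max) - apply(y_hat, 1L, min),
    max_up_run = apply(d > 0, 1L, longest_run),
    max_down_run = apply(d < 0, 1L, longest_run),
    end_diff = abs(y_hat[, ncol(y_hat)] - y_hat[, 1L]))
}
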