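category_colors <- function() {
  c(hyper = "#B2182B", hypo = "#2166AC", biphasic = "#E6B800",
    NR = "grey70")
}

#' Proteome impact scatter plot
#'
#' Each protein's mean average slope at 37 degrees C (constitutive
#' abundance, x-axis) against 52 degrees C (thermal stability, y-axis).
#' Hits are filled; kinases drawn in beige.
#'
#' @param impact Impact table from \code{\link{proteome_impact}}.
#' @param hit_threshold Threshold drawn as dashed guides, default 0.5.
#' @param ... Passed to \code{plot.default}.
#' @return Invisibly, \code{impact}.
#' @export
plot_proteome_impact <- function(impact, hit_threshold = 0.5, ...) {
  x <- impact$slope_37
  y <- impact$slope_52
  lim <- range(c(x, y, -hit_threshold, hit_threshold), na.rm = TRUE)
  col <- ifelse(impact$is_kinase, "#D4A96A",
                ifelse(impact$is_hit, "#B2182B", "grey60"))
  graphics::plot(x, y, xlim = lim, ylim = lim,
                 pch = ifelse(impact$is_hit, 19, 1), col = col,
                 xlab = "Average slope, 37 °C (abundance)",
                 ylab = "Average slope, 52 °C (thermal stability)",
                 main = "Proteome impact", ...)
  graphics::abline(h = c(-1, 1) * hit_threshold,
                   v = c(-1, 1) * hit_threshold, lty = 2, col = "grey40")
  invisible(impact)
}

#' Phospho-response scatter plot
#'
#' Phosphosites plotted by their number of continuous upward intervals
#' (x-axis) against the mean average slope at 37 degrees C (y-axis),
#' colored by final response category.
#'
#' @param calls Phospho-response table from \code{\link{phospho_response}}.
#' @param ... Passed to \code{plot.default}.
#' @return Invisibly, \code{calls}.
#' @export
plot_phospho_response <- function(calls, ...) {
  cols <- category_colors()
  if (!nrow(calls)) {
    graphics::plot(0, 0, type = "n",
                   xlab = "Continuous upward intervals",
                   ylab = "Mean average slope (37 °C)",
                   main = "Phospho-response")
    return(invisible(calls))
  }
  jit <- calls$upward_intervals +
    stats::runif(nrow(calls), -0.18, 0.18)
  graphics::plot(jit, calls$mean_slope,
                 col = cols[calls$final_category], pch = 19, cex = 0.6,
                 xlab = "Continuous upward intervals",
                 ylab = "Mean average slope (37 °C)",
                 main = "Phospho-response", ...)
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 19,
                   bty = "n", cex = 0.8)
  invisible(calls)
}

#' Panel of per-entity dose-response curves
#'
#' Draws the two replicate curves (observed points and kernel-smoothed
#' fits) for a handful of entities, colored by final category bars as in
#' per-site response panels.
#'
#' @param rows Complete, deduplicated site or protein table (one row per
#'   entity x replicate).
#' @param entities Character vector of entity ids to draw (at most 9).
#' @param config A \code{\link{run_config}}.
#' @return Invisibly, NULL.
#' @export
plot_curve_panel <- function(rows, entities, config) {
  entities <- utils::head(unique(entities), 9L)
  if (!length(entities)) return(invisible(NULL))
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(entities)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  repcol <- c("#1B7837", "#8C510A")
  for (id in entities) {
    sub <- rows[rows$entity_id == id, , drop = FALSE]
    reps <- sort(unique(sub$replicate_id))
    tm <- trace_matrix(sub, config)
    graphics::plot(NA, xlim = range(tm$x), ylim = range(tm$y),
                   xlab = "Dose position", ylab = "Fold change", main = id)
    for (j in seq_along(reps)) {
      y <- tm$y[sub$replicate_id == reps[j], , drop = FALSE][1L, ]
      yh <- gaussian_kernel_smooth(tm$x, y, config$bandwidth)
      graphics::points(tm$x, y, col = repcol[j], pch = 19, cex = 0.7)
      graphics::lines(tm$x, yh, col = repcol[j], lwd = 2)
    }
  }
  invisible(NULL)
}
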