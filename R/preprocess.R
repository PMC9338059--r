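#' Filter phosphosites by localization probability
#'
#' Removes rows whose phosphosite localization probability is strictly below
#' \code{min_prob}; a site sitting exactly at the boundary is kept.
#'
#' @param rows Site table from \code{\link{read_site_table}}.
#' @param min_prob Minimum localization probability in [0, 1]. Default 0.5.
#' @return The filtered table; number of removed rows reported via
#'   \code{message} and stored in attribute \code{"n_removed"}.
#' @export
filter_localization <- function(rows, min_prob = 0.5) {
  if (min_prob < 0 || min_prob > 1)
    stop("parameter error: min_prob must lie in [0, 1]")
  keep <- rows$localization_prob >= min_prob
  removed <- sum(!keep)
  if (removed) message(removed, " site row(s) below localization probability ",
                       min_prob, " removed")
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "design") <- attr(rows, "design")
  attr(out, "n_removed") <- removed
  out
}

#' Collapse site multiplicity variants to the best-localized row
#'
#' The same site (protein, position, residue) may appear in several rows
#' (e.g. multiply phosphorylated peptide variants); per replicate and
#' temperature only the row with the highest localization probability is
#' kept (first occurrence on ties).
#'
#' @param rows Site table.
#' @return Deduplicated site table.
#' @export
collapse_site_variants <- function(rows) {
  if (!nrow(rows)) return(rows)
  key <- paste(rows$entity_id, rows$replicate_id, rows$temperature, sep = "\r")
  ord <- order(key, -rows$localization_prob, method = "radix")
  out <- rows[ord, , drop = FALSE]
  out <- out[!duplicated(key[ord]), , drop = FALSE]
  out <- out[order(out$entity_id, out$temperature, out$replicate_id,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "design") <- attr(rows, "design")
  out
}

#' Keep entities quantified with nonzero intensity in both replicates
#'
#' An entity (site or protein) is retained at a given temperature only if it
#' is present in both replicates there and every dose channel has a strictly
#' positive intensity in both. Completeness is evaluated per temperature, so
#' an entity may survive at 37 degrees C and be dropped at 52 degrees C.
#'
#' @param rows Site or protein table (one row per entity x replicate x
#'   temperature, i.e. after \code{\link{collapse_site_variants}} /
#'   \code{\link{aggregate_protein}}).
#' @param n_replicates Required number of replicates, default 2.
#' @return The filtered table.
#' @export
filter_complete <- function(rows, n_replicates = 2L) {
  if (!nrow(rows)) return(rows)
  ic <- intensity_cols(rows)
  ok_row <- rowSums(as.matrix(rows[ic]) > 0) == length(ic)
  grp <- paste(rows$entity_id, rows$temperature, sep = "\r")
  n_ok <- tapply(ok_row, grp, sum)
  n_reps <- tapply(rows$replicate_id, grp, function(r) length(unique(r)))
  complete <- names(n_ok)[n_ok == n_replicates & n_reps == n_replicates]
  out <- rows[grp %in% complete & ok_row, , drop = FALSE]
  dropped <- length(unique(grp)) - length(complete)
  if (dropped) message(dropped, " entity/temperature group(s) dropped as incomplete")
  rownames(out) <- NULL
  attr(out, "design") <- attr(rows, "design")
  out
}

#' Aggregate peptide rows to one summed trace per protein
#'
#' Peptide intensities of the same protein are summed channel-wise, per
#' replicate and temperature, before curve fitting.
#'
#' @param rows Protein/peptide table from \code{\link{read_protein_table}}.
#' @return One row per protein x replicate x temperature with summed
#'   intensities.
#' @export
aggregate_protein <- function(rows) {
  if (!nrow(rows)) return(rows)
  ic <- intensity_cols(rows)
  key <- paste(rows$protein_id, rows$replicate_id, rows$temperature, sep = "\r")
  first <- !duplicated(key)
  out <- rows[first, , drop = FALSE]
  sums <- rowsum(as.matrix(rows[ic]), group = key, reorder = FALSE)
  out[ic] <- sums[match(key[first], rownames(sums)), , drop = FALSE]
  if ("is_kinase" %in% names(rows)) {
    kin <- tapply(rows$is_kinase, key, any)
    out$is_kinase <- as.logical(kin[match(key[first], names(kin))])
  }
  out <- out[order(out$protein_id, out$temperature, out$replicate_id,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "design") <- attr(rows, "design")
  out
}

#' Construct a dose trace from a table row
#'
#' A dose trace is one entity's abundances across the retained ordinal dose
#' positions for one replicate at one temperature.
#'
#' @param y Numeric abundance vector, one value per dose position.
#' @param design A \code{\link{dose_design}}.
#' @param entity_id,replicate_id,temperature Identifiers carried along.
#' @return Object of class \code{"dose_trace"} with fields \code{x}
#'   (ordinal positions), \code{y}, \code{normalized}.
#' @export
dose_trace <- function(y, design = dose_design(), entity_id = NA_character_,
                       replicate_id = NA_integer_, temperature = NA_real_) {
  y <- as.numeric(y)
  if (length(y) != length(design$positions))
    stop("design error: trace length ", length(y), " does not match the ",
         length(design$positions), "-dose design")
  structure(list(entity_id = entity_id, replicate_id = replicate_id,
                 temperature = temperature,
                 x = design$positions, y = y, normalized = FALSE),
            class = "dose_trace")
}

#' Drop excluded ordinal positions from a trace
#'
#' User-specified outlier dose positions (experiment-level channel
#' artifacts) are removed before fitting; the surviving points keep their
#' original ordinal labels so smoothing distances remain on the design
#' scale.
#'
#' @param trace A \code{\link{dose_trace}}.
#' @param excluded Integer vector of ordinal positions to drop.
#' @return The shortened trace; at least 3 points must survive.
#' @export
drop_excluded_positions <- function(trace, excluded = integer()) {
  stopifnot(inherits(trace, "dose_trace"))
  excluded <- as.integer(excluded)
  keep <- !(trace$x %in% excluded)
  if (sum(keep) < 3L)
    stop("degenerate-trace error: fewer than 3 dose points remain after exclusion")
  trace$x <- trace$x[keep]
  trace$y <- trace$y[keep]
  trace
}

#' Normalize a trace to fold changes relative to the first dose
#'
#' Every abundance is divided by the abundance at the first retained dose
#' (the vehicle/untreated condition), so the trace starts at exactly 1.
#'
#' @param trace A \code{\link{dose_trace}}.
#' @return The normalized trace (\code{normalized = TRUE}). Idempotent.
#' @export
normalize_first_dose <- function(trace) {
  stopifnot(inherits(trace, "dose_trace"))
  if (isTRUE(trace$normalized)) return(trace)
  y0 <- trace$y[1L]
  if (!is.finite(y0) || y0 == 0)
    stop("normalization error: first-dose abundance is zero or missing for entity ",
         trace$entity_id)
  trace$y <- trace$y / y0
  trace$normalized <- TRUE
  trace
}

#' @export
print.dose_trace <- function(x, ...) {
  cat(sprintf("Dose trace %s (replicate %s, %s degC)%s\n",
              x$entity_id, x$replicate_id, x$temperature,
              if (x$normalized) ", first-dose normalized" else ""))
  print(data.frame(position = x$x, y = x$y), row.names = FALSE)
  invisible(x)
}

# Build the normalized intensity matrix used by the vectorized pipeline:
# rows = table rows, columns = retained positions. Assumes filter_complete
# has run (first-dose intensities strictly positive).
trace_matrix <- function(rows, config) {
  ic <- intensity_cols(rows)
  keep <- !(seq_along(ic) %in% config$excluded_positions)
  if (sum(keep) < 3L)
    stop("degenerate-trace error: fewer than 3 dose points remain after exclusion")
  y <- as.matrix(rows[ic])[, keep, drop = FALSE]
  x <- config$design$positions[keep]
  if (any(y[, 1L] <= 0))
    stop("normalization error: nonpositive first-dose intensity; run filter_complete first")
  list(x = x, y = y / y[, 1L])
}
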