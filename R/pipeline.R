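#' Phosphosite dose-response analysis, end to end
#'
#' Runs the full phosphoproteomics arm of the workflow on parsed site rows:
#' localization filtering, collapsing of site multiplicity variants,
#' completeness filtering across both replicates, first-dose normalization,
#' Gaussian-kernel fitting of each replicate, per-replicate response
#' classification, replicate reconciliation, and assembly of the
#' phospho-response table.
#'
#' @param rows Site table from \code{\link{read_site_table}} (or several
#'   \code{rbind}-ed tables), containing exactly two replicates at the
#'   analysis temperature.
#' @param config A \code{\link{run_config}}.
#' @param temperature Temperature arm to analyse, default 37.
#' @return List of class \code{"phospho_result"}: \code{calls} (the
#'   \code{\link{phospho_response}} table), \code{manifest} (a
#'   \code{\link{run_manifest}}).
#' @export
analyze_phospho <- function(rows, config, temperature = 37) {
  stopifnot(inherits(config, "run_config"))
  rows <- rows[rows$temperature == temperature, , drop = FALSE]
  n_parsed <- nrow(rows)
  reps <- sort(unique(rows$replicate_id))
  if (n_parsed && length(reps) != 2L)
    stop("config error: expected exactly 2 replicates, found ",
         length(reps), " (", paste(reps, collapse = ", "), ")")
  loc <- filter_localization(rows, config$min_localization)
  dedup <- collapse_site_variants(loc)
  complete <- filter_complete(dedup)
  calls <- fit_and_call(complete, config)
  result <- phospho_response(calls)
  counts <- attr(result, "counts")
  manifest <- run_manifest(
    config = config,
    counts = list(parsed = n_parsed,
                  after_localization = nrow(loc),
                  after_dedup = nrow(dedup),
                  entities_complete = if (nrow(complete))
                    length(unique(complete$entity_id)) else 0L,
                  classified = as.list(counts)))
  structure(list(calls = result, manifest = manifest),
            class = "phospho_result")
}

# Fit both replicates of every complete entity and reconcile.
fit_and_call <- function(rows, config) {
  empty <- data.frame(entity_id = character(), protein_id = character(),
                      gene = character(), site_position = integer(),
                      residue = character(),
                      slope_rep1 = numeric(), slope_rep2 = numeric(),
                      category_rep1 = character(), category_rep2 = character(),
                      final_category = character(), mean_slope = numeric(),
                      upward_intervals = integer(), stringsAsFactors = FALSE)
  if (!nrow(rows)) return(empty)
  reps <- sort(unique(rows$replicate_id))
  r1 <- rows[rows$replicate_id == reps[1L], , drop = FALSE]
  r2 <- rows[rows$replicate_id == reps[2L], , drop = FALSE]
  ids <- intersect(r1$entity_id, r2$entity_id)
  if (!length(ids)) return(empty)
  r1 <- r1[match(ids, r1$entity_id), , drop = FALSE]
  r2 <- r2[match(ids, r2$entity_id), , drop = FALSE]
  tm1 <- trace_matrix(r1, config)
  tm2 <- trace_matrix(r2, config)
  f1 <- smooth_matrix(tm1$y, tm1$x, config$bandwidth)
  f2 <- smooth_matrix(tm2$y, tm2$x, config$bandwidth)
  s1 <- curve_stats_matrix(f1, tm1$x)
  s2 <- curve_stats_matrix(f2, tm2$x)
  cat1 <- classify_stats(s1$range_fitted, s1$average_slope, s1$max_up_run,
                         s1$max_down_run, s1$end_diff, config)
  cat2 <- classify_stats(s2$range_fitted, s2$average_slope, s2$max_up_run,
                         s2$max_down_run, s2$end_diff, config)
  mean_fit <- (f1 + f2) / 2
  dmean <- mean_fit[, -1L, drop = FALSE] - mean_fit[, -ncol(mean_fit), drop = FALSE]
  data.frame(entity_id = ids,
             protein_id = r1$protein_id,
             gene = r1$gene,
             site_position = if ("site_position" %in% names(r1))
               r1$site_position else NA_integer_,
             residue = if ("residue" %in% names(r1)) r1$residue
               else NA_character_,
             slope_rep1 = s1$average_slope,
             slope_rep2 = s2$average_slope,
             category_rep1 = cat1,
             category_rep2 = cat2,
             final_category = reconcile_categories(cat1, cat2),
             mean_slope = (s1$average_slope + s2$average_slope) / 2,
             upward_intervals = apply(dmean > 0, 1L, longest_run),
             stringsAsFactors = FALSE)
}

#' Proteome impact analysis, end to end
#'
#' Runs the protein arm of the workflow: peptide-to-protein aggregation,
#' completeness filtering per temperature, first-dose normalization,
#' kernel fitting of every replicate curve at 37 and 52 degrees C, and
#' assembly of the impact table with hit calls.
#'
#' @param rows Protein table from \code{\link{read_protein_table}}
#'   (both temperatures, two replicates each; \code{rbind} several reads
#'   if the experiment is split across files).
#' @param config A \code{\link{run_config}}.
#' @param temperatures The two temperature labels, default \code{c(37, 52)}.
#' @return List of class \code{"proteome_result"}: \code{impact} (the
#'   \code{\link{proteome_impact}} table), \code{slopes} (per
#'   protein x replicate x temperature), \code{manifest}.
#' @export
analyze_proteome <- function(rows, config, temperatures = c(37, 52)) {
  stopifnot(inherits(config, "run_config"))
  rows <- rows[rows$temperature %in% temperatures, , drop = FALSE]
  n_parsed <- nrow(rows)
  agg <- aggregate_protein(rows)
  complete <- filter_complete(agg)
  slopes <- protein_slopes(complete, config)
  impact <- proteome_impact(slopes, config, temperatures)
  manifest <- run_manifest(
    config = config,
    counts = list(parsed = n_parsed,
                  proteins_aggregated = if (nrow(agg))
                    length(unique(agg$protein_id)) else 0L,
                  proteins_complete = if (nrow(complete))
                    length(unique(complete$protein_id)) else 0L,
                  hits = sum(impact$is_hit)))
  structure(list(impact = impact, slopes = slopes, manifest = manifest),
            class = "proteome_result")
}

# Average slope of each protein x replicate x temperature curve.
protein_slopes <- function(rows, config) {
  if (!nrow(rows))
    return(data.frame(protein_id = character(), gene = character(),
                      is_kinase = logical(), replicate_id = integer(),
                      temperature = numeric(), average_slope = numeric(),
                      stringsAsFactors = FALSE))
  tm <- trace_matrix(rows, config)
  f <- smooth_matrix(tm$y, tm$x, config$bandwidth)
  s <- curve_stats_matrix(f, tm$x)
  data.frame(protein_id = rows$protein_id,
             gene = rows$gene,
             is_kinase = if ("is_kinase" %in% names(rows)) rows$is_kinase
               else FALSE,
             replicate_id = rows$replicate_id,
             temperature = rows$temperature,
             average_slope = s$average_slope,
             stringsAsFactors = FALSE)
}

#' Gene-set enrichment of workflow hits
#'
#' Convenience wrapper tying \code{\link{hypergeom_enrichment}} to the
#' outputs of the impact/phospho analyses: hits are tested against the
#' background of all identified proteins.
#'
#' @param hit_ids Character vector of hit protein identifiers.
#' @param background_ids All identified protein identifiers.
#' @param gene_sets Named list from \code{\link{read_gene_sets}}.
#' @param alpha Raw p-value threshold, default 0.05.
#' @return Enrichment data frame (see \code{\link{hypergeom_enrichment}}).
#' @export
run_enrichment <- function(hit_ids, background_ids, gene_sets,
                           alpha = 0.05) {
  hypergeom_enrichment(hit_ids, background_ids, gene_sets, alpha)
}

#' Run manifest: reproducibility record of one workflow invocation
#'
#' @param config The \code{\link{run_config}} used.
#' @param counts Named list of per-stage record counts.
#' @param inputs Optional character vector of input file paths; their MD5
#'   digests are recorded.
#' @return List of class \code{"run_manifest"} with the configuration
#'   snapshot, input digests, package version, timestamp and counts.
#' @export
run_manifest <- function(config, counts = list(), inputs = character()) {
  digests <- if (length(inputs)) tools::md5sum(inputs) else character()
  structure(list(
    version = as.character(utils::packageVersion("doseimpact")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = config[c("bandwidth", "range_T", "down_run_C", "up_run_B",
                          "end_factor_E", "hit_threshold",
                          "min_localization", "excluded_positions",
                          "biphasic_down_run", "end_rule", "hit_rule")],
    doses = config$design$doses,
    input_md5 = as.list(digests),
    counts = counts), class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Run manifest (doseimpact", x$version, "at", x$timestamp, ")\n")
  cat("  parameters:",
      paste(names(x$parameters),
            vapply(x$parameters, function(v) paste(format(v), collapse = ","), ""),
            sep = "=", collapse = ", "), "\n")
  flat <- unlist(x$counts)
  cat("  counts:", paste(names(flat), flat, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.phospho_result <- function(x, ...) {
  counts <- attr(x$calls, "counts")
  cat("Phospho-response analysis:", nrow(x$calls), "sites\n")
  print(counts)
  invisible(x)
}

#' @export
print.proteome_result <- function(x, ...) {
  cat("Proteome impact analysis:", nrow(x$impact), "proteins, ",
      sum(x$impact$is_hit), "hit(s)\n")
  invisible(x)
}
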