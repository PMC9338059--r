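#' Proteome impact map: per-protein average slopes at two temperatures
#'
#' Assembles one record per protein from its fitted curves: the mean (over
#' replicates) average slope of the constitutive-abundance curves at 37
#' degrees C and of the thermal-stability curves at 52 degrees C. A protein
#' is a hit when the slope on either axis exceeds the configured threshold
#' (in magnitude, under the default two-sided rule). A protein quantified at
#' only one temperature is kept, with the missing axis reported as NA and
#' the hit call made on the present axis.
#'
#' @param slopes Data frame with one row per protein x replicate x
#'   temperature and columns \code{protein_id}, \code{gene},
#'   \code{temperature}, \code{average_slope}, optionally \code{is_kinase}.
#'   Produced by \code{\link{analyze_proteome}} internally, or built by the
#'   caller from \code{\link{fit_dose_curve}} results.
#' @param config A \code{\link{run_config}} (uses \code{hit_threshold} and
#'   \code{hit_rule}).
#' @param temperatures The two temperature labels, default \code{c(37, 52)}.
#' @return Data frame with columns \code{protein_id}, \code{gene},
#'   \code{slope_37}, \code{slope_52}, \code{is_kinase}, \code{is_hit}.
#' @export
proteome_impact <- function(slopes, config, temperatures = c(37, 52)) {
  stopifnot(inherits(config, "run_config"))
  need <- c("protein_id", "temperature", "average_slope")
  missing_cols <- setdiff(need, names(slopes))
  if (length(missing_cols))
    stop("schema error: missing column(s): ", paste(missing_cols, collapse = ", "))
  ids <- sort(unique(slopes$protein_id))
  mean_slope_at <- function(temp) {
    sub <- slopes[slopes$temperature == temp, , drop = FALSE]
    m <- tapply(sub$average_slope, sub$protein_id, mean)
    as.numeric(m[ids])
  }
  s37 <- mean_slope_at(temperatures[1])
  s52 <- mean_slope_at(temperatures[2])
  first <- slopes[!duplicated(slopes$protein_id), , drop = FALSE]
  first <- first[match(ids, first$protein_id), , drop = FALSE]
  exceeds <- function(s) {
    v <- if (config$hit_rule == "absolute") abs(s) else s
    !is.na(s) & v > config$hit_threshold
  }
  data.frame(
    protein_id = ids,
    gene = if ("gene" %in% names(slopes)) first$gene else "",
    slope_37 = s37,
    slope_52 = s52,
    is_kinase = if ("is_kinase" %in% names(slopes)) first$is_kinase else FALSE,
    is_hit = exceeds(s37) | exceeds(s52),
    stringsAsFactors = FALSE)
}

#' Phospho-response table and category proportions
#'
#' One row per phosphosite with the per-replicate and final response
#' categories, the mean average slope, and the upward-interval metric; the
#' attribute \code{"proportions"} carries the global category proportions
#' (the pie-chart summary).
#'
#' @param calls Data frame of reconciled site calls, as produced by
#'   \code{\link{analyze_phospho}} (columns \code{entity_id},
#'   \code{final_category}, \code{mean_slope}, \code{upward_intervals},
#'   per-replicate slopes and categories).
#' @return The table, sorted by \code{entity_id}, with category counts and
#'   proportions attached as attributes \code{"counts"} and
#'   \code{"proportions"}.
#' @export
phospho_response <- function(calls) {
  cats <- response_categories()
  if (nrow(calls) && !all(calls$final_category %in% cats))
    stop("input error: unknown response category in calls")
  out <- calls[order(calls$entity_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  counts <- vapply(cats, function(k) sum(out$final_category == k), 1L)
  attr(out, "counts") <- counts
  attr(out, "proportions") <-
    if (nrow(out)) counts / nrow(out) else counts * NA_real_
  out
}

#' Per-protein heterogeneity of phosphosite responses
#'
#' Buckets proteins by the exact set of responsive (non-NR) categories
#' observed among their phosphosites, e.g. proteins carrying both
#' hyper- and hypo-phosphorylated sites.
#'
#' @param calls Site-call data frame with \code{protein_id} and
#'   \code{final_category} columns.
#' @return List with \code{per_protein} (named list: protein -> sorted
#'   category set) and \code{combination_counts} (table over the
#'   "+"-joined combination labels). Counts sum to the number of proteins
#'   with at least one responsive site.
#' @export
heterogeneity_summary <- function(calls) {
  resp <- calls[calls$final_category != "NR", , drop = FALSE]
  per_protein <- lapply(split(resp$final_category, resp$protein_id),
                        function(x) sort(unique(x)))
  labels <- vapply(per_protein, paste, "", collapse = "+")
  list(per_protein = per_protein,
       combination_counts = table(labels))
}

#' Hypergeometric gene-set over-representation test
#'
#' For each gene set, tests whether the hit list is enriched for set
#' members relative to the background of all identified proteins, using the
#' upper-tail hypergeometric probability
#' \deqn{p = \sum_{j \ge k} \binom{K}{j} \binom{N-K}{n-j} / \binom{N}{n}}
#' with N the background size, K the set size within the background, n the
#' hit-list size and k the observed overlap. Sets are intersected with the
#' background before testing. Significance is called at raw p < 0.05; a
#' Benjamini-Hochberg adjusted column is reported alongside but does not
#' drive the flag.
#'
#' @param hit_ids Character vector of hit identifiers (must all be in the
#'   background).
#' @param background_ids Character vector: all identified proteins.
#' @param gene_sets Named list of member vectors, from
#'   \code{\link{read_gene_sets}}.
#' @param alpha Significance threshold on the raw p-value, default 0.05.
#' @return Data frame with columns \code{set_name}, \code{overlap_k},
#'   \code{set_size_K}, \code{hits_n}, \code{background_N}, \code{p_value},
#'   \code{p_adjust}, \code{significant}.
#' @examples
#' hypergeom_enrichment(paste0("P", 1:4), paste0("P", 1:10),
#'                      list(set1 = paste0("P", 1:5)))
#' @export
hypergeom_enrichment <- function(hit_ids, background_ids, gene_sets,
                                 alpha = 0.05) {
  hit_ids <- unique(as.character(hit_ids))
  background_ids <- unique(as.character(background_ids))
  stray <- setdiff(hit_ids, background_ids)
  if (length(stray))
    stop("input error: hit identifier(s) not in background: ",
         paste(utils::head(stray, 5), collapse = ", "))
  if (!length(gene_sets))
    return(data.frame(set_name = character(), overlap_k = integer(),
                      set_size_K = integer(), hits_n = integer(),
                      background_N = integer(), p_value = numeric(),
                      p_adjust = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  N <- length(background_ids)
  n <- length(hit_ids)
  K <- vapply(gene_sets, function(s) length(intersect(s, background_ids)), 1L)
  k <- vapply(gene_sets, function(s) length(intersect(s, hit_ids)), 1L)
  # upper tail P(X >= k); phyper's tail excludes the bound, hence k - 1
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  data.frame(set_name = names(gene_sets),
             overlap_k = k, set_size_K = K, hits_n = n, background_N = N,
             p_value = p,
             p_adjust = stats::p.adjust(p, method = "BH"),
             significant = p < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}
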