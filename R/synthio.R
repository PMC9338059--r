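#' Specification for a synthetic dose-response dataset
#'
#' Describes a synthetic isothermal dose-response experiment with known
#' ground-truth response labels: a dose ladder, the number of phosphosites
#' per response pattern, shape parameters for each pattern, multiplicative
#' log-normal noise, and two biological replicates that share the pattern
#' but not the noise draws.
#'
#' Pattern shapes on ordinal positions x (before noise, scaled by
#' \code{base_intensity}):
#' \describe{
#'   \item{hyper}{sigmoid rise, \code{1 + A plogis((x - m)/s)}, default
#'     A = 0.6, m at the ladder midpoint, s = 1.}
#'   \item{hypo}{mirrored sigmoid fall, \code{1 + A (1 - plogis((x-m)/s))},
#'     default A = 1.}
#'   \item{biphasic}{Gaussian bell, \code{1 + A exp(-(x-m)^2 / 2 s^2)},
#'     default A = 0.8, s = 1.5, ends level.}
#'   \item{flat}{constant 1 (truth label \code{"NR"}).}
#' }
#' Amplitudes are chosen so that at zero noise the kernel-fitted ranges
#' clear the default responsiveness threshold T = 0.3 by at least 50
#' percent, while the flat pattern stays well under it.
#'
#' @param design A \code{\link{dose_design}}.
#' @param n_per_category Named integer vector: sites per pattern
#'   (\code{hyper}, \code{hypo}, \code{biphasic}, \code{flat}).
#' @param noise_sigma Standard deviation of the Gaussian noise applied on
#'   the log-intensity scale. Default 0.05.
#' @param replicates Number of biological replicates (fixed design: 2).
#' @param base_intensity Reporter-intensity scale of the vehicle dose.
#' @param amplitudes Named list overriding the per-pattern amplitudes.
#' @param seed Integer seed making the dataset reproducible.
#' @return Object of class \code{"synth_spec"}.
#' @export
synth_spec <- function(design = dose_design(),
                       n_per_category = c(hyper = 200L, hypo = 200L,
                                          biphasic = 200L, flat = 200L),
                       noise_sigma = 0.05,
                       replicates = 2L,
                       base_intensity = 1e6,
                       amplitudes = list(),
                       seed = 1L) {
  stopifnot(inherits(design, "dose_design"))
  if (noise_sigma < 0) stop("parameter error: noise_sigma must be >= 0")
  if (replicates != 2L)
    stop("config error: the replicate design is fixed at 2")
  patterns <- c("hyper", "hypo", "biphasic", "flat")
  n_per_category <- n_per_category[patterns]
  names(n_per_category) <- patterns
  n_per_category[is.na(n_per_category)] <- 0L
  amp <- utils::modifyList(
    list(hyper = 0.6, hypo = 1.0, biphasic = 0.8, flat = 0,
         stabilized = 6, destabilized = 6, abundance_up = 6),
    amplitudes)
  n_per_category <- stats::setNames(as.integer(n_per_category), patterns)
  structure(list(design = design,
                 n_per_category = n_per_category,
                 patterns = patterns,
                 noise_sigma = noise_sigma,
                 replicates = 2L,
                 base_intensity = base_intensity,
                 amplitudes = amp,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# Noise-free shape value at ordinal positions x.
pattern_shape <- function(pattern, x, amplitude, midpoint = NULL) {
  m <- midpoint %||% ((min(x) + max(x)) / 2)
  switch(pattern,
         hyper = ,
         stabilized = ,
         abundance_up = 1 + amplitude * stats::plogis(x - m),
         hypo = ,
         destabilized = 1 + amplitude * (1 - stats::plogis(x - m)),
         biphasic = 1 + amplitude * exp(-(x - m)^2 / (2 * 1.5^2)),
         flat = rep(1, length(x)),
         stop("unknown pattern: ", pattern))
}

# Truth label induced by a pattern under the default thresholds.
pattern_label <- function(pattern) {
  switch(pattern,
         hyper = "hyper", hypo = "hypo", biphasic = "biphasic",
         flat = "NR",
         stabilized = , destabilized = , abundance_up = pattern,
         stop("unknown pattern: ", pattern))
}

#' Generate one synthetic dose trace
#'
#' Unnormalized reporter intensities
#' \code{y_i = base * shape(x_i) * exp(eps_i)} with
#' \code{eps_i ~ Normal(0, noise_sigma^2)}; deterministic under a seed.
#'
#' @param pattern One of \code{"hyper"}, \code{"hypo"}, \code{"biphasic"},
#'   \code{"flat"} (phosphosites) or \code{"stabilized"},
#'   \code{"destabilized"}, \code{"abundance_up"} (proteins).
#' @param spec A \code{\link{synth_spec}}.
#' @param seed Optional seed set before drawing the noise.
#' @param entity_id,replicate_id,temperature Identifiers for the trace.
#' @return A \code{\link{dose_trace}} of unnormalized intensities.
#' @export
make_trace <- function(pattern, spec = synth_spec(), seed = NULL,
                       entity_id = NA_character_, replicate_id = 1L,
                       temperature = 37) {
  if (!is.null(seed)) set.seed(seed)
  x <- spec$design$positions
  shape <- pattern_shape(pattern, x, spec$amplitudes[[pattern]])
  eps <- stats::rnorm(length(x), 0, spec$noise_sigma)
  dose_trace(spec$base_intensity * shape * exp(eps), spec$design,
             entity_id = entity_id, replicate_id = replicate_id,
             temperature = temperature)
}

#' Generate a complete synthetic dataset on disk
#'
#' Writes three TSV files in the quantification-table dialect of
#' \code{\link{read_site_table}} / \code{\link{read_protein_table}}:
#' \describe{
#'   \item{site_table.tsv}{Phosphosites at 37 degrees C, two replicates,
#'     one row per site x replicate, with known response patterns.}
#'   \item{protein_table.tsv}{Proteins at 37 and 52 degrees C, two
#'     replicates: thermally stabilized, destabilized, abundance-responsive
#'     and flat proteins (a quarter of the flat site count each, minimum
#'     5).}
#'   \item{truth.tsv}{One row per entity: generating pattern and the truth
#'     label the pipeline should recover.}
#' }
#'
#' @param spec A \code{\link{synth_spec}}.
#' @param dir Output directory (created if needed).
#' @return Named list of the three file paths (class
#'   \code{"synth_dataset"}), with the spec attached as attribute.
#' @export
make_dataset <- function(spec = synth_spec(), dir = tempfile("synthdata")) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  design <- spec$design
  nchan <- length(design$channels)
  x <- design$positions

  site_ids <- sprintf("SYNP%04d", seq_len(sum(spec$n_per_category)))
  site_pattern <- rep(spec$patterns, spec$n_per_category)
  site_rows <- expand_entities(site_ids, site_pattern, spec,
                               temperatures = 37)
  site_df <- data.frame(
    Protein = site_rows$entity,
    check.names = FALSE, stringsAsFactors = FALSE)
  site_df[["Gene names"]] <- sub("^SYNP", "GENE", site_rows$entity)
  site_df[["Position"]] <- 100L
  site_df[["Amino acid"]] <- "S"
  site_df[["Localization prob"]] <- 1
  site_df[["Replicate"]] <- site_rows$replicate
  site_df[["Temperature"]] <- site_rows$temperature
  site_df[design$channels] <- as.data.frame(site_rows$intensities)

  n_prot <- max(5L, spec$n_per_category[["flat"]] %/% 4L)
  prot_patterns <- c("stabilized", "destabilized", "abundance_up", "flat")
  prot_ids <- sprintf("PROT%04d", seq_len(4L * n_prot))
  prot_pattern <- rep(prot_patterns, each = n_prot)
  prot_rows <- expand_entities(prot_ids, prot_pattern, spec,
                               temperatures = c(37, 52))
  prot_df <- data.frame(Protein = prot_rows$entity,
                        check.names = FALSE, stringsAsFactors = FALSE)
  prot_df[["Gene names"]] <- sub("^PROT", "PGENE", prot_rows$entity)
  prot_df[["Replicate"]] <- prot_rows$replicate
  prot_df[["Temperature"]] <- prot_rows$temperature
  prot_df[design$channels] <- as.data.frame(prot_rows$intensities)

  truth <- rbind(
    data.frame(entity_id = paste0(site_ids, "_S100"),
               protein_id = site_ids, kind = "site",
               pattern = site_pattern,
               label = vapply(site_pattern, pattern_label, ""),
               stringsAsFactors = FALSE),
    data.frame(entity_id = prot_ids, protein_id = prot_ids, kind = "protein",
               pattern = prot_pattern,
               label = vapply(prot_pattern, pattern_label, ""),
               stringsAsFactors = FALSE))

  paths <- list(site_table = file.path(dir, "site_table.tsv"),
                protein_table = file.path(dir, "protein_table.tsv"),
                truth = file.path(dir, "truth.tsv"))
  utils::write.table(site_df, paths$site_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(prot_df, paths$protein_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  structure(paths, spec = spec, class = "synth_dataset")
}

# One row per entity x replicate x temperature with noisy intensities.
# The 37-degree arm of thermal patterns is flat: stability changes show at
# the heat-challenge temperature only, abundance changes at 37 only.
expand_entities <- function(ids, patterns, spec, temperatures) {
  x <- spec$design$positions
  grid <- expand.grid(i = seq_along(ids),
                      replicate = seq_len(spec$replicates),
                      temperature = temperatures)
  eff_pattern <- patterns[grid$i]
  thermal <- eff_pattern %in% c("stabilized", "destabilized")
  eff_pattern[thermal & grid$temperature == 37] <- "flat"
  eff_pattern[eff_pattern == "abundance_up" & grid$temperature == 52] <- "flat"
  shapes <- t(vapply(eff_pattern,
                     function(p) pattern_shape(p, x, spec$amplitudes[[p]]),
                     numeric(length(x))))
  noise <- matrix(stats::rnorm(length(eff_pattern) * length(x),
                               0, spec$noise_sigma),
                  nrow = length(eff_pattern))
  list(entity = ids[grid$i],
       replicate = grid$replicate,
       temperature = grid$temperature,
       intensities = spec$base_intensity * shapes * exp(noise))
}
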