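#' Read a phosphosite quantification table
#'
#' Reads a MaxQuant-like tab-separated phosphosite table (one row per site,
#' reporter intensities in one column per dose channel) and validates it
#' against a dose design. Rows failing validation (non-numeric intensities,
#' localization probability outside [0, 1], missing site position or residue)
#' are counted and reported via a warning, never silently dropped; a negative
#' intensity is treated as a corrupt file and raises an error naming the row
#' and channel.
#'
#' @param path Path to a TSV file with a header row.
#' @param design A \code{\link{dose_design}}; its channel names must all be
#'   present in the header.
#' @param replicate,temperature Replicate id and temperature label for every
#'   row of the file. Ignored when the file carries its own
#'   \code{Replicate} / \code{Temperature} columns.
#' @param columns Named list of column names, see
#'   \code{\link{default_columns}} for the MaxQuant-like defaults.
#'
#' @return A data frame with columns \code{protein_id}, \code{gene},
#'   \code{site_position}, \code{residue}, \code{localization_prob},
#'   \code{replicate_id}, \code{temperature}, \code{entity_id}, followed by
#'   one intensity column per channel (\code{intensity_1..n}). The dose
#'   design is attached as attribute \code{"design"}.
#' @export
read_site_table <- function(path, design, replicate = NULL,
                            temperature = NULL,
                            columns = default_columns()) {
  stopifnot(inherits(design, "dose_design"))
  columns <- utils::modifyList(default_columns(), columns)
  raw <- read_quant_tsv(path)
  if (is.null(raw)) {
    warning("empty input file: ", path)
    return(empty_site_frame(design))
  }
  mandatory <- c(columns$protein, columns$position, columns$residue,
                 columns$localization)
  check_schema(raw, mandatory, design, path)
  n <- length(design$channels)
  intens <- intensity_matrix(raw, design, path)
  loc <- suppressWarnings(as.numeric(raw[[columns$localization]]))
  pos <- suppressWarnings(as.integer(raw[[columns$position]]))
  res <- as.character(raw[[columns$residue]])

  bad_loc <- is.na(loc) | loc < 0 | loc > 1
  bad_pos <- is.na(pos) | pos < 1L
  bad_res <- !(res %in% c("S", "T", "Y"))
  bad_int <- rowSums(is.na(intens)) > 0L
  malformed <- bad_loc | bad_pos | bad_res | bad_int
  if (any(malformed))
    warning(sum(malformed), " of ", nrow(raw), " row(s) in ", basename(path),
            " malformed and rejected (",
            sum(bad_loc), " localization, ", sum(bad_pos), " position, ",
            sum(bad_res), " residue, ", sum(bad_int), " intensity)")

  out <- data.frame(
    protein_id = as.character(raw[[columns$protein]]),
    gene = gene_column(raw, columns),
    site_position = pos,
    residue = res,
    localization_prob = loc,
    replicate_id = rep_column(raw, columns, replicate, path),
    temperature = temp_column(raw, columns, temperature, path),
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(intens))
  out <- out[!malformed, , drop = FALSE]
  rownames(out) <- NULL
  out$entity_id <- paste0(out$protein_id, "_", out$residue, out$site_position)
  out <- out[c(setdiff(names(out), paste0("intensity_", seq_len(n))),
               paste0("intensity_", seq_len(n)))]
  attr(out, "design") <- design
  attr(out, "n_rejected") <- sum(malformed)
  out
}

#' Read a protein quantification table
#'
#' As \code{\link{read_site_table}} but for protein-level (or peptide-level,
#' to be aggregated with \code{\link{aggregate_protein}}) rows without site
#' fields. An optional kinase list marks proteins as kinases.
#'
#' @inheritParams read_site_table
#' @param kinases Character vector of kinase accessions, e.g. from
#'   \code{\link{read_kinase_list}}; proteins in it get
#'   \code{is_kinase = TRUE}.
#' @return A data frame with columns \code{protein_id}, \code{gene},
#'   \code{is_kinase}, \code{replicate_id}, \code{temperature},
#'   \code{entity_id} and the intensity columns; design attached as
#'   attribute \code{"design"}.
#' @export
read_protein_table <- function(path, design, replicate = NULL,
                               temperature = NULL, kinases = character(),
                               columns = default_columns()) {
  stopifnot(inherits(design, "dose_design"))
  columns <- utils::modifyList(default_columns(), columns)
  raw <- read_quant_tsv(path)
  if (is.null(raw)) {
    warning("empty input file: ", path)
    return(empty_protein_frame(design))
  }
  check_schema(raw, columns$protein, design, path)
  n <- length(design$channels)
  intens <- intensity_matrix(raw, design, path)
  bad_int <- rowSums(is.na(intens)) > 0L
  if (any(bad_int))
    warning(sum(bad_int), " of ", nrow(raw), " row(s) in ", basename(path),
            " with non-numeric intensities rejected")
  out <- data.frame(
    protein_id = as.character(raw[[columns$protein]]),
    gene = gene_column(raw, columns),
    stringsAsFactors = FALSE)
  out$is_kinase <- out$protein_id %in% kinases
  out$replicate_id <- rep_column(raw, columns, replicate, path)
  out$temperature <- temp_column(raw, columns, temperature, path)
  out$entity_id <- out$protein_id
  out <- cbind(out, as.data.frame(intens))
  out <- out[!bad_int, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "design") <- design
  attr(out, "n_rejected") <- sum(bad_int)
  out
}

#' Read a gene-set file
#'
#' Two-column TSV without header: set name, member identifier. Duplicate
#' members within a set are removed.
#'
#' @param path Path to the gene-set file.
#' @return Named list mapping set name to a character vector of members.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("input error: gene-set file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(structure(list(), names = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(parts, length, 1L) < 2L))
    stop("input error: gene-set file must have two tab-separated columns")
  sets <- vapply(parts, `[`, "", 1L)
  members <- vapply(parts, `[`, "", 2L)
  lapply(split(members, sets), unique)
}

#' Read a kinase accession list (one accession per line)
#'
#' @param path Path to a plain-text file.
#' @return Character vector of accessions.
#' @export
read_kinase_list <- function(path) {
  if (!file.exists(path)) stop("input error: kinase list not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

#' Write a result table to TSV
#'
#' Writes impact, phospho-response or enrichment result tables with a fixed
#' column order and rows sorted by identifier, so that repeated runs on the
#' same input produce byte-identical files. Numeric fields survive a write /
#' re-read round trip to better than 6 significant digits.
#'
#' @param records Data frame as produced by \code{\link{proteome_impact}},
#'   \code{\link{phospho_response}} or \code{\link{hypergeom_enrichment}}.
#' @param path Output file path.
#' @param kind One of \code{"impact"}, \code{"phospho"},
#'   \code{"enrichment"}; selects the required column set and sort key.
#' @return Invisibly, the path written.
#' @export
write_results <- function(records, path,
                          kind = c("impact", "phospho", "enrichment")) {
  kind <- match.arg(kind)
  key <- switch(kind,
                impact = "protein_id",
                phospho = "entity_id",
                enrichment = "set_name")
  required <- switch(kind,
    impact = c("protein_id", "gene", "slope_37", "slope_52",
               "is_kinase", "is_hit"),
    phospho = c("entity_id", "protein_id", "gene", "site_position", "residue",
                "slope_rep1", "slope_rep2", "category_rep1", "category_rep2",
                "final_category", "mean_slope", "upward_intervals"),
    enrichment = c("set_name", "overlap_k", "set_size_K", "hits_n",
                   "background_N", "p_value", "p_adjust", "significant"))
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("schema error: missing column(s) for kind '", kind, "': ",
         paste(missing_cols, collapse = ", "))
  out <- records[required]
  if (nrow(out)) out <- out[order(out[[key]], method = "radix"), , drop = FALSE]
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("I/O error: cannot write ", path))
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read back a result table written by \code{\link{write_results}}
#'
#' @param path Path to the TSV.
#' @return Data frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

# --- internal helpers ------------------------------------------------------

read_quant_tsv <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first) || !nzchar(trimws(first))) return(NULL)
  raw <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!nrow(raw)) return(NULL)
  raw
}

check_schema <- function(raw, mandatory, design, path) {
  missing_cols <- setdiff(c(mandatory, design$channels), names(raw))
  missing_chan <- intersect(missing_cols, design$channels)
  if (length(missing_chan) && length(missing_chan) < length(design$channels))
    stop("design error: file ", basename(path), " has ",
         length(design$channels) - length(missing_chan),
         " of ", length(design$channels),
         " configured intensity channels (missing: ",
         paste(missing_chan, collapse = ", "), ")")
  if (length(missing_cols))
    stop("schema error: missing column(s) in ", basename(path), ": ",
         paste(missing_cols, collapse = ", "))
  invisible(TRUE)
}

intensity_matrix <- function(raw, design, path) {
  n <- length(design$channels)
  m <- matrix(NA_real_, nrow(raw), n,
              dimnames = list(NULL, paste0("intensity_", seq_len(n))))
  for (j in seq_len(n))
    m[, j] <- suppressWarnings(as.numeric(raw[[design$channels[j]]]))
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("validation error: negative intensity in ", basename(path),
         " at row ", neg[1, 1], ", channel '",
         design$channels[neg[1, 2]], "'")
  m
}

gene_column <- function(raw, columns) {
  if (columns$gene %in% names(raw)) as.character(raw[[columns$gene]])
  else rep("", nrow(raw))
}

rep_column <- function(raw, columns, replicate, path) {
  if (columns$replicate %in% names(raw))
    return(as.integer(raw[[columns$replicate]]))
  if (is.null(replicate))
    stop("input error: ", basename(path), " has no '", columns$replicate,
         "' column and no replicate id was given")
  rep(as.integer(replicate), nrow(raw))
}

temp_column <- function(raw, columns, temperature, path) {
  if (columns$temperature %in% names(raw))
    return(as.numeric(raw[[columns$temperature]]))
  if (is.null(temperature))
    stop("input error: ", basename(path), " has no '", columns$temperature,
         "' column and no temperature was given")
  rep(as.numeric(temperature), nrow(raw))
}

empty_site_frame <- function(design) {
  n <- length(design$channels)
  out <- data.frame(protein_id = character(), gene = character(),
                    site_position = integer(), residue = character(),
                    localization_prob = numeric(),
                    replicate_id = integer(), temperature = numeric(),
                    entity_id = character(), stringsAsFactors = FALSE)
  for (j in seq_len(n)) out[[paste0("intensity_", j)]] <- numeric()
  attr(out, "design") <- design
  attr(out, "n_rejected") <- 0L
  out
}

empty_protein_frame <- function(design) {
  n <- length(design$channels)
  out <- data.frame(protein_id = character(), gene = character(),
                    is_kinase = logical(), replicate_id = integer(),
                    temperature = numeric(), entity_id = character(),
                    stringsAsFactors = FALSE)
  for (j in seq_len(n)) out[[paste0("intensity_", j)]] <- numeric()
  attr(out, "design") <- design
  attr(out, "n_rejected") <- 0L
  out
}

intensity_cols <- function(df) grep("^intensity_[0-9]+$", names(df), value = TRUE)
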