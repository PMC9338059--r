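#' Dose design: the dose ladder and its ordinal positions
#'
#' An isothermal dose-response experiment measures abundance across a ladder
#' of drug concentrations, quantified in one reporter channel per dose. All
#' curve fitting in this package happens on the ordinal position of each dose
#' (1, 2, ..., n), not on the concentration itself, so that unevenly spaced
#' ladders still yield evenly weighted smoothing.
#'
#' @param doses Numeric vector of concentrations in micromolar, nondecreasing,
#'   with the vehicle (zero/untreated) dose first. The default is a 9-dose
#'   staurosporine ladder from 0 to 10 uM.
#' @param channels Character vector of reporter-intensity column names, one
#'   per dose, in dose order. Defaults to
#'   \code{"Reporter intensity corrected 1..n"} (MaxQuant-like).
#' @param reference_channel Optional name of a common reference channel
#'   (e.g. TMT 127N shared between plexes). It is read if present in input
#'   tables but never enters curve fitting.
#'
#' @return An object of class \code{"dose_design"} with elements
#'   \code{doses}, \code{positions} (1..n), \code{channels},
#'   \code{reference_channel}.
#' @examples
#' d <- dose_design()
#' d$positions
#' @export
dose_design <- function(doses = c(0, 0.0024, 0.0098, 0.0390, 0.1563,
                                  0.6250, 2.5, 5.0, 10.0),
                        channels = NULL,
                        reference_channel = NULL) {
  doses <- as.numeric(doses)
  n <- length(doses)
  if (n < 3L)
    stop("design error: a dose ladder needs at least 3 doses, got ", n)
  if (anyNA(doses) || any(doses < 0))
    stop("design error: doses must be nonnegative numbers")
  if (is.unsorted(doses))
    stop("design error: doses must be nondecreasing with the vehicle dose first")
  if (is.null(channels))
    channels <- paste("Reporter intensity corrected", seq_len(n))
  channels <- as.character(channels)
  if (length(channels) != n)
    stop("design error: need exactly one channel per dose (",
         n, " doses, ", length(channels), " channels)")
  if (anyDuplicated(channels))
    stop("design error: duplicated channel names")
  if (!is.null(reference_channel) && reference_channel %in% channels)
    stop("design error: the reference channel cannot also carry a dose")
  structure(list(doses = doses,
                 positions = seq_len(n),
                 channels = channels,
                 reference_channel = reference_channel),
            class = "dose_design")
}

#' @export
print.dose_design <- function(x, ...) {
  cat("Dose design:", length(x$doses), "doses\n")
  print(data.frame(position = x$positions, dose_uM = x$doses,
                   channel = x$channels), row.names = FALSE)
  if (!is.null(x$reference_channel))
    cat("Reference channel (excluded from fitting):", x$reference_channel, "\n")
  invisible(x)
}

default_columns <- function() {
  list(protein = "Protein",
       gene = "Gene names",
       position = "Position",
       residue = "Amino acid",
       localization = "Localization prob",
       replicate = "Replicate",
       temperature = "Temperature")
}

#' Run configuration for the dose-response workflow
#'
#' Bundles the dose design with every user-tunable parameter of the analysis:
#' the kernel bandwidth, the four classification thresholds, the hit
#' threshold for the protein impact map, and preprocessing options.
#'
#' The classification thresholds are, on first-dose-normalized fold changes:
#' \describe{
#'   \item{range_T}{A fitted curve whose range (max - min of fitted values)
#'     does not exceed \code{T} is non-responsive. Default 0.3.}
#'   \item{up_run_B}{Minimum number of consecutive strictly increasing
#'     adjacent fitted pairs for a hyper-phosphorylation call (and, by
#'     default, for each arm of a biphasic call). Default 3.}
#'   \item{down_run_C}{Minimum number of consecutive strictly decreasing
#'     adjacent fitted pairs for a hypo-phosphorylation call. Default 5.}
#'   \item{end_factor_E}{A biphasic curve must return near its start:
#'     |last - first| of the fitted curve must not exceed \code{E} times the
#'     fitted range. Default 0.45.}
#' }
#'
#' @param design A \code{\link{dose_design}}.
#' @param bandwidth Gaussian kernel bandwidth \code{b} on the
#'   ordinal-position scale; must be positive. Default 1.
#' @param range_T,down_run_C,up_run_B,end_factor_E Classification thresholds,
#'   see Details.
#' @param hit_threshold Proteins whose mean average slope at either
#'   temperature exceeds this in magnitude are flagged as hits. Default 0.5.
#' @param min_localization Phosphosites with localization probability below
#'   this fraction are filtered out. Default 0.5.
#' @param excluded_positions Integer vector of ordinal dose positions dropped
#'   from every trace before fitting (experiment-level outlier channels).
#' @param biphasic_down_run Which threshold the downward arm of a biphasic
#'   curve must meet: \code{"B"} (default) or \code{"C"}.
#' @param end_rule How the end-difference condition is scaled: against the
#'   fitted range (\code{"range"}, default) or against the threshold T
#'   (\code{"threshold"}).
#' @param hit_rule \code{"absolute"} (default) flags hits by |slope| >
#'   threshold on either temperature axis; \code{"positive"} uses the signed
#'   slope.
#' @param columns Named list of input column names (see
#'   \code{\link{read_site_table}}).
#'
#' @return An object of class \code{"run_config"}.
#' @examples
#' cfg <- run_config(bandwidth = 1, range_T = 0.3)
#' cfg$up_run_B
#' @export
run_config <- function(design = dose_design(),
                       bandwidth = 1,
                       range_T = 0.3,
                       down_run_C = 5L,
                       up_run_B = 3L,
                       end_factor_E = 0.45,
                       hit_threshold = 0.5,
                       min_localization = 0.5,
                       excluded_positions = integer(),
                       biphasic_down_run = c("B", "C"),
                       end_rule = c("range", "threshold"),
                       hit_rule = c("absolute", "positive"),
                       columns = default_columns()) {
  stopifnot(inherits(design, "dose_design"))
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0)
    stop("parameter error: bandwidth must be a single positive number")
  if (!is.numeric(range_T) || range_T <= 0)
    stop("parameter error: range_T must be positive")
  down_run_C <- as.integer(down_run_C)
  up_run_B <- as.integer(up_run_B)
  if (down_run_C < 1L || up_run_B < 1L)
    stop("parameter error: run-length thresholds B and C must be >= 1")
  if (end_factor_E < 0 || end_factor_E > 1)
    stop("parameter error: end_factor_E must lie in [0, 1]")
  if (hit_threshold <= 0)
    stop("parameter error: hit_threshold must be positive")
  if (min_localization < 0 || min_localization > 1)
    stop("parameter error: min_localization must lie in [0, 1]")
  excluded_positions <- sort(unique(as.integer(excluded_positions)))
  if (length(excluded_positions) &&
      (min(excluded_positions) < 1L ||
       max(excluded_positions) > length(design$doses)))
    stop("parameter error: excluded_positions outside 1..",
         length(design$doses))
  if (length(design$doses) - length(excluded_positions) < 3L)
    stop("parameter error: exclusion leaves fewer than 3 dose positions")
  structure(list(design = design,
                 bandwidth = bandwidth,
                 range_T = range_T,
                 down_run_C = down_run_C,
                 up_run_B = up_run_B,
                 end_factor_E = end_factor_E,
                 hit_threshold = hit_threshold,
                 min_localization = min_localization,
                 excluded_positions = excluded_positions,
                 biphasic_down_run = match.arg(biphasic_down_run),
                 end_rule = match.arg(end_rule),
                 hit_rule = match.arg(hit_rule),
                 columns = utils::modifyList(default_columns(), columns)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  cat(sprintf("  doses: %d (positions 1..%d), excluded: %s\n",
              length(x$design$doses), length(x$design$doses),
              if (length(x$excluded_positions))
                paste(x$excluded_positions, collapse = ",") else "none"))
  cat(sprintf("  bandwidth b = %g (ordinal units)\n", x$bandwidth))
  cat(sprintf("  thresholds: T = %g, B = %d, C = %d, E = %g\n",
              x$range_T, x$up_run_B, x$down_run_C, x$end_factor_E))
  cat(sprintf("  hit threshold = %g (%s), min localization = %g\n",
              x$hit_threshold, x$hit_rule, x$min_localization))
  invisible(x)
}

#' Read a run configuration from a flat key-value file
#'
#' The file holds one \code{key = value} (or \code{key: value}) pair per
#' line; \code{#} starts a comment. Recognised keys: \code{doses} (comma
#' separated), \code{bandwidth}, \code{T}, \code{C}, \code{B}, \code{E},
#' \code{hit_threshold}, \code{min_localization}, \code{excluded_positions}
#' (comma separated), \code{biphasic_down_run}, \code{end_rule},
#' \code{hit_rule}, and any input column name prefixed \code{column_}
#' (e.g. \code{column_protein}). Unrecognised keys raise an error.
#'
#' @param path Path to the configuration file.
#' @return A \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("input error: config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_ ]*?)\\s*[=:]\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, 1L) != 3L]
  if (length(bad))
    stop("config error: cannot parse line(s): ", paste(bad, collapse = "; "))
  keys <- trimws(vapply(kv, `[`, "", 2L))
  vals <- trimws(vapply(kv, `[`, "", 3L))
  get <- function(k) if (k %in% keys) vals[match(k, keys)] else NULL
  num <- function(k, default) {
    v <- get(k); if (is.null(v)) default else as.numeric(v)
  }
  numvec <- function(k, default) {
    v <- get(k)
    if (is.null(v)) default
    else as.numeric(strsplit(v, "[,;[:space:]]+")[[1]])
  }
  known <- c("doses", "bandwidth", "T", "C", "B", "E", "hit_threshold",
             "min_localization", "excluded_positions", "biphasic_down_run",
             "end_rule", "hit_rule", "reference_channel")
  colkeys <- keys[startsWith(keys, "column_")]
  unknown <- setdiff(keys, c(known, colkeys))
  if (length(unknown))
    stop("config error: unknown key(s): ", paste(unknown, collapse = ", "))
  columns <- default_columns()
  for (k in colkeys)
    columns[[sub("^column_", "", k)]] <- vals[match(k, keys)]
  design <- dose_design(doses = numvec("doses", dose_design()$doses),
                        reference_channel = get("reference_channel"))
  run_config(design = design,
             bandwidth = num("bandwidth", 1),
             range_T = num("T", 0.3),
             down_run_C = num("C", 5),
             up_run_B = num("B", 3),
             end_factor_E = num("E", 0.45),
             hit_threshold = num("hit_threshold", 0.5),
             min_localization = num("min_localization", 0.5),
             excluded_positions = numvec("excluded_positions", integer()),
             biphasic_down_run = get("biphasic_down_run") %||% "B",
             end_rule = get("end_rule") %||% "range",
             hit_rule = get("hit_rule") %||% "absolute",
             columns = columns)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
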