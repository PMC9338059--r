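#' Response categories
#'
#' The four phosphosite dose-response categories: hyper-phosphorylation
#' (monotone increase), hypo-phosphorylation (monotone decrease), biphasic
#' (rise then fall, or fall then rise, returning near the start) and
#' non-responsive.
#' @export
response_categories <- function() c("hyper", "hypo", "biphasic", "NR")

#' Classify a fitted dose-response curve
#'
#' Decision procedure, applied in order to the fitted-curve statistics:
#' \enumerate{
#'   \item fitted range <= T: non-responsive (\code{"NR"});
#'   \item longest upward and downward runs both meet the biphasic run
#'     requirement and the end difference is within E times the fitted
#'     range: \code{"biphasic"};
#'   \item positive average slope and upward run >= B: \code{"hyper"};
#'   \item negative average slope and downward run >= C: \code{"hypo"};
#'   \item otherwise \code{"NR"}.
#' }
#' Biphasic is tested before hyper/hypo so that a bell-shaped curve with a
#' small net slope is not absorbed into a monotone class. The biphasic run
#' requirement uses B for both directions by default
#' (\code{config$biphasic_down_run = "C"} switches the downward arm to C),
#' and the end-difference condition scales with the fitted range by default
#' (\code{config$end_rule = "threshold"} scales with T instead).
#'
#' @param curve A \code{"dose_curve"} from \code{\link{fit_dose_curve}}.
#' @param config A \code{\link{run_config}} with thresholds T, B, C, E.
#' @return One of \code{"hyper"}, \code{"hypo"}, \code{"biphasic"},
#'   \code{"NR"}.
#' @export
classify_curve <- function(curve, config) {
  stopifnot(inherits(curve, "dose_curve"), inherits(config, "run_config"))
  classify_stats(curve$range_fitted, curve$average_slope,
                 curve$max_up_run, curve$max_down_run,
                 curve$end_diff, config)
}

# Vectorized core of the decision procedure.
classify_stats <- function(range_fitted, slope, up_run, down_run,
                           end_diff, config) {
  bip_down <- if (config$biphasic_down_run == "C") config$down_run_C
              else config$up_run_B
  end_limit <- if (config$end_rule == "threshold")
    rep(config$end_factor_E * config$range_T, length(range_fitted))
  else config$end_factor_E * range_fitted
  out <- rep("NR", length(range_fitted))
  responsive <- range_fitted > config$range_T
  bi <- responsive & up_run >= config$up_run_B & down_run >= bip_down &
    end_diff <= end_limit
  hyper <- responsive & !bi & slope > 0 & up_run >= config$up_run_B
  hypo <- responsive & !bi & !hyper & slope < 0 & down_run >= config$down_run_C
  out[bi] <- "biphasic"
  out[hyper] <- "hyper"
  out[hypo] <- "hypo"
  out
}

#' Reconcile the two replicate calls for one entity
#'
#' Each replicate is fitted and categorized on its own; an entity receives
#' a responsive final category only when both replicates agree on it. The
#' entity's summary slope is always the arithmetic mean of the two
#' replicates' average slopes, whatever the final category.
#'
#' @param call1,call2 Lists (or one-row data frames) with elements
#'   \code{entity_id}, \code{category}, \code{average_slope} for replicate
#'   1 and 2.
#' @return List with \code{entity_id}, \code{final_category},
#'   \code{mean_average_slope}, and the per-replicate inputs.
#' @export
reconcile_replicates <- function(call1, call2) {
  if (!identical(as.character(call1$entity_id), as.character(call2$entity_id)))
    stop("pairing error: replicate calls for different entities ('",
         call1$entity_id, "' vs '", call2$entity_id, "')")
  final <- reconcile_categories(call1$category, call2$category)
  list(entity_id = call1$entity_id,
       final_category = final,
       mean_average_slope = (call1$average_slope + call2$average_slope) / 2,
       replicate1 = call1, replicate2 = call2)
}

reconcile_categories <- function(cat1, cat2) {
  ifelse(cat1 == cat2 & cat1 != "NR", cat1, "NR")
}

#' Upward-interval metric for the phospho-response map
#'
#' The x-axis of the phospho-response scatter: the longest run of strictly
#' increasing adjacent points of the element-wise mean of the two
#' replicates' fitted curves.
#'
#' @param fitted1,fitted2 Fitted-value vectors of the two replicates (same
#'   positions).
#' @return Integer run length.
#' @export
upward_interval_metric <- function(fitted1, fitted2) {
  if (length(fitted1) != length(fitted2))
    stop("pairing error: replicate fitted curves differ in length")
  run_statistics((fitted1 + fitted2) / 2)[["max_up_run"]]
}
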