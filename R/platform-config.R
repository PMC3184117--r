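#' Platform detection configuration
#'
#' Bundles the per-platform detection settings: the Ct detection
#' threshold (signals with Ct above it are treated as undetected), the
#' run length in cycles, and the replicate detection rule. Two rules
#' are used at different points of the evaluation: `any_replicate`
#' (an assay is called detected if at least one replicate has a
#' numeric Ct at or below the threshold; used for false-positive
#' counting) and `all_replicates` (every replicate must be at or below
#' threshold; used for "n detected" summaries and for inclusion in the
#' recovery analysis, which drops an assay if any of its measurements
#' fails the threshold).
#'
#' @param detection_threshold_ct positive Ct threshold; detection is
#'   inclusive (`Ct <= threshold`).
#' @param max_cycles run length, default 40.
#' @param detection_rule `"any_replicate"` or `"all_replicates"`.
#' @return a `platform_config` list.
#' @export
platform_config <- function(detection_threshold_ct, max_cycles = 40,
                            detection_rule = c("any_replicate",
                                               "all_replicates")) {
  detection_rule <- match.arg(detection_rule)
  if (!is.numeric(detection_threshold_ct) || detection_threshold_ct <= 0) {
    sv_stop("detection_threshold_ct must be positive")
  }
  if (detection_threshold_ct > max_cycles) {
    sv_stop("detection_threshold_ct must not exceed max_cycles")
  }
  structure(list(detection_threshold_ct = detection_threshold_ct,
                 max_cycles = max_cycles,
                 detection_rule = detection_rule),
            class = "platform_config")
}
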