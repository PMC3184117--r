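# Specificity analysis: false-positive-rate curves over Ct detection
# thresholds, no-RT-based threshold selection, attribution of false
# positives to sequence homology, and the mismatch-stratified
# cross-reaction table.

# internal: per-assay replicate summary for one sample
assay_replicate_stats <- function(ct, sample_id) {
  sub <- ct[ct$sample_id == sample_id, , drop = FALSE]
  if (!nrow(sub)) sv_stop("unknown sample: ", sample_id)
  sp <- split(sub$ct, sub$assay_id)
  data.frame(
    assay_id = names(sp),
    n_replicates = lengths(sp),
    n_undetected = vapply(sp, function(v) sum(is.na(v)), 0L),
    min_ct = vapply(sp, function(v) {
      if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
    }, 0),
    max_ct = vapply(sp, function(v) {
      if (anyNA(v)) NA_real_ else max(v)
    }, 0),
    stringsAsFactors = FALSE, row.names = NULL)
}

# internal: detected flags at a threshold under a replicate rule;
# under all_replicates, max_ct is NA when any replicate is undetected
detected_at <- function(stats, threshold, rule) {
  if (rule == "any_replicate") {
    !is.na(stats$min_ct) & stats$min_ct <= threshold
  } else {
    !is.na(stats$max_ct) & stats$max_ct <= threshold
  }
}

#' Per-assay detection calls for one sample
#'
#' Applies the platform detection rule at the configured threshold.
#' Under `any_replicate` an assay is detected if at least one replicate
#' has a numeric Ct at or below the threshold; under `all_replicates`
#' every replicate must. The representative Ct reported is the smallest
#' numeric replicate Ct (NA if all replicates are undetected).
#'
#' @param ct a [ct_table()].
#' @param sample_id sample to call.
#' @param config a [platform_config()].
#' @return data.frame with columns `sample_id`, `assay_id`, `detected`,
#'   `representative_ct`.
#' @export
detect_calls <- function(ct, sample_id, config) {
  stats <- assay_replicate_stats(ct, sample_id)
  data.frame(sample_id = sample_id, assay_id = stats$assay_id,
             detected = detected_at(stats, config$detection_threshold_ct,
                                    config$detection_rule),
             representative_ct = stats$min_ct,
             stringsAsFactors = FALSE)
}

#' False-positive-rate curve over Ct detection thresholds
#'
#' For a sample of known content, an assay is a potential false
#' positive when its designed target miRNA is absent from the sample.
#' At each threshold the curve counts how many of those assays
#' nevertheless produced a signal (false positives), how many did not
#' (true negatives), the false positive rate FP / (FP + TN) (which
#' equals 1 - specificity), and how many false positives have sequence
#' homology to at least one miRNA that is present (homology-related
#' false positives), together with a one-sided enrichment p-value
#' against the expected homology fraction.
#'
#' @param ct a [ct_table()].
#' @param sample_id sample of known content.
#' @param design a [spike_design()] defining which miRNAs are present.
#' @param catalog an [assay_catalog()]; assays present in `ct` but
#'   missing from the catalog are excluded with a warning.
#' @param thresholds ascending numeric vector of Ct thresholds.
#' @param homology a [build_homology_map()] for `catalog`.
#' @param detection_rule replicate rule for false-positive counting;
#'   default `"any_replicate"` (a single offending replicate already
#'   constitutes a spurious signal).
#' @param enrichment_mode `"poisson"` (default) or `"binomial"`.
#' @return a `specificity_curve` data.frame (one row per threshold)
#'   with attribute `expected_fraction`.
#' @export
fp_rate_curve <- function(ct, sample_id, design, catalog, thresholds,
                          homology,
                          detection_rule = "any_replicate",
                          enrichment_mode = "poisson") {
  if (is.unsorted(thresholds)) sv_stop("thresholds must be ascending")
  stats <- assay_replicate_stats(ct, sample_id)
  unknown <- setdiff(stats$assay_id, catalog$assay_id)
  if (length(unknown)) {
    sv_warn(length(unknown), " assay(s) in the Ct table are absent from ",
            "the catalog and were excluded (e.g. ", unknown[1L], ")")
    stats <- stats[!(stats$assay_id %in% unknown), , drop = FALSE]
  }
  target <- catalog$target_mirna_id[match(stats$assay_id,
                                          catalog$assay_id)]
  present <- present_mirnas(design, sample_id)
  absent <- is.na(target) | !(target %in% present)
  stats <- stats[absent, , drop = FALSE]

  rel <- homology[homology$mirna_id %in% present, , drop = FALSE]
  has_hom <- stats$assay_id %in% unique(rel$assay_id)
  exp_frac <- mean(has_hom)

  rows <- lapply(thresholds, function(th) {
    det <- detected_at(stats, th, detection_rule)
    n_fp <- sum(det)
    n_hom <- sum(det & has_hom)
    p <- if (n_fp == 0L || exp_frac <= 0 || exp_frac >= 1) {
      NA_real_
    } else {
      enrichment_test(n_hom, n_fp, exp_frac, mode = enrichment_mode,
                      quiet = TRUE)
    }
    data.frame(threshold = th, n_false_positive = n_fp,
               n_true_negative = nrow(stats) - n_fp,
               fp_rate = if (nrow(stats)) n_fp / nrow(stats) else NA_real_,
               n_homology_related = n_hom, p_enrichment = p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, expected_fraction = exp_frac, sample_id = sample_id,
            class = c("specificity_curve", "data.frame"))
}

#' Suggest a Ct detection threshold from no-RT controls
#'
#' Signals in a no-reverse-transcription control are template
#' independent; a detection threshold placed at (the floor of) a low
#' quantile of the numeric no-RT Ct values excludes almost all such
#' artifact signals. When the no-RT control produced no numeric signal
#' at all, the run length (`max_cycles`) is returned, i.e. no
#' threshold tighter than the run itself is needed.
#'
#' @param no_rt a [ct_table()] holding the no-RT control measurements.
#' @param quantile quantile of the numeric no-RT Cts, in (0, 1].
#' @param config a [platform_config()].
#' @return suggested integer-valued threshold (floor of the quantile).
#' @export
suggest_threshold <- function(no_rt, quantile = 0.01, config) {
  if (quantile <= 0 || quantile > 1) sv_stop("quantile must be in (0, 1]")
  cts <- no_rt$ct[!is.na(no_rt$ct)]
  if (!length(cts)) return(config$max_cycles)
  floor(stats::quantile(cts, quantile, type = 7, names = FALSE))
}

#' Enrichment test for homology-related false positives
#'
#' One-sided upper-tail probability of observing at least
#' `n_homology_fp` homology-related false positives among `n_fp` false
#' positives when each false positive is homology-related with the
#' expected fraction. Mode `"poisson"` (a Poisson randomness test with
#' `lambda = n_fp * expected_fraction`) is the default; mode
#' `"binomial"` uses the exact Binomial(`n_fp`, `expected_fraction`)
#' tail.
#'
#' @param n_homology_fp,n_fp observed counts,
#'   `0 <= n_homology_fp <= n_fp`.
#' @param expected_fraction expected homology fraction in (0, 1).
#' @param mode `"poisson"` or `"binomial"`.
#' @param quiet suppress the undefined-case warning.
#' @return p-value; 1.0 (with a warning) when `n_fp` is 0.
#' @export
enrichment_test <- function(n_homology_fp, n_fp, expected_fraction,
                            mode = c("poisson", "binomial"),
                            quiet = FALSE) {
  mode <- match.arg(mode)
  if (n_homology_fp < 0 || n_homology_fp > n_fp) {
    sv_stop("need 0 <= n_homology_fp <= n_fp")
  }
  if (expected_fraction <= 0 || expected_fraction >= 1) {
    sv_stop("expected_fraction must be in (0, 1)")
  }
  if (n_fp == 0L) {
    if (!quiet) sv_warn("no false positives; enrichment undefined, p = 1")
    return(1)
  }
  if (mode == "poisson") {
    count_tail(n_homology_fp, lambda = n_fp * expected_fraction,
               mode = "poisson")
  } else {
    count_tail(n_homology_fp, n = n_fp, p = expected_fraction,
               mode = "binomial")
  }
}

#' Mismatch-stratified false-positive table
#'
#' Restricts to assays whose target is absent from the sample but which
#' have at least one homolog among the present miRNAs, stratifies them
#' by the minimum mismatch count to any present miRNA (each assay
#' appears in exactly one stratum), and reports per stratum the number
#' of assays, the number detected at the platform threshold (false
#' positives) and the false positive rate as a percentage rounded to
#' the nearest integer.
#'
#' @param ct a [ct_table()].
#' @param sample_id sample of known content.
#' @param design a [spike_design()].
#' @param catalog an [assay_catalog()].
#' @param homology a [build_homology_map()].
#' @param config a [platform_config()]; its threshold and replicate
#'   rule define the false-positive call.
#' @return a `mismatch_table` data.frame with columns `mismatches`,
#'   `n_assays`, `n_false_positive`, `fp_rate_pct`.
#' @export
mismatch_stratified_fp <- function(ct, sample_id, design, catalog,
                                   homology, config) {
  stats <- assay_replicate_stats(ct, sample_id)
  stats <- stats[stats$assay_id %in% catalog$assay_id, , drop = FALSE]
  target <- catalog$target_mirna_id[match(stats$assay_id,
                                          catalog$assay_id)]
  present <- present_mirnas(design, sample_id)
  stats <- stats[is.na(target) | !(target %in% present), , drop = FALSE]

  rel <- homology[homology$mirna_id %in% present, , drop = FALSE]
  min_mm <- tapply(rel$mismatches, rel$assay_id, min)
  stats$min_mm <- as.integer(min_mm[stats$assay_id])
  stats <- stats[!is.na(stats$min_mm), , drop = FALSE]
  stats$fp <- detected_at(stats, config$detection_threshold_ct,
                          config$detection_rule)

  levels_present <- sort(unique(stats$min_mm))
  if (!length(levels_present)) {
    out <- data.frame(mismatches = integer(0), n_assays = integer(0),
                      n_false_positive = integer(0),
                      fp_rate_pct = numeric(0))
    return(structure(out, sample_id = sample_id,
                     class = c("mismatch_table", "data.frame")))
  }
  rows <- lapply(levels_present, function(m) {
    grp <- stats[stats$min_mm == m, , drop = FALSE]
    data.frame(mismatches = m, n_assays = nrow(grp),
               n_false_positive = sum(grp$fp),
               fp_rate_pct = round(100 * sum(grp$fp) / nrow(grp)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, sample_id = sample_id,
            class = c("mismatch_table", "data.frame"))
}
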