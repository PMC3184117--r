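# Recovery analysis: per-assay delta-Ct between two samples versus the
# fold change implied by the spike design, per-direction summaries and
# cross-platform comparisons.

#' Per-assay delta-Ct between two samples
#'
#' The delta-Ct for an assay is the mean Ct of the second sample's
#' replicates minus the mean Ct of the first sample's replicates, so a
#' template four-fold more abundant in the first sample yields +2. An
#' assay is excluded (delta `NA`, with a reason) if any of its
#' measurements in either sample is undetected or detected after the
#' detection threshold, or if the assay is missing from a sample
#' entirely.
#'
#' @param ct a [ct_table()].
#' @param sample_a,sample_b sample ids (first and second sample).
#' @param assays assay ids to evaluate; default: all assays observed in
#'   both samples.
#' @param config a [platform_config()]; its threshold defines the
#'   exclusion rule.
#' @return data.frame with columns `assay_id`, `delta_ct`, `included`,
#'   `reason`.
#' @export
delta_ct_per_assay <- function(ct, sample_a, sample_b, assays = NULL,
                               config) {
  sub_a <- ct[ct$sample_id == sample_a, , drop = FALSE]
  sub_b <- ct[ct$sample_id == sample_b, , drop = FALSE]
  if (!nrow(sub_a)) sv_stop("unknown sample: ", sample_a)
  if (!nrow(sub_b)) sv_stop("unknown sample: ", sample_b)
  if (is.null(assays)) {
    assays <- sort(intersect(unique(sub_a$assay_id),
                             unique(sub_b$assay_id)))
  }
  th <- config$detection_threshold_ct
  one <- function(assay) {
    va <- sub_a$ct[sub_a$assay_id == assay]
    vb <- sub_b$ct[sub_b$assay_id == assay]
    if (!length(va) || !length(vb)) {
      return(list(NA_real_, "missing_from_sample"))
    }
    if (anyNA(c(va, vb))) return(list(NA_real_, "undetected_replicate"))
    if (any(c(va, vb) > th)) return(list(NA_real_, "beyond_threshold"))
    list(mean(vb) - mean(va), "")
  }
  res <- lapply(assays, one)
  data.frame(assay_id = assays,
             delta_ct = vapply(res, function(r) r[[1L]], 0),
             included = vapply(res, function(r) r[[2L]] == "", TRUE),
             reason = vapply(res, function(r) r[[2L]], ""),
             stringsAsFactors = FALSE)
}

#' Summarize recovered delta-Ct values by expected-direction group
#'
#' Groups the per-assay delta-Ct values by their expected delta-Ct
#' (typically +2 and -2 for a reciprocal four-fold design) and reports
#' per group the number of included assays, the median, the
#' interquartile range (linear-interpolation quartiles, quantile type
#' 7) and the sample variance (n - 1 denominator).
#'
#' @param deltas a [delta_ct_per_assay()] result.
#' @param expected named numeric vector: expected delta-Ct per assay id.
#' @param quantile_type quartile convention passed to
#'   [stats::quantile()] (default 7).
#' @return a `recovery_summary` data.frame, one row per expected value.
#' @export
recovery_summary <- function(deltas, expected, quantile_type = 7) {
  exp_vals <- expected[deltas$assay_id]
  if (anyNA(exp_vals)) {
    sv_stop("expected delta-Ct missing for ",
            deltas$assay_id[which(is.na(exp_vals))[1L]])
  }
  groups <- sort(unique(exp_vals))
  rows <- lapply(groups, function(g) {
    d <- deltas$delta_ct[deltas$included & exp_vals == g]
    if (!length(d)) {
      return(data.frame(expected = g, n_included = 0L, median = NA_real_,
                        iqt = NA_real_, variance = NA_real_,
                        degenerate = TRUE))
    }
    q <- stats::quantile(d, c(0.25, 0.75), type = quantile_type,
                         names = FALSE)
    data.frame(expected = g, n_included = length(d), median = median(d),
               iqt = q[2L] - q[1L],
               variance = if (length(d) > 1L) var(d) else NA_real_,
               degenerate = length(d) < 2L)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("recovery_summary", "data.frame"))
}

#' Compare fold-change recovery between two platforms
#'
#' Restricts both platforms to the assays included on both, then per
#' expected-direction group compares the delta-Ct distributions
#' (two-sided Mann-Whitney U), compares the overall accuracy through
#' the variance of the residuals observed - expected (two-sided
#' variance-ratio F test), and correlates the per-assay residuals of
#' the two platforms (Pearson) to ask whether the poorly recovered
#' assays are the same on both.
#'
#' @param deltas_1,deltas_2 [delta_ct_per_assay()] results for the two
#'   platforms, over a shared assay id universe.
#' @param expected named numeric vector of expected delta-Ct per assay.
#' @param min_common minimum number of assays included on both
#'   platforms; below it the comparison is refused (default 3).
#' @return a `recovery_comparison` list: `p_median` (named by group),
#'   `p_variance`, `discordance_r`, `n_common`.
#' @export
compare_recovery <- function(deltas_1, deltas_2, expected,
                             min_common = 3L) {
  common <- intersect(deltas_1$assay_id[deltas_1$included],
                      deltas_2$assay_id[deltas_2$included])
  if (length(common) < min_common) {
    sv_stop("comparison refused: only ", length(common),
            " assays included on both platforms",
            class = "spikeval_refused")
  }
  d1 <- setNames(deltas_1$delta_ct, deltas_1$assay_id)[common]
  d2 <- setNames(deltas_2$delta_ct, deltas_2$assay_id)[common]
  exp_c <- expected[common]
  if (anyNA(exp_c)) sv_stop("expected delta-Ct missing for a common assay")

  groups <- sort(unique(exp_c))
  p_median <- vapply(groups, function(g) {
    mann_whitney_u(d1[exp_c == g], d2[exp_c == g])$p_value
  }, 0)
  names(p_median) <- paste0("expected_", groups)

  r1 <- d1 - exp_c
  r2 <- d2 - exp_c
  # residuals can be exactly constant in degenerate (noise-free) data
  p_var <- tryCatch(variance_ratio_test(r1, r2)$p_value,
                    spikeval_zero_variance = function(e) NA_real_)
  disc <- tryCatch(pearson_r(r1, r2),
                   spikeval_zero_variance = function(e) NA_real_)
  structure(list(p_median = p_median, p_variance = p_var,
                 discordance_r = disc, n_common = length(common)),
            class = "recovery_comparison")
}
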