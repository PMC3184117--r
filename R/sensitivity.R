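# Reproducibility, dilution-series sensitivity and per-assay linearity.

#' Pearson correlation of duplicate measurements for one sample
#'
#' Restricts to assays detected under the `all_replicates` rule (both
#' duplicates at or below the threshold) and, optionally, to an assay
#' subset, then correlates the two replicate Ct vectors.
#'
#' @param ct a [ct_table()] with exactly two replicates for the sample.
#' @param sample_id sample id.
#' @param config a [platform_config()].
#' @param restrict_assays optional assay id subset.
#' @param exclude_assays optional assay ids to drop before the
#'   correlation (explicit outlier-well exclusion list; never a
#'   heuristic).
#' @return list with `r` (NA when fewer than 3 assays are detected),
#'   `n_detected`, and `flagged` (TRUE when r is undefined).
#' @export
replicate_correlation <- function(ct, sample_id, config,
                                  restrict_assays = NULL,
                                  exclude_assays = NULL) {
  sub <- ct[ct$sample_id == sample_id, , drop = FALSE]
  if (!nrow(sub)) sv_stop("unknown sample: ", sample_id)
  reps <- sort(unique(sub$replicate_id))
  if (length(reps) != 2L) {
    sv_stop("replicate correlation needs exactly two replicates; found ",
            length(reps))
  }
  if (!is.null(restrict_assays)) {
    sub <- sub[sub$assay_id %in% restrict_assays, , drop = FALSE]
  }
  if (!is.null(exclude_assays)) {
    sub <- sub[!(sub$assay_id %in% exclude_assays), , drop = FALSE]
  }
  a <- sub[sub$replicate_id == reps[1L], , drop = FALSE]
  b <- sub[sub$replicate_id == reps[2L], , drop = FALSE]
  common <- intersect(a$assay_id, b$assay_id)
  x <- setNames(a$ct, a$assay_id)[common]
  y <- setNames(b$ct, b$assay_id)[common]
  th <- config$detection_threshold_ct
  keep <- !is.na(x) & !is.na(y) & x <= th & y <= th
  n <- sum(keep)
  if (n < 3L) {
    return(list(r = NA_real_, n_detected = n, flagged = TRUE))
  }
  r <- tryCatch(pearson_r(x[keep], y[keep]),
                spikeval_zero_variance = function(e) NA_real_)
  list(r = r, n_detected = n, flagged = is.na(r))
}

#' Construct a dilution series
#'
#' Binds a Ct table whose samples are the dilution points to the known
#' template input at each point. Copies must decrease by the stated
#' dilution factor from point to point.
#'
#' @param ct a [ct_table()]; its `sample_id` values are point ids.
#' @param points data.frame with columns `point_id` and
#'   `copies_per_pcr` (input copies per PCR at that point, for the
#'   reference pool; only relative spacing enters the analysis).
#' @param dilution_factor expected step factor between consecutive
#'   points (default 10).
#' @return a `dilution_series` list.
#' @export
dilution_series <- function(ct, points, dilution_factor = 10) {
  need <- c("point_id", "copies_per_pcr")
  miss <- setdiff(need, names(points))
  if (length(miss)) sv_stop("points missing column(s): ",
                            paste(miss, collapse = ", "))
  points <- points[order(-points$copies_per_pcr), , drop = FALSE]
  ratio <- points$copies_per_pcr[-nrow(points)] /
    points$copies_per_pcr[-1L]
  if (any(abs(ratio - dilution_factor) > 1e-6 * dilution_factor)) {
    sv_stop("copies_per_pcr must decrease by the dilution factor (",
            dilution_factor, ") between consecutive points")
  }
  missing_pts <- setdiff(points$point_id, unique(ct$sample_id))
  if (length(missing_pts)) {
    sv_stop("no measurements for dilution point ", missing_pts[1L])
  }
  rownames(points) <- NULL
  structure(list(ct = ct, points = points,
                 dilution_factor = dilution_factor),
            class = "dilution_series")
}

#' Read a dilution series from TSV
#'
#' The series TSV follows the Ct-table schema plus the columns
#' `point_id` and `copies_per_pcr` (repeated on every row of a point).
#'
#' @param path file path.
#' @param max_cycles passed to the Ct validation.
#' @param dilution_factor expected step factor (default 10).
#' @return a [dilution_series()].
#' @export
read_dilution_series <- function(path, max_cycles = 40,
                                 dilution_factor = 10) {
  df <- read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("point_id", "copies_per_pcr", "replicate_id", "assay_id", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    sv_stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  }
  raw <- trimws(df$ct)
  undet <- raw %in% c("Undetermined", "NA", "")
  ctv <- suppressWarnings(as.numeric(raw))
  if (any(!undet & is.na(ctv))) sv_stop("unparseable ct value in ", path)
  ctv[undet] <- NA_real_
  ct <- ct_table(df$point_id, df$replicate_id, df$assay_id, ctv,
                 max_cycles = max_cycles)
  pts <- unique(data.frame(point_id = df$point_id,
                           copies_per_pcr = as.numeric(df$copies_per_pcr),
                           stringsAsFactors = FALSE))
  dilution_series(ct, pts, dilution_factor = dilution_factor)
}

#' Detection counts and duplicate correlation along a dilution series
#'
#' Per dilution point: the number of assays detected in both
#' replicates (`all_replicates` rule) and the Pearson correlation of
#' the duplicate Ct vectors over the detected assays.
#'
#' @param series a [dilution_series()].
#' @param config a [platform_config()].
#' @param restrict_assays optional assay id subset.
#' @param exclude_assays optional named list: point id -> assay ids to
#'   exclude at that point (explicit outlier-well exclusions).
#' @return data.frame with one row per point: `point_id`,
#'   `copies_per_pcr`, `n_detected`, `r`.
#' @export
dilution_detection <- function(series, config, restrict_assays = NULL,
                               exclude_assays = NULL) {
  rows <- lapply(seq_len(nrow(series$points)), function(i) {
    pid <- series$points$point_id[i]
    rc <- replicate_correlation(series$ct, pid, config,
                                restrict_assays = restrict_assays,
                                exclude_assays = exclude_assays[[pid]])
    data.frame(point_id = pid,
               copies_per_pcr = series$points$copies_per_pcr[i],
               n_detected = rc$n_detected, r = rc$r,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare detection counts between two platforms
#'
#' Two-sided Fisher's exact test on the 2x2 table of detected versus
#' not-detected assays out of a common total.
#'
#' @param n_detected_1,n_detected_2 detected counts.
#' @param n_total common number of assays interrogated.
#' @return the two-sided p-value.
#' @export
detection_comparison <- function(n_detected_1, n_detected_2, n_total) {
  if (n_detected_1 > n_total || n_detected_2 > n_total ||
      n_detected_1 < 0 || n_detected_2 < 0) {
    sv_stop("detected counts must lie in [0, n_total]")
  }
  fisher_exact_2x2(n_detected_1, n_total - n_detected_1,
                   n_detected_2, n_total - n_detected_2)$p_value
}

#' Per-assay linearity across a dilution series
#'
#' For each assay, regresses Ct against log10 input copies across the
#' retained dilution points, using every replicate measurement as its
#' own point. No detection threshold is applied; undetected wells are
#' imputed at the platform's detection threshold (background level),
#' which makes the full assay set assessable. The weakest point(s) can
#' be dropped via `points_used` (by default the lowest-input point of a
#' five-point series is excluded). Assays with zero Ct variance after
#' imputation (e.g. never detected anywhere) get r-squared 0 and are
#' flagged.
#'
#' @param series a [dilution_series()].
#' @param config a [platform_config()]; its threshold is the imputation
#'   value.
#' @param points_used number of points retained, counted from the
#'   highest input (default: all but the lowest point).
#' @param restrict_assays optional assay id subset.
#' @param r2_cutoff summary cutoff for "linear" assays (default 0.9).
#' @return a `linearity_result` list: `per_assay` data.frame
#'   (`assay_id`, `r_squared`, `n_points_used`, `flagged`) and
#'   `summary` (`n_assays`, `n_assays_r2_ge_cutoff`, `cutoff`).
#' @export
assay_linearity <- function(series, config,
                            points_used = nrow(series$points) - 1L,
                            restrict_assays = NULL, r2_cutoff = 0.9) {
  if (points_used < 2L || points_used > nrow(series$points)) {
    sv_stop("points_used must be between 2 and the number of points")
  }
  pts <- series$points[seq_len(points_used), , drop = FALSE]
  sub <- series$ct[series$ct$sample_id %in% pts$point_id, , drop = FALSE]
  if (!is.null(restrict_assays)) {
    sub <- sub[sub$assay_id %in% restrict_assays, , drop = FALSE]
  }
  th <- config$detection_threshold_ct
  sub$ct_imputed <- ifelse(is.na(sub$ct), th, pmin(sub$ct, Inf))
  sub$log10_copies <- log10(
    pts$copies_per_pcr[match(sub$sample_id, pts$point_id)])

  sp <- split(sub, sub$assay_id)
  per <- lapply(sp, function(d) {
    y <- d$ct_imputed
    x <- d$log10_copies
    if (length(unique(x)) < 2L || var(y) == 0) {
      return(data.frame(assay_id = d$assay_id[1L], r_squared = 0,
                        n_points_used = length(unique(d$sample_id)),
                        flagged = TRUE, stringsAsFactors = FALSE))
    }
    data.frame(assay_id = d$assay_id[1L], r_squared = cor(x, y)^2,
               n_points_used = length(unique(d$sample_id)),
               flagged = FALSE, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  per <- per[order(per$assay_id), , drop = FALSE]
  rownames(per) <- NULL
  structure(list(per_assay = per,
                 summary = list(
                   n_assays = nrow(per),
                   n_assays_r2_ge_cutoff = sum(per$r_squared >= r2_cutoff),
                   cutoff = r2_cutoff)),
            class = "linearity_result")
}
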