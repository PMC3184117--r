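# Assembly of the machine-readable evaluation report: the pipeline's
# analog of the benchmark's summary tables (threshold curves, mismatch
# stratification, recovery summaries, reproducibility and dilution
# metrics), serialized as JSON plus per-section TSVs.

# internal: expected delta-Ct per assay for a sample pair, for every
# catalog assay whose target has nonzero copies in both samples
expected_deltas_for_catalog <- function(design, sample_a, sample_b,
                                        catalog) {
  targets <- catalog$target_mirna_id
  ca <- design_copies(design, sample_a, targets)
  cb <- design_copies(design, sample_b, targets)
  ok <- !is.na(targets) & ca > 0 & cb > 0
  setNames(log2(ca[ok] / cb[ok]), catalog$assay_id[ok])
}

# internal: list-ify S3 bits so jsonlite writes plain structures
plain <- function(x) {
  if (is.data.frame(x)) {
    attrs <- setdiff(names(attributes(x)), c("names", "row.names", "class"))
    for (a in attrs) attr(x, a) <- NULL
    return(as.data.frame(x))
  }
  if (is.list(x)) return(lapply(unclass(x), plain))
  x
}

#' Run the full evaluation over a (simulated or loaded) study
#'
#' Executes the requested analysis stages for every platform of the
#' study and assembles the evaluation report: specificity
#' (false-positive-rate curves over thresholds, suggested no-RT-based
#' threshold, expected homology fraction, enrichment, the
#' mismatch-stratified table), recovery (per-assay delta-Ct against
#' the design, per-direction summaries, cross-platform comparison),
#' reproducibility (duplicate correlations per sample) and
#' sensitivity/linearity (dilution-series detection counts and
#' correlations, cross-platform detection tests, per-assay linearity).
#' All stages are deterministic: the only randomness in the package
#' lives in the simulator behind its seed.
#'
#' @param study a [simulate_study()] result, or any list with the same
#'   shape (as produced by [run_evaluate()]'s input loader).
#' @param stages subset of `c("specificity", "recovery",
#'   "reproducibility", "sensitivity")`.
#' @param thresholds Ct thresholds for the specificity curves.
#' @param no_rt_quantile quantile for [suggest_threshold()].
#' @param r2_cutoff linearity cutoff (default 0.9).
#' @return an `evaluation_report` list with one section per stage plus
#'   `provenance`.
#' @export
evaluate_study <- function(study,
                           stages = c("specificity", "recovery",
                                      "reproducibility", "sensitivity"),
                           thresholds = seq(20, 40, by = 0.5),
                           no_rt_quantile = 0.01, r2_cutoff = 0.9) {
  stages <- match.arg(stages, several.ok = TRUE)
  platforms <- names(study$platforms)
  report <- list(specificity = NULL, recovery = NULL,
                 reproducibility = NULL, sensitivity_linearity = NULL)

  if ("specificity" %in% stages) {
    sec <- list()
    for (nm in platforms) {
      pl <- study$platforms[[nm]]
      ct <- study$tables[[nm]]
      cfg <- pl$profile$config
      no_rt <- ct_subset(ct, ct$sample_id == study$samples$no_rt)
      sugg <- suggest_threshold(no_rt, no_rt_quantile, cfg)
      curves <- list()
      enrich <- list()
      for (s in study$samples$synthetic) {
        cur <- fp_rate_curve(ct, s, study$design, pl$catalog, thresholds,
                             pl$homology)
        at <- cur[which.min(abs(cur$threshold -
                                  cfg$detection_threshold_ct)), ]
        enrich[[s]] <- list(
          threshold = at$threshold, n_false_positive = at$n_false_positive,
          n_homology_related = at$n_homology_related,
          fp_rate = at$fp_rate,
          p_poisson = at$p_enrichment,
          p_binomial = if (at$n_false_positive > 0)
            enrichment_test(at$n_homology_related, at$n_false_positive,
                            attr(cur, "expected_fraction"),
                            mode = "binomial", quiet = TRUE) else NA_real_)
        curves[[s]] <- plain(cur)
      }
      ef <- expected_homology_fraction(
        pl$catalog, study$panel,
        present_mirnas(study$design, study$samples$synthetic[1L]),
        homology = pl$homology)
      mt <- mismatch_stratified_fp(ct, study$samples$synthetic[1L],
                                   study$design, pl$catalog, pl$homology,
                                   cfg)
      sec[[nm]] <- list(detection_threshold = cfg$detection_threshold_ct,
                        suggested_threshold = sugg,
                        expected_fraction = ef, curves = curves,
                        enrichment_at_threshold = enrich,
                        mismatch_table = plain(mt))
    }
    report$specificity <- sec
  }

  if ("recovery" %in% stages) {
    com <- common_assays(study)
    per <- list()
    deltas_by <- list(synthetic = list(), spiked_plasma = list())
    expected_by <- list(synthetic = list(), spiked_plasma = list())
    for (nm in platforms) {
      pl <- study$platforms[[nm]]
      ct <- study$tables[[nm]]
      cfg <- pl$profile$config
      per[[nm]] <- list()
      for (role in c("synthetic", "spiked_plasma")) {
        pair <- study$samples[[role]]
        if (length(pair) != 2L) next
        exp_all <- expected_deltas_for_catalog(study$design, pair[1L],
                                               pair[2L], pl$catalog)
        use <- intersect(names(exp_all), com[[nm]])
        d <- delta_ct_per_assay(ct, pair[1L], pair[2L], assays = use,
                                config = cfg)
        summ <- recovery_summary(d, exp_all)
        per[[nm]][[role]] <- list(deltas = d, summary = plain(summ))
        deltas_by[[role]][[nm]] <- d
        expected_by[[role]][[nm]] <- exp_all
      }
    }
    comparisons <- list()
    if (length(platforms) >= 2L) {
      p1 <- platforms[1L]; p2 <- platforms[2L]
      for (role in c("synthetic", "spiked_plasma")) {
        d1 <- deltas_by[[role]][[p1]]
        d2 <- deltas_by[[role]][[p2]]
        if (is.null(d1) || is.null(d2)) next
        # compare on the shared target universe: reindex platform 2's
        # deltas by the target miRNA so assay ids line up
        tid1 <- study$platforms[[p1]]$catalog$target_mirna_id
        tid2 <- study$platforms[[p2]]$catalog$target_mirna_id
        map2 <- setNames(study$platforms[[p2]]$catalog$assay_id, tid2)
        tgt1 <- tid1[match(d1$assay_id,
                           study$platforms[[p1]]$catalog$assay_id)]
        d2r <- d2[match(map2[tgt1], d2$assay_id), , drop = FALSE]
        d2r$assay_id <- d1$assay_id
        d2r$included[is.na(d2r$included)] <- FALSE
        d2r$reason[is.na(d2r$reason)] <- "missing_from_platform"
        expected <- expected_by[[role]][[p1]]
        cmp <- tryCatch(
          compare_recovery(d1, d2r, expected),
          spikeval_refused = function(e) list(refused = conditionMessage(e)))
        comparisons[[role]] <- plain(unclass(cmp))
      }
    }
    report$recovery <- list(per_platform = per, comparisons = comparisons)
  }

  if ("reproducibility" %in% stages) {
    com <- common_assays(study)
    sec <- list()
    for (nm in platforms) {
      ct <- study$tables[[nm]]
      cfg <- study$platforms[[nm]]$profile$config
      roster <- c(study$samples$synthetic, study$samples$spiked_plasma,
                  study$samples$plasma, study$samples$no_rt)
      rows <- list()
      for (s in roster) {
        for (scope in c("all", "common")) {
          restrict <- if (scope == "common") com[[nm]] else NULL
          rc <- replicate_correlation(ct, s, cfg,
                                      restrict_assays = restrict)
          rows[[length(rows) + 1L]] <-
            data.frame(sample_id = s, scope = scope, r = rc$r,
                       n_detected = rc$n_detected,
                       stringsAsFactors = FALSE)
        }
      }
      sec[[nm]] <- do.call(rbind, rows)
      rownames(sec[[nm]]) <- NULL
    }
    report$reproducibility <- sec
  }

  if ("sensitivity" %in% stages &&
      length(study$samples$dilution)) {
    com <- common_assays(study)
    per <- list()
    for (nm in platforms) {
      cfg <- study$platforms[[nm]]$profile$config
      series <- study_dilution_series(study, nm)
      det <- dilution_detection(series, cfg, restrict_assays = com[[nm]])
      lin <- assay_linearity(series, cfg, restrict_assays = com[[nm]],
                             r2_cutoff = r2_cutoff)
      per[[nm]] <- list(dilution = det,
                        linearity_summary = lin$summary,
                        linearity_per_assay = lin$per_assay)
    }
    comparisons <- list()
    if (length(platforms) >= 2L) {
      p1 <- platforms[1L]; p2 <- platforms[2L]
      n_total <- length(com[[p1]])
      d1 <- per[[p1]]$dilution; d2 <- per[[p2]]$dilution
      comparisons$detection <- data.frame(
        point_id = d1$point_id,
        n_detected_1 = d1$n_detected, n_detected_2 = d2$n_detected,
        n_total = n_total,
        p = vapply(seq_len(nrow(d1)), function(i) {
          detection_comparison(d1$n_detected[i], d2$n_detected[i],
                               n_total)
        }, 0), stringsAsFactors = FALSE)
      l1 <- per[[p1]]$linearity_summary; l2 <- per[[p2]]$linearity_summary
      comparisons$linearity <- list(
        n_linear_1 = l1$n_assays_r2_ge_cutoff,
        n_linear_2 = l2$n_assays_r2_ge_cutoff,
        n_total_1 = l1$n_assays, n_total_2 = l2$n_assays,
        p = fisher_exact_2x2(
          l1$n_assays_r2_ge_cutoff,
          l1$n_assays - l1$n_assays_r2_ge_cutoff,
          l2$n_assays_r2_ge_cutoff,
          l2$n_assays - l2$n_assays_r2_ge_cutoff)$p_value)
    }
    report$sensitivity_linearity <- list(per_platform = per,
                                         comparisons = comparisons)
  }

  report$provenance <- list(
    tool = "spikeval",
    version = as.character(packageVersion("spikeval")),
    seed = if (!is.null(study$sim_seed)) study$sim_seed else NA,
    stages = stages,
    thresholds = list(min = min(thresholds), max = max(thresholds),
                      n = length(thresholds)),
    platforms = platforms,
    input_digests = if (!is.null(study$input_digests))
      study$input_digests else NULL)
  structure(plain(report), class = "evaluation_report")
}

#' Write an evaluation report (JSON plus per-section TSV tables)
#'
#' The JSON file holds the full nested report; the tabular sections
#' (specificity curves, mismatch table, per-assay recovery,
#' reproducibility, dilution metrics, per-assay linearity) are also
#' written as sibling TSV files for spreadsheet use.
#'
#' @param report an [evaluate_study()] result.
#' @param path path of the JSON file; TSVs are written next to it with
#'   the same stem.
#' @return invisibly, the vector of files written.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(plain(unclass(report)), path, auto_unbox = TRUE,
                       digits = NA, na = "null", null = "null",
                       pretty = TRUE)
  stem <- sub("\\.json$", "", path)
  files <- path
  emit <- function(df, tag) {
    f <- paste0(stem, "_", tag, ".tsv")
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, f)
  }
  for (nm in names(report$specificity)) {
    sp <- report$specificity[[nm]]
    for (s in names(sp$curves)) {
      emit(sp$curves[[s]], paste0("specificity_", nm, "_", s))
    }
    emit(sp$mismatch_table, paste0("mismatch_", nm))
  }
  for (nm in names(report$recovery$per_platform)) {
    for (role in names(report$recovery$per_platform[[nm]])) {
      emit(report$recovery$per_platform[[nm]][[role]]$deltas,
           paste0("recovery_", nm, "_", role))
    }
  }
  for (nm in names(report$reproducibility)) {
    emit(report$reproducibility[[nm]], paste0("reproducibility_", nm))
  }
  for (nm in names(report$sensitivity_linearity$per_platform)) {
    pp <- report$sensitivity_linearity$per_platform[[nm]]
    emit(pp$dilution, paste0("dilution_", nm))
    emit(pp$linearity_per_assay, paste0("linearity_", nm))
  }
  invisible(files)
}

#' Read an evaluation report back from its JSON file
#' @param path JSON path written by [write_report()].
#' @return the report as nested lists/data.frames.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE,
                     simplifyDataFrame = TRUE)
}
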