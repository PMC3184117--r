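#' Alignment parameters for the homology screen
#'
#' The cross-reactivity screen asks, for every assay, which panel
#' miRNAs lie within a bounded sequence distance of the assay's target:
#' at most `max_mismatches` mismatched positions in the best local
#' (Smith-Waterman) alignment and at most `max_overhang` unaligned
#' terminal bases at either end. Scoring values are the simplest scheme
#' consistent with those bounds (+1 match, -1 mismatch, -1 gap,
#' linear); all of them are configurable.
#'
#' @param match_score,mismatch_score,gap_score alignment scores;
#'   `gap_score = -Inf` disables gaps entirely.
#' @param max_mismatches inclusive mismatch bound (default 4).
#' @param max_overhang inclusive per-end overhang bound (default 8).
#' @param count_indels_as_mismatches if `TRUE` (default) gap columns
#'   inside the local alignment count toward the mismatch total.
#' @return an `alignment_params` list.
#' @export
alignment_params <- function(match_score = 1, mismatch_score = -1,
                             gap_score = -1, max_mismatches = 4L,
                             max_overhang = 8L,
                             count_indels_as_mismatches = TRUE) {
  if (match_score <= 0) sv_stop("match_score must be positive")
  if (max_mismatches < 0 || max_overhang < 0) {
    sv_stop("max_mismatches and max_overhang must be >= 0")
  }
  structure(list(match_score = match_score,
                 mismatch_score = mismatch_score,
                 gap_score = gap_score,
                 max_mismatches = as.integer(max_mismatches),
                 max_overhang = as.integer(max_overhang),
                 count_indels_as_mismatches =
                   isTRUE(count_indels_as_mismatches)),
            class = "alignment_params")
}

# internal: map -Inf gap scores to a finite sentinel the C++ DP can use
finite_gap <- function(gap_score) {
  if (is.infinite(gap_score) && gap_score < 0) -1e9 else gap_score
}

#' Align a pair of sequences and summarize the best local alignment
#'
#' Runs Smith-Waterman local alignment under `params` and reports the
#' summary the homology bound is defined on, in "nucleotide
#' difference" terms over the end-to-end overlap the alignment
#' implies: `mismatches` counts the mismatched core columns
#' (substitutions plus, by default, gap columns) together with the
#' differences found when the core is extended diagonally through the
#' overlapping terminal bases that score maximization trimmed away --
#' those positions still face a base of the other sequence, so
#' trimming must not silently convert them into overhang.
#' `overhang_left`/`overhang_right` count only the genuine
#' end offset: the bases by which one sequence extends past the other
#' at that end. `aligned_length` is the span of the implied overlap.
#' Ties among equal-scoring alignments are broken by fewest
#' mismatches, then smallest total overhang, then leftmost start, so
#' the output is deterministic. If the sequences share no common base
#' at all, the summary is the offset-0 full overlap, entirely
#' mismatched.
#'
#' @param seq_a,seq_b nucleotide sequences (normalized internally).
#' @param params an [alignment_params()].
#' @return an `alignment_summary` list with elements `mismatches`,
#'   `overhang_left`, `overhang_right`, `aligned_length`, `score`.
#' @export
align_pair <- function(seq_a, seq_b, params = alignment_params()) {
  seq_a <- normalize_sequence(seq_a)
  seq_b <- normalize_sequence(seq_b)
  if (!nzchar(seq_a) || !nzchar(seq_b)) sv_stop("empty sequence")
  out <- sw_align_cpp(seq_a, seq_b, params$match_score,
                      params$mismatch_score, finite_gap(params$gap_score),
                      params$count_indels_as_mismatches)
  structure(out, class = "alignment_summary")
}

#' Does an alignment summary satisfy the homology bound?
#'
#' TRUE iff `mismatches <= max_mismatches` and each terminal overhang
#' is `<= max_overhang` (bounds inclusive: "up to four mismatches and
#' eight nucleotide overhangs" admits exactly 4 and exactly 8).
#'
#' @param summary an `alignment_summary` (or any list with the three
#'   fields).
#' @param params an [alignment_params()].
#' @return logical.
#' @export
is_homologous <- function(summary, params = alignment_params()) {
  summary$mismatches <= params$max_mismatches &&
    summary$overhang_left <= params$max_overhang &&
    summary$overhang_right <= params$max_overhang
}

#' Build the homology map between an assay catalog and a miRNA panel
#'
#' For every assay, aligns its target sequence against every panel
#' miRNA and keeps the pairs satisfying [is_homologous()]. An assay's
#' own designed target is excluded from its homolog list: homologs
#' model cross-reaction, not intended detection. Entries are ordered by
#' mismatch count, then miRNA id.
#'
#' @param catalog an [assay_catalog()].
#' @param panel a [mirna_panel()].
#' @param params an [alignment_params()].
#' @return a `homology_map` data.frame with columns `assay_id`,
#'   `platform_id`, `mirna_id`, `mismatches`, `overhang_left`,
#'   `overhang_right`, `aligned_length`; attribute `params`.
#' @export
build_homology_map <- function(catalog, panel,
                               params = alignment_params()) {
  if (!nrow(catalog) || !nrow(panel)) sv_stop("empty catalog or panel")
  res <- sw_align_many_cpp(catalog$target_sequence, panel$sequence,
                           params$match_score, params$mismatch_score,
                           finite_gap(params$gap_score),
                           params$count_indels_as_mismatches)
  ok <- res$mismatches <= params$max_mismatches &
    res$overhang_left <= params$max_overhang &
    res$overhang_right <= params$max_overhang
  # drop each assay's own designed target
  own <- outer(catalog$target_mirna_id, panel$mirna_id, "==")
  own[is.na(own)] <- FALSE
  ok <- ok & !own
  idx <- which(ok, arr.ind = TRUE)
  df <- data.frame(assay_id = catalog$assay_id[idx[, 1L]],
                   platform_id = catalog$platform_id[idx[, 1L]],
                   mirna_id = panel$mirna_id[idx[, 2L]],
                   mismatches = res$mismatches[idx],
                   overhang_left = res$overhang_left[idx],
                   overhang_right = res$overhang_right[idx],
                   aligned_length = res$aligned_length[idx],
                   stringsAsFactors = FALSE)
  df <- df[order(match(df$assay_id, catalog$assay_id), df$mismatches,
                 df$mirna_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, params = params,
            class = c("homology_map", "data.frame"))
}

#' Write a homology map to TSV
#' @param map a [build_homology_map()] result.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_homology_map <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Expected fraction of potential false positives explained by homology
#'
#' A potential false positive is an assay whose designed target miRNA
#' is absent from the sample; among those, this computes how many have
#' sequence homology (per the homology map) to at least one miRNA that
#' is present. The resulting fraction is the null expectation for the
#' share of homology-related false positives if detection were
#' independent of homology.
#'
#' @param catalog an [assay_catalog()].
#' @param panel a [mirna_panel()] (only used to build `homology` when
#'   not supplied).
#' @param sample_mirnas character vector of miRNA ids present in the
#'   sample.
#' @param params an [alignment_params()].
#' @param homology optional precomputed [build_homology_map()].
#' @return list with `n_potential_fp`, `n_homologous`, `fraction`.
#' @export
expected_homology_fraction <- function(catalog, panel, sample_mirnas,
                                       params = alignment_params(),
                                       homology = NULL) {
  if (is.null(homology)) {
    homology <- build_homology_map(catalog, panel, params)
  }
  absent <- !(catalog$target_mirna_id %in% sample_mirnas)
  n_pot <- sum(absent)
  if (n_pot == 0L) {
    sv_stop("no assay targets a miRNA absent from the sample; ",
            "expected fraction undefined", class = "spikeval_undefined")
  }
  rel <- homology[homology$mirna_id %in% sample_mirnas, , drop = FALSE]
  homologous_assays <- unique(rel$assay_id)
  n_hom <- sum(catalog$assay_id[absent] %in% homologous_assays)
  list(n_potential_fp = n_pot, n_homologous = n_hom,
       fraction = n_hom / n_pot)
}
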