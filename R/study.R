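# Study-level generators: random panels with planted homologs, assay
# catalogs, the full spike design roster (two reciprocal 4:1 synthetic
# samples, spiked plasma, a no-RT control and a five-point 10-fold
# dilution series) and the end-to-end simulated study.

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = "")
  }, "")
}

# substitute exactly m interior positions (>= 5 bases from each end) so
# the planted mismatch count survives terminal trimming by the aligner
mutate_interior <- function(seq, m) {
  if (m == 0L) return(seq)
  ch <- strsplit(seq, "")[[1L]]
  len <- length(ch)
  pos <- sample(seq(5L, len - 4L), m)
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Generate a random synthetic miRNA panel
#'
#' Random sequences standing in for the two pools of synthetic
#' spike-in miRNAs (88 in pool A, 86 in pool B by default).
#'
#' @param n_pool_a,n_pool_b pool sizes (defaults 88 and 86).
#' @param length sequence length in nt (default 22).
#' @param seed integer seed.
#' @return a [mirna_panel()].
#' @export
make_panel <- function(n_pool_a = 88L, n_pool_b = 86L, length = 22L,
                       seed = 7L) {
  set.seed(seed)
  n <- n_pool_a + n_pool_b
  mirna_panel(sprintf("syn-mir-%03d", seq_len(n)),
              random_dna(n, length),
              rep(c("A", "B"), c(n_pool_a, n_pool_b)))
}

#' Generate off-panel miRNA species, with planted homologs
#'
#' Models the remainder of a platform's assay universe: miRNAs that
#' are not spiked into the samples. Some are planted as mutated copies
#' of random panel members carrying an exact number of interior
#' substitutions (the cross-reaction candidates, stratified by
#' mismatch count), the rest are unrelated random sequences.
#'
#' @param panel a [mirna_panel()].
#' @param n_random number of unrelated off-panel species.
#' @param homolog_counts named or positional integer vector: how many
#'   off-panel species to plant at 0, 1, 2, ... mismatches from a
#'   panel member.
#' @param seed integer seed.
#' @return data.frame with columns `mirna_id`, `sequence`,
#'   `planted_mismatches` (`NA` for unrelated species),
#'   `source_mirna_id`.
#' @export
make_offpanel <- function(panel, n_random = 385L,
                          homolog_counts = c(3L, 18L, 34L, 52L, 60L),
                          seed = 11L) {
  set.seed(seed)
  rows <- list()
  idx <- 0L
  for (m in seq_along(homolog_counts)) {
    mm <- m - 1L
    for (i in seq_len(homolog_counts[m])) {
      idx <- idx + 1L
      src <- sample(nrow(panel), 1L)
      rows[[idx]] <- data.frame(
        mirna_id = sprintf("off-hom-%03d", idx),
        sequence = mutate_interior(panel$sequence[src], mm),
        planted_mismatches = mm,
        source_mirna_id = panel$mirna_id[src],
        stringsAsFactors = FALSE)
    }
  }
  planted <- if (idx) do.call(rbind, rows) else NULL
  unrelated <- data.frame(
    mirna_id = sprintf("off-rnd-%03d", seq_len(n_random)),
    sequence = random_dna(n_random, nchar(panel$sequence[1L])),
    planted_mismatches = NA_integer_,
    source_mirna_id = NA_character_, stringsAsFactors = FALSE)
  out <- rbind(planted, unrelated)
  rownames(out) <- NULL
  out
}

#' Build a platform assay catalog for a simulated study
#'
#' One assay per covered panel miRNA (target sequence equal to the
#' miRNA sequence) plus one assay per off-panel species. Panel
#' coverage below 1 drops a random subset of panel miRNAs from the
#' platform, emulating incomplete panel representation.
#'
#' @param panel a [mirna_panel()].
#' @param offpanel a [make_offpanel()] result (or NULL for none).
#' @param platform_id platform label.
#' @param panel_coverage fraction of panel miRNAs with an assay.
#' @param seed integer seed (used for the coverage subset).
#' @return an [assay_catalog()].
#' @export
make_catalog <- function(panel, offpanel = NULL, platform_id = "sim",
                         panel_coverage = 1.0, seed = 13L) {
  set.seed(seed)
  n_keep <- round(panel_coverage * nrow(panel))
  keep <- sort(sample(nrow(panel), n_keep))
  ids <- c(panel$mirna_id[keep],
           if (!is.null(offpanel)) offpanel$mirna_id)
  seqs <- c(panel$sequence[keep],
            if (!is.null(offpanel)) offpanel$sequence)
  assay_catalog(paste0(platform_id, "-", ids), platform_id, ids, seqs)
}

#' Build the study spike design
#'
#' The roster mirrors a reciprocal-pool spike-in study: two synthetic
#' samples mixing pool A and pool B 1:4 and 4:1 (0.25e6 and 1e6 copies
#' per reaction for the low- and high-abundance pools, giving every
#' species a four-fold difference between the samples), spiked plasma
#' counterparts adding an endogenous background, a pure plasma sample,
#' a no-RT control without any template, and a five-point 10-fold
#' dilution series of spiked plasma sample 1 starting at 5000 (pool A)
#' / 20000 (pool B) copies per PCR.
#'
#' @param panel a [mirna_panel()].
#' @param endogenous optional data.frame (`mirna_id`,
#'   `copies_per_reaction`) of endogenous plasma species.
#' @param copies_high,copies_low per-reaction copies of the abundant /
#'   scarce pool (defaults 1e6 and 0.25e6).
#' @param dilution_start_copies pool-A copies per PCR at the first
#'   dilution point (default 5000); pool B scales with the high/low
#'   ratio.
#' @param n_dilution_points number of 10-fold points (default 5).
#' @return list: `design` (a [spike_design()] over all samples),
#'   `samples` (roster of sample ids by role), `dilution_points`
#'   (data.frame `point_id`, `copies_per_pcr`).
#' @export
study_design <- function(panel, endogenous = NULL, copies_high = 1e6,
                         copies_low = 0.25e6,
                         dilution_start_copies = 5000,
                         n_dilution_points = 5L) {
  a <- panel$pool == "A"
  rows <- list(
    data.frame(sample_id = "synthetic_1", mirna_id = panel$mirna_id,
               copies_per_reaction = ifelse(a, copies_low, copies_high)),
    data.frame(sample_id = "synthetic_2", mirna_id = panel$mirna_id,
               copies_per_reaction = ifelse(a, copies_high, copies_low)))
  endo <- if (!is.null(endogenous) && nrow(endogenous)) {
    data.frame(mirna_id = endogenous$mirna_id,
               copies_per_reaction = endogenous$copies_per_reaction)
  } else NULL
  add_sample <- function(id, base) {
    data.frame(sample_id = id, mirna_id = base$mirna_id,
               copies_per_reaction = base$copies_per_reaction)
  }
  sp1 <- rbind(rows[[1L]][-1L], endo)
  sp2 <- rbind(rows[[2L]][-1L], endo)
  rows <- c(rows, list(add_sample("spiked_plasma_1", sp1),
                       add_sample("spiked_plasma_2", sp2)))
  if (!is.null(endo)) rows <- c(rows, list(add_sample("plasma", endo)))
  # dilution series: spiked plasma sample 1 scaled to copies-per-PCR
  scale0 <- dilution_start_copies / copies_low
  pts <- data.frame(
    point_id = paste0("dil_", seq_len(n_dilution_points)),
    copies_per_pcr = dilution_start_copies *
      10^(-(seq_len(n_dilution_points) - 1L)))
  for (p in seq_len(n_dilution_points)) {
    sc <- scale0 * 10^(-(p - 1L))
    d <- sp1
    d$copies_per_reaction <- d$copies_per_reaction * sc
    rows <- c(rows, list(add_sample(pts$point_id[p], d)))
  }
  all <- do.call(rbind, rows)
  design <- spike_design(all$sample_id, all$mirna_id,
                         all$copies_per_reaction)
  samples <- list(synthetic = c("synthetic_1", "synthetic_2"),
                  spiked_plasma = c("spiked_plasma_1", "spiked_plasma_2"),
                  plasma = if (!is.null(endo)) "plasma" else character(0),
                  no_rt = "no_rt", dilution = pts$point_id)
  list(design = design, samples = samples, dilution_points = pts)
}

#' Assemble the deterministic scaffold of a simulated study
#'
#' Everything about a study that is fixed before any well is simulated:
#' the panel, the off-panel species, the endogenous plasma content, the
#' per-platform assay catalogs with their homology maps, and the spike
#' design roster. Separating the scaffold from [simulate_study()] lets
#' many noise realizations share one (comparatively expensive) homology
#' screen.
#'
#' @param panel a [mirna_panel()]; default [make_panel()] at full study
#'   scale.
#' @param offpanel a [make_offpanel()] result; default at full scale.
#' @param profiles named list of [platform_profile()]s.
#' @param n_endogenous number of endogenous plasma species (drawn from
#'   the unrelated off-panel species).
#' @param endogenous_copies_range log-uniform range of endogenous
#'   copies per reaction.
#' @param align_params an [alignment_params()].
#' @param seed integer seed (endogenous draw and coverage subsets).
#' @param ... forwarded to [study_design()].
#' @return a `study_scaffold` list.
#' @export
study_scaffold <- function(panel = make_panel(),
                           offpanel = make_offpanel(panel),
                           profiles = list(
                             mircury_like = platform_profile("mircury_like"),
                             taqman_like = platform_profile("taqman_like")),
                           n_endogenous = 100L,
                           endogenous_copies_range = c(1e2, 1e5),
                           align_params = alignment_params(),
                           seed = 17L, ...) {
  set.seed(seed)
  endo <- NULL
  if (n_endogenous > 0L && !is.null(offpanel)) {
    pool <- offpanel$mirna_id[is.na(offpanel$planted_mismatches)]
    if (n_endogenous > length(pool)) {
      sv_stop("n_endogenous exceeds the number of unrelated off-panel ",
              "species")
    }
    ids <- sort(sample(pool, n_endogenous))
    lo <- log10(endogenous_copies_range[1L])
    hi <- log10(endogenous_copies_range[2L])
    endo <- data.frame(mirna_id = ids,
                       copies_per_reaction = 10^runif(n_endogenous, lo, hi),
                       stringsAsFactors = FALSE)
  }
  des <- study_design(panel, endogenous = endo, ...)
  platforms <- list()
  for (i in seq_along(profiles)) {
    prof <- profiles[[i]]
    nm <- names(profiles)[i]
    catalog <- make_catalog(panel, offpanel, platform_id = nm,
                            panel_coverage = prof$panel_coverage,
                            seed = seed + i)
    platforms[[nm]] <- list(profile = prof, catalog = catalog,
                            homology = build_homology_map(
                              catalog, panel, align_params))
  }
  structure(list(panel = panel, offpanel = offpanel, endogenous = endo,
                 design = des$design, samples = des$samples,
                 dilution_points = des$dilution_points,
                 platforms = platforms, align_params = align_params,
                 seed = seed),
            class = "study_scaffold")
}

#' Simulate the full study
#'
#' Simulates every Ct table of the study roster (synthetic samples,
#' spiked plasma, pure plasma, no-RT control and the dilution series)
#' for each platform profile of the scaffold, and returns them together
#' with the ground truth.
#'
#' @param scaffold a [study_scaffold()].
#' @param seed integer seed for the stochastic wells.
#' @param n_replicates replicates per sample (default 2).
#' @return a `simulated_study` list: the scaffold fields plus `tables`
#'   (named per platform, each a [ct_table()] covering all samples) and
#'   `seed`.
#' @export
simulate_study <- function(scaffold, seed = scaffold$seed,
                           n_replicates = 2L) {
  set.seed(seed)
  roster <- c(scaffold$samples$synthetic, scaffold$samples$spiked_plasma,
              scaffold$samples$plasma, scaffold$samples$no_rt,
              scaffold$samples$dilution)
  tables <- list()
  for (nm in names(scaffold$platforms)) {
    pl <- scaffold$platforms[[nm]]
    tables[[nm]] <- simulate_ct_table(scaffold$design, pl$catalog,
                                      pl$homology, pl$profile$params,
                                      n_replicates = n_replicates,
                                      samples = roster, seed = NULL)
  }
  structure(c(scaffold, list(tables = tables, sim_seed = seed,
                             n_replicates = n_replicates)),
            class = "simulated_study")
}

# internal: dilution series object for one platform of a study
study_dilution_series <- function(study, platform) {
  ct <- study$tables[[platform]]
  dil <- ct_subset(ct, ct$sample_id %in% study$dilution_points$point_id)
  dilution_series(dil, study$dilution_points)
}

# internal: assay ids shared by all platforms (via common target ids)
common_assays <- function(study) {
  targets <- lapply(study$platforms, function(pl) {
    pl$catalog$target_mirna_id[pl$catalog$target_mirna_id %in%
                                 study$panel$mirna_id]
  })
  shared <- Reduce(intersect, targets)
  lapply(study$platforms, function(pl) {
    pl$catalog$assay_id[match(shared, pl$catalog$target_mirna_id)]
  })
}
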