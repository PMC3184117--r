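# Parametric Ct-data simulator. Generates Ct tables with the
# statistical structure the evaluation assumes: a log-linear
# amplification model, Gaussian cycle noise, Poisson well occupancy at
# low copy numbers (mechanistic dropout), mismatch-dependent
# cross-reactive amplification driven by the homology map,
# template-independent background signals (no-RT-like), and sporadic
# poorly amplifying outlier wells.

#' Simulator parameters
#'
#' @param ct_at_ref Ct observed at the reference copy number (default
#'   20 at `ref_copies` = 1e6).
#' @param ref_copies reference copy number for `ct_at_ref`.
#' @param efficiency per-cycle amplification efficiency in (0, 1]; the
#'   per-cycle factor is `1 + efficiency` (1.0 = perfect doubling, one
#'   Ct per two-fold).
#' @param noise_sd Gaussian measurement noise on Ct, in cycles.
#' @param preamp_cycles pre-amplification modeled as a pure downward Ct
#'   offset (cycles subtracted).
#' @param crossreact_base_fraction weight with which a perfectly
#'   matching off-target template (0 mismatches) contributes to an
#'   assay's effective template.
#' @param crossreact_log10_penalty_per_mismatch each mismatch divides
#'   the cross-reactive contribution by `10^penalty` (default 1, i.e.
#'   ten-fold per mismatch).
#' @param background_rate probability that an assay-replicate well
#'   emits a template-independent background signal.
#' @param background_ct_range uniform Ct range of background signals.
#' @param outlier_well_rate probability of a poorly amplifying well.
#' @param outlier_shift Ct shift applied to an outlier well (`NA` turns
#'   the well undetected instead).
#' @param input_fraction fraction of the nominal copies a reaction
#'   actually samples (models reverse-transcription/loading
#'   efficiency); scales the occupancy mean.
#' @param occupancy_dropout draw template molecules per well from a
#'   Poisson with mean equal to the effective copies (TRUE, default)
#'   or use the mean deterministically (FALSE).
#' @param max_cycles run length; Ct values beyond it become undetected.
#' @param seed integer seed used by [simulate_ct_table()] by default.
#' @return a `simulator_params` list.
#' @export
simulator_params <- function(ct_at_ref = 20, ref_copies = 1e6,
                             efficiency = 1.0, noise_sd = 0.3,
                             preamp_cycles = 0L,
                             crossreact_base_fraction = 0.5,
                             crossreact_log10_penalty_per_mismatch = 1.0,
                             background_rate = 0.05,
                             background_ct_range = c(38, 40),
                             outlier_well_rate = 0, outlier_shift = 6,
                             input_fraction = 1.0,
                             occupancy_dropout = TRUE, max_cycles = 40,
                             seed = 1L) {
  p <- list(ct_at_ref = ct_at_ref, ref_copies = ref_copies,
            efficiency = efficiency, noise_sd = noise_sd,
            preamp_cycles = preamp_cycles,
            crossreact_base_fraction = crossreact_base_fraction,
            crossreact_log10_penalty_per_mismatch =
              crossreact_log10_penalty_per_mismatch,
            background_rate = background_rate,
            background_ct_range = background_ct_range,
            outlier_well_rate = outlier_well_rate,
            outlier_shift = outlier_shift,
            input_fraction = input_fraction,
            occupancy_dropout = isTRUE(occupancy_dropout),
            max_cycles = max_cycles, seed = as.integer(seed))
  rates <- c(p$crossreact_base_fraction, p$background_rate,
             p$outlier_well_rate)
  if (any(rates < 0 | rates > 1)) sv_stop("rates must lie in [0, 1]")
  if (p$noise_sd < 0) sv_stop("noise_sd must be >= 0")
  if (p$efficiency <= 0 || p$efficiency > 1) {
    sv_stop("efficiency must be in (0, 1]")
  }
  if (p$input_fraction <= 0) sv_stop("input_fraction must be positive")
  structure(p, class = "simulator_params")
}

#' Built-in platform profiles
#'
#' Two stylized platform presets used throughout the package. They
#' emulate the qualitative contrasts between a universal-RT, LNA-primer
#' style platform and a stem-loop-RT, pre-amplified style platform
#' without making claims about any real product's parameters:
#' `"mircury_like"` has no pre-amplification, a detection threshold of
#' Ct 38, and a ~10% no-RT background signal rate at late Ct;
#' `"taqman_like"` has a 12-cycle pre-amplification offset, a detection
#' threshold of Ct 30, almost no background signals, a smaller sampled
#' input fraction (stronger low-copy dropout), more cycle noise and
#' more sporadic poorly amplifying wells.
#'
#' @param name `"mircury_like"` or `"taqman_like"`.
#' @param seed seed stored in the profile's parameters.
#' @param ... overrides forwarded to [simulator_params()].
#' @return a `platform_profile` list: `name`, `params`
#'   ([simulator_params()]), `config` ([platform_config()]), and
#'   `panel_coverage` (fraction of panel miRNAs with an assay).
#' @export
platform_profile <- function(name = c("mircury_like", "taqman_like"),
                             seed = 1L, ...) {
  name <- match.arg(name)
  if (name == "mircury_like") {
    defaults <- list(preamp_cycles = 0L, background_rate = 66 / 689,
                     outlier_well_rate = 0.002, input_fraction = 1.0,
                     seed = seed)
    threshold <- 38
    coverage <- 143 / 174
  } else {
    defaults <- list(preamp_cycles = 12L, background_rate = 0.005,
                     outlier_well_rate = 0.02, input_fraction = 0.1,
                     seed = seed)
    threshold <- 30
    coverage <- 155 / 174
  }
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  params <- do.call(simulator_params, defaults)
  config <- platform_config(threshold, max_cycles = params$max_cycles)
  structure(list(name = name, params = params, config = config,
                 panel_coverage = coverage),
            class = "platform_profile")
}

#' Expected Ct under the log-linear amplification model
#'
#' `Ct = ct_at_ref - log(copies / ref_copies) / log(1 + efficiency)
#' - preamp_cycles`: at 100% efficiency each two-fold increase in
#' template lowers Ct by one cycle, so a four-fold difference is two
#' cycles.
#'
#' @param copies template copies, > 0 (vectorized).
#' @param params a [simulator_params()].
#' @return expected Ct values.
#' @export
expected_ct <- function(copies, params = simulator_params()) {
  if (any(copies <= 0)) sv_stop("copies must be positive")
  params$ct_at_ref -
    log(copies / params$ref_copies) / log(1 + params$efficiency) -
    params$preamp_cycles
}

#' Effective template copies seen by each assay in a sample
#'
#' The assay's own designed target copies plus the cross-reactive
#' contribution of every homologous panel miRNA present in the sample:
#' `copies * crossreact_base_fraction *
#' 10^(-penalty * mismatches)`. With the cross-reaction weight at zero
#' (or an infinite penalty) the effective template reduces to the own
#' target copies.
#'
#' @param assay_ids assay ids (vectorized).
#' @param sample_id sample id.
#' @param catalog an [assay_catalog()].
#' @param design a [spike_design()].
#' @param homology a [build_homology_map()] covering the assays.
#' @param params a [simulator_params()].
#' @return named numeric vector of effective copies per assay.
#' @export
effective_template <- function(assay_ids, sample_id, catalog, design,
                               homology, params = simulator_params()) {
  target <- catalog$target_mirna_id[match(assay_ids, catalog$assay_id)]
  ids <- unique(c(target[!is.na(target)], homology$mirna_id))
  copies <- if (length(ids)) design_copies(design, sample_id, ids) else
    numeric(0)
  own <- ifelse(is.na(target), 0, copies[target])
  own[is.na(own)] <- 0
  out <- setNames(as.numeric(own), assay_ids)
  hm <- homology[homology$assay_id %in% assay_ids, , drop = FALSE]
  if (nrow(hm) && params$crossreact_base_fraction > 0) {
    w <- copies[hm$mirna_id] * params$crossreact_base_fraction *
      10^(-params$crossreact_log10_penalty_per_mismatch * hm$mismatches)
    cross <- tapply(w, hm$assay_id, sum)
    out[names(cross)] <- out[names(cross)] + as.numeric(cross)
  }
  out
}

#' Simulate a Ct table for every sample of a design
#'
#' Per (sample, assay, replicate) well: the effective template (scaled
#' by `input_fraction`) sets the Poisson occupancy mean; an occupancy
#' of zero leaves the well undetected unless a background signal fires
#' (uniform Ct in `background_ct_range`); otherwise the Ct is the
#' log-linear expectation at the realized occupancy plus Gaussian
#' noise, possibly shifted by a poorly-amplifying-well outlier. Ct
#' values beyond `max_cycles` become undetected. The output is fully
#' reproducible for a given seed.
#'
#' @param design a [spike_design()].
#' @param catalog an [assay_catalog()].
#' @param homology a [build_homology_map()].
#' @param params a [simulator_params()].
#' @param n_replicates replicates per sample (default 2, duplicate
#'   RT + qPCR).
#' @param samples sample ids to simulate; defaults to the samples in
#'   the design. Samples without design rows (e.g. a no-RT control)
#'   receive background signals only.
#' @param seed seed applied on entry (`NULL` to use the current RNG
#'   state, e.g. inside [simulate_study()]).
#' @return a [ct_table()].
#' @export
simulate_ct_table <- function(design, catalog, homology, params,
                              n_replicates = 2L,
                              samples = NULL, seed = params$seed) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(samples)) samples <- unique(design$sample_id)
  n_assay <- nrow(catalog)
  blocks <- list()
  for (s in samples) {
    lam <- effective_template(catalog$assay_id, s, catalog, design,
                              homology, params) * params$input_fraction
    for (rep_i in seq_len(n_replicates)) {
      k <- if (params$occupancy_dropout) rpois(n_assay, lam) else lam
      ctv <- rep(NA_real_, n_assay)
      pos <- which(k > 0)
      if (length(pos)) {
        ctv[pos] <- expected_ct(k[pos], params)
        if (params$noise_sd > 0) {
          ctv[pos] <- ctv[pos] + rnorm(length(pos), 0, params$noise_sd)
        }
      }
      fires <- runif(n_assay) < params$background_rate
      bg <- runif(n_assay, params$background_ct_range[1L],
                  params$background_ct_range[2L])
      take_bg <- fires & (is.na(ctv) | bg < ctv)
      ctv[take_bg] <- bg[take_bg]
      if (params$outlier_well_rate > 0) {
        out_w <- runif(n_assay) < params$outlier_well_rate
        hit <- out_w & !is.na(ctv)
        if (is.na(params$outlier_shift)) {
          ctv[hit] <- NA_real_
        } else {
          ctv[hit] <- ctv[hit] + params$outlier_shift
        }
      }
      ctv[!is.na(ctv) & ctv > params$max_cycles] <- NA_real_
      ctv[!is.na(ctv) & ctv <= 0] <- 0.01  # unreachable at sane params
      blocks[[length(blocks) + 1L]] <-
        data.frame(sample_id = s, replicate_id = paste0("r", rep_i),
                   assay_id = catalog$assay_id, ct = ctv,
                   stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, blocks)
  ct_table(df$sample_id, df$replicate_id, df$assay_id, df$ct,
           max_cycles = params$max_cycles)
}
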