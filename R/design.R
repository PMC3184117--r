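#' Construct a spike design
#'
#' The spike design records, per sample, how many copies of each spiked
#' miRNA were added per reaction. Pairs absent from the design mean
#' zero copies (the miRNA is not in that sample). The design implies
#' the expected log2 fold change (expected delta-Ct) between any two
#' samples for every species present in both.
#'
#' @param sample_id,mirna_id character vectors.
#' @param copies_per_reaction non-negative numeric copies.
#' @return a `spike_design` data.frame.
#' @export
spike_design <- function(sample_id, mirna_id, copies_per_reaction) {
  df <- data.frame(sample_id = as.character(sample_id),
                   mirna_id = as.character(mirna_id),
                   copies_per_reaction = as.numeric(copies_per_reaction),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$copies_per_reaction)) ||
      any(df$copies_per_reaction < 0)) {
    sv_stop("copies_per_reaction must be finite and >= 0")
  }
  key <- paste(df$sample_id, df$mirna_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), ][1L, ]
    sv_stop("duplicate design entry: (", d$sample_id, ", ", d$mirna_id, ")")
  }
  structure(df, class = c("spike_design", "data.frame"))
}

#' Read a spike design from TSV (columns `sample_id`, `mirna_id`,
#' `copies_per_reaction`)
#' @param path file path.
#' @return a [spike_design()].
#' @export
read_spike_design <- function(path) {
  df <- read.delim(path, check.names = FALSE,
                   colClasses = c(sample_id = "character",
                                  mirna_id = "character"))
  need <- c("sample_id", "mirna_id", "copies_per_reaction")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    sv_stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  }
  spike_design(df$sample_id, df$mirna_id,
               as.numeric(df$copies_per_reaction))
}

#' Write a spike design to TSV
#' @param design a [spike_design()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_spike_design <- function(design, path) {
  write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# internal: copies of each mirna in one sample (0 when absent)
design_copies <- function(design, sample_id, mirna_ids) {
  sub <- design[design$sample_id == sample_id, , drop = FALSE]
  out <- setNames(rep(0, length(mirna_ids)), mirna_ids)
  hit <- sub$mirna_id %in% mirna_ids
  out[sub$mirna_id[hit]] <- sub$copies_per_reaction[hit]
  out
}

# internal: ids with nonzero copies in a sample
present_mirnas <- function(design, sample_id) {
  sub <- design[design$sample_id == sample_id &
                  design$copies_per_reaction > 0, , drop = FALSE]
  unique(sub$mirna_id)
}

#' Expected delta-Ct between two samples for one miRNA
#'
#' Under ideal (100% efficient) amplification, a template present at
#' `c_a` copies in sample A and `c_b` copies in sample B yields a Ct
#' difference `Ct(B) - Ct(A) = log2(c_a / c_b)`: a species four-fold
#' higher in sample A gives an expected delta-Ct of +2. This is the
#' sign convention used throughout the package (delta-Ct is reported
#' as Ct of the second sample minus Ct of the first).
#'
#' @param design a [spike_design()].
#' @param sample_a,sample_b sample ids.
#' @param mirna_id miRNA id; must have nonzero copies in both samples.
#' @return expected delta-Ct (log2 fold change of A over B).
#' @export
expected_delta_ct <- function(design, sample_a, sample_b, mirna_id) {
  ca <- design_copies(design, sample_a, mirna_id)[[1L]]
  cb <- design_copies(design, sample_b, mirna_id)[[1L]]
  if (ca <= 0 || cb <= 0) {
    sv_stop("fold change undefined: ", mirna_id,
            " has zero copies in at least one of ", sample_a, "/", sample_b,
            class = "spikeval_undefined")
  }
  log2(ca / cb)
}
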