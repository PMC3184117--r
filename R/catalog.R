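#' Construct an assay catalog
#'
#' One row per qPCR assay on a platform: the platform-unique assay id,
#' a free-text platform label, the miRNA the assay was designed for
#' (its id; used to decide presence/absence against a spike design) and
#' the assay's target sequence (used for the homology screen).
#'
#' @param assay_id unique assay identifiers.
#' @param platform_id platform label (recycled if length 1).
#' @param target_mirna_id designed target miRNA ids; `NA` allowed for
#'   assays whose target could not be mapped.
#' @param target_sequence target nucleotide sequences.
#' @return an `assay_catalog` data.frame.
#' @export
assay_catalog <- function(assay_id, platform_id, target_mirna_id,
                          target_sequence) {
  assay_id <- as.character(assay_id)
  if (anyDuplicated(assay_id)) {
    sv_stop("duplicate assay_id: ", assay_id[duplicated(assay_id)][1L])
  }
  target_sequence <- normalize_sequence(target_sequence)
  if (any(!nzchar(target_sequence))) sv_stop("empty target_sequence")
  df <- data.frame(assay_id = assay_id,
                   platform_id = rep_len(as.character(platform_id),
                                         length(assay_id)),
                   target_mirna_id = as.character(target_mirna_id),
                   target_sequence = target_sequence,
                   stringsAsFactors = FALSE)
  structure(df, class = c("assay_catalog", "data.frame"))
}

#' Read an assay catalog from TSV
#'
#' Columns: `assay_id`, `platform_id`, `target_mirna_id`,
#' `target_sequence`.
#'
#' @param path file path.
#' @return an [assay_catalog()].
#' @export
read_assay_catalog <- function(path) {
  df <- read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("assay_id", "platform_id", "target_mirna_id", "target_sequence")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    sv_stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  }
  assay_catalog(df$assay_id, df$platform_id, df$target_mirna_id,
                df$target_sequence)
}

#' Write an assay catalog to TSV
#' @param catalog an [assay_catalog()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_assay_catalog <- function(catalog, path) {
  write.table(as.data.frame(catalog), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
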