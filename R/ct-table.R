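#' Construct a Ct table
#'
#' A Ct table is the package's long-form container for qPCR cycle
#' threshold measurements: one row per (sample, replicate, assay) well.
#' Undetected wells ("Undetermined" in instrument exports) are encoded
#' as `NA` in the `ct` column.
#'
#' @param sample_id,replicate_id,assay_id character vectors.
#' @param ct numeric vector of Ct values; `NA` means undetected.
#' @param max_cycles maximum thermocycler cycle; numeric Ct values must
#'   lie in `(0, max_cycles]`. Default 40.
#' @return a `ct_table` (a validated data.frame).
#' @export
ct_table <- function(sample_id, replicate_id, assay_id, ct,
                     max_cycles = 40) {
  df <- data.frame(sample_id = as.character(sample_id),
                   replicate_id = as.character(replicate_id),
                   assay_id = as.character(assay_id),
                   ct = as.numeric(ct), stringsAsFactors = FALSE)
  validate_ct_table(df, max_cycles = max_cycles)
}

validate_ct_table <- function(df, max_cycles = 40) {
  need <- c("sample_id", "replicate_id", "assay_id", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) sv_stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(max_cycles) || max_cycles <= 0) {
    sv_stop("max_cycles must be a positive number")
  }
  key <- paste(df$sample_id, df$replicate_id, df$assay_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    sv_stop("duplicate measurement key: (", d$sample_id, ", ",
            d$replicate_id, ", ", d$assay_id, ")")
  }
  bad <- which(!is.na(df$ct) & (df$ct <= 0 | df$ct > max_cycles))
  if (length(bad)) {
    sv_stop("Ct out of (0, ", max_cycles, "] at row ", bad[1L],
            " (value ", df$ct[bad[1L]], ")")
  }
  rownames(df) <- NULL
  structure(df[need], max_cycles = max_cycles,
            class = c("ct_table", "data.frame"))
}

#' Read a Ct table from TSV
#'
#' Expects a tab-separated file with header columns `sample_id`,
#' `replicate_id`, `assay_id`, `ct`. The `ct` column holds decimal Ct
#' values; the tokens `Undetermined`, `NA` and the empty string all map
#' to the undetected sentinel (instrument exports differ in which token
#' they emit).
#'
#' @param path file path.
#' @param max_cycles maximum admissible Ct (default 40); values outside
#'   `(0, max_cycles]` are a hard error, not clamped.
#' @return a [ct_table()].
#' @export
read_ct_table <- function(path, max_cycles = 40) {
  df <- read.delim(path, colClasses = "character", check.names = FALSE,
                   na.strings = character(0))
  need <- c("sample_id", "replicate_id", "assay_id", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    sv_stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  }
  raw <- trimws(df$ct)
  undet <- raw %in% c("Undetermined", "NA", "")
  ct <- suppressWarnings(as.numeric(raw))
  bad <- which(!undet & is.na(ct))
  if (length(bad)) {
    sv_stop("unparseable ct value at row ", bad[1L], ": '", raw[bad[1L]], "'")
  }
  ct[undet] <- NA_real_
  ct_table(df$sample_id, df$replicate_id, df$assay_id, ct,
           max_cycles = max_cycles)
}

#' Write a Ct table to TSV
#'
#' Inverse of [read_ct_table()]: undetected wells are written as the
#' token `Undetermined`.
#'
#' @param ct a `ct_table`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_ct_table <- function(ct, path) {
  df <- as.data.frame(ct)
  df$ct <- ifelse(is.na(df$ct), "Undetermined",
                  format(df$ct, trim = TRUE, digits = 15, scientific = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal: subset a ct_table, keeping class/attributes
ct_subset <- function(ct, keep) {
  structure(as.data.frame(ct)[keep, , drop = FALSE],
            max_cycles = attr(ct, "max_cycles"),
            class = c("ct_table", "data.frame"))
}

ct_samples <- function(ct) unique(ct$sample_id)
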