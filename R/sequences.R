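#' Normalize a nucleotide sequence to the internal DNA alphabet
#'
#' Sequences are stored internally in the DNA alphabet so that assay
#' target sequences and synthetic miRNA sequences compare directly:
#' letters are upper-cased and `U` is rewritten to `T`. Only the
#' characters `A`, `C`, `G`, `T`, `U`, `N` are accepted.
#'
#' @param x character vector of nucleotide sequences (5'->3').
#' @return character vector of normalized sequences.
#' @examples
#' normalize_sequence("acguACGU")  # "ACGTACGT"
#' @export
normalize_sequence <- function(x) {
  if (!is.character(x)) sv_stop("sequences must be character")
  out <- chartr("u", "t", tolower(x))
  out <- toupper(out)
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) {
    sv_stop("invalid character in sequence(s): ",
            paste(utils::head(x[bad], 3L), collapse = ", "))
  }
  out
}

# minimal FASTA reader/writer for the short panel sequences the package
# handles; records must have unique ids, description kept verbatim
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!length(lines) || !hdr[1L]) sv_stop("not a FASTA file: ", path)
  idx <- cumsum(hdr)
  heads <- sub("^>", "", lines[hdr])
  ids <- sub("\\s.*$", "", heads)
  desc <- ifelse(grepl("\\s", heads), sub("^\\S+\\s+", "", heads), "")
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) paste(gsub("\\s", "", x), collapse = ""), "")
  seqs <- as.character(seqs)
  if (anyDuplicated(ids)) {
    sv_stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  }
  data.frame(id = ids, description = desc, sequence = seqs,
             stringsAsFactors = FALSE)
}

write_fasta <- function(ids, seqs, path, desc = NULL) {
  hd <- if (is.null(desc)) ids else paste(ids, desc)
  writeLines(paste0(">", hd, "\n", seqs), path)
}
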