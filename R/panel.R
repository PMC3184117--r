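#' Construct a synthetic miRNA panel
#'
#' The panel describes the synthetic miRNA species spiked into the
#' samples: a miRBase-style identifier, the 18-25 nt sequence, and a
#' pool label (`A` or `B`). The two pools are mixed at reciprocal 4:1
#' ratios to create the pair of samples whose comparison carries a
#' known four-fold difference for every species.
#'
#' @param mirna_id character vector of unique identifiers.
#' @param sequence nucleotide sequences (RNA or DNA alphabet; stored
#'   DNA-normalized, see [normalize_sequence()]).
#' @param pool pool labels, each `"A"` or `"B"`.
#' @return a `mirna_panel` data.frame with attribute `pool_counts`.
#' @export
mirna_panel <- function(mirna_id, sequence, pool) {
  mirna_id <- as.character(mirna_id)
  pool <- as.character(pool)
  if (anyDuplicated(mirna_id)) {
    sv_stop("duplicate mirna_id: ", mirna_id[duplicated(mirna_id)][1L])
  }
  if (!all(pool %in% c("A", "B"))) sv_stop("pool labels must be 'A' or 'B'")
  sequence <- normalize_sequence(sequence)
  len <- nchar(sequence)
  if (any(len < 18L | len > 25L)) {
    sv_warn("panel sequence length outside the typical mature-miRNA ",
            "range 18-25 nt")
  }
  df <- data.frame(mirna_id = mirna_id, sequence = sequence, pool = pool,
                   stringsAsFactors = FALSE)
  structure(df, pool_counts = c(A = sum(pool == "A"), B = sum(pool == "B")),
            class = c("mirna_panel", "data.frame"))
}

#' Read a miRNA panel from FASTA
#'
#' Pool membership is taken either from a `pool=A` / `pool=B` token in
#' the FASTA description line or from an explicit `pool_map` sidecar
#' (a named vector or a data.frame with columns `mirna_id`, `pool`).
#'
#' @param path FASTA file of panel sequences.
#' @param pool_map optional pool assignment; overrides description tokens.
#' @return a [mirna_panel()].
#' @export
read_panel <- function(path, pool_map = NULL) {
  fa <- read_fasta(path)
  if (is.null(pool_map)) {
    m <- regmatches(fa$description,
                    regexpr("pool=[AB]", fa$description))
    pool <- rep(NA_character_, nrow(fa))
    hit <- grepl("pool=[AB]", fa$description)
    pool[hit] <- sub("pool=", "", m)
    if (anyNA(pool)) {
      sv_stop("no pool label for ", fa$id[which(is.na(pool))[1L]],
              "; supply pool_map or pool=A/B description tokens")
    }
  } else {
    if (is.data.frame(pool_map)) {
      pool_map <- setNames(as.character(pool_map$pool), pool_map$mirna_id)
    }
    pool <- unname(pool_map[fa$id])
    if (anyNA(pool)) {
      sv_stop("pool_map missing entry for ", fa$id[which(is.na(pool))[1L]])
    }
  }
  mirna_panel(fa$id, fa$sequence, pool)
}

#' Write a miRNA panel to FASTA (pool label in the description)
#' @param panel a [mirna_panel()].
#' @param path output FASTA path.
#' @return invisibly, `path`.
#' @export
write_panel <- function(panel, path) {
  write_fasta(panel$mirna_id, panel$sequence, path,
              desc = paste0("pool=", panel$pool))
  invisible(path)
}
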