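#' Create an edit table
#'
#' Edits are the atomic sequence changes the genotyper calls and the
#' simulator plants: insertions (`pos` = 0-based amplicon position of the
#' base to the right of the inserted sequence), deletions (`pos` =
#' 0-based start of the deleted run, `length` bases) and single-base
#' substitutions (`seq` = alternative base).
#'
#' @param kind Character vector: "insertion", "deletion" or "substitution".
#' @param pos Integer vector of 0-based amplicon positions.
#' @param seq Inserted bases / alternative base (`NA` for deletions).
#' @param length Deleted length (`NA` for other kinds; substitutions are
#'   always length 1).
#' @return Tibble with columns `kind`, `pos`, `seq`, `length`.
#' @export
edit_table <- function(kind = character(0), pos = integer(0),
                       seq = NA_character_, length = NA_integer_) {
  out <- tibble(kind = as.character(kind), pos = as.integer(pos),
                seq = as.character(seq), length = as.integer(length))
  bad <- !out$kind %in% c("insertion", "deletion", "substitution")
  if (any(bad)) abort("edit kind must be insertion, deletion or substitution")
  out$length[out$kind == "insertion"] <- nchar(out$seq[out$kind == "insertion"])
  out$length[out$kind == "substitution"] <- 1L
  out[order(out$pos), , drop = FALSE]
}

no_edits <- function() edit_table()

#' Apply an edit table to a DNA sequence
#'
#' @param sequence DNA string (amplicon coordinates of the edits).
#' @param edits An [edit_table()]; edits must not overlap.
#' @return Edited DNA string.
#' @export
apply_edits <- function(sequence, edits) {
  if (nrow(edits) == 0) return(sequence)
  len <- nchar(sequence)
  ed <- edits[order(edits$pos, decreasing = TRUE), , drop = FALSE]
  for (i in seq_len(nrow(ed))) {
    p <- ed$pos[i]
    if (p < 0 || p > len) abort("edit outside amplicon")
    sequence <- switch(ed$kind[i],
      insertion = paste0(substr(sequence, 1, p), ed$seq[i],
                         substr(sequence, p + 1, nchar(sequence))),
      deletion = {
        if (p + ed$length[i] > nchar(sequence)) abort("deletion runs off amplicon")
        paste0(substr(sequence, 1, p),
               substr(sequence, p + ed$length[i] + 1, nchar(sequence)))
      },
      substitution = {
        if (p >= nchar(sequence)) abort("substitution outside amplicon")
        paste0(substr(sequence, 1, p), ed$seq[i],
               substr(sequence, p + 2, nchar(sequence)))
      })
  }
  sequence
}

#' Left-normalize indels against a reference sequence
#'
#' Shifts each insertion/deletion to its leftmost equivalent placement
#' (VCF convention) so that edit placement in homopolymer or repeat
#' context is deterministic and region-membership tests are
#' placement-invariant. Substitutions are unchanged.
#'
#' @param edits An [edit_table()] in reference coordinates.
#' @param sequence The reference DNA string.
#' @return The normalized edit table, sorted by position.
#' @export
normalize_edits <- function(edits, sequence) {
  if (nrow(edits) == 0) return(edits)
  ref <- strsplit(sequence, "")[[1]]
  for (i in seq_len(nrow(edits))) {
    p <- edits$pos[i]
    if (edits$kind[i] == "insertion") {
      s <- strsplit(edits$seq[i], "")[[1]]
      k <- length(s)
      while (p > 0 && ref[p] == s[k]) {
        s <- c(s[k], s[-k])
        p <- p - 1L
      }
      edits$pos[i] <- p
      edits$seq[i] <- paste(s, collapse = "")
    } else if (edits$kind[i] == "deletion") {
      len <- edits$length[i]
      while (p > 0 && ref[p] == ref[p + len]) p <- p - 1L
      edits$pos[i] <- p
    }
  }
  edits[order(edits$pos), , drop = FALSE]
}

# half-open [start, end) footprint used for the editing-region test;
# an insertion's footprint covers both flanking bases
edit_footprints <- function(edits) {
  start <- ifelse(edits$kind == "insertion", edits$pos - 1L, edits$pos)
  end <- ifelse(edits$kind == "deletion", edits$pos + edits$length,
                edits$pos + 1L)
  cbind(start = pmax(start, 0L), end = end)
}

#' Format edits in compact HGVS-like genomic notation
#'
#' Insertions print as `g.<left>_<right>ins<SEQ>` (1-based flanking
#' bases), deletions as `g.<start>_<end>del`, substitutions as
#' `g.<pos><REF>>ALT`. An empty edit table prints as `"WT"`.
#'
#' @param edits An [edit_table()].
#' @param sequence Reference sequence (used for the substitution REF base).
#' @return Single string.
#' @export
format_edits <- function(edits, sequence = NULL) {
  if (nrow(edits) == 0) return("WT")
  ed <- edits[order(edits$pos), , drop = FALSE]
  lab <- vapply(seq_len(nrow(ed)), function(i) {
    p <- ed$pos[i]
    switch(ed$kind[i],
      insertion = sprintf("g.%d_%dins%s", p, p + 1, ed$seq[i]),
      deletion = if (ed$length[i] == 1) sprintf("g.%ddel", p + 1) else
        sprintf("g.%d_%ddel", p + 1, p + ed$length[i]),
      substitution = {
        ref <- if (is.null(sequence)) "N" else substr(sequence, p + 1, p + 1)
        sprintf("g.%d%s>%s", p + 1, ref, ed$seq[i])
      })
  }, character(1))
  paste(lab, collapse = ";")
}
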