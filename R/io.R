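#' Read a FASTA file into a tibble
#'
#' @param path FASTA file.
#' @param type "dna" or "aa".
#' @return Tibble with columns `id`, `sequence`.
#' @export
read_fasta <- function(path, type = c("dna", "aa")) {
  type <- match.arg(type)
  x <- if (type == "dna") {
    Biostrings::readDNAStringSet(path)
  } else {
    Biostrings::readAAStringSet(path)
  }
  tibble(id = sub("\\s.*$", "", names(x)),
         sequence = unname(as.character(x)))
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param x Tibble with `id` and `sequence` columns, or a named character
#'   vector.
#' @param path Output file.
#' @param type "dna" or "aa".
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, type = c("dna", "aa")) {
  type <- match.arg(type)
  if (is_tibble(x) || is.data.frame(x)) {
    seqs <- stats::setNames(x$sequence, x$id)
  } else {
    seqs <- x
  }
  set <- if (type == "dna") Biostrings::DNAStringSet(seqs) else Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

ANNOT_COLS <- c("seq_id", "segment_start", "segment_end", "phase")

#' Read a CDS-segment annotation sidecar
#'
#' A minimal tab-delimited annotation (one row per coding segment) with a
#' required header line `seq_id  segment_start  segment_end  phase`;
#' coordinates are 0-based half-open on the amplicon.
#'
#' @param path TSV file.
#' @return Tibble with the four annotation columns.
#' @export
read_cds_annotation <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(names(d), ANNOT_COLS)) {
    abort(sprintf("annotation header must be exactly: %s",
                  paste(ANNOT_COLS, collapse = ", ")))
  }
  as_tibble(d)
}

#' Write a CDS-segment annotation sidecar
#'
#' @param annot Tibble with columns `seq_id`, `segment_start`,
#'   `segment_end`, `phase` (or an [amplicon()], whose segments are
#'   exported).
#' @param path Output TSV file.
#' @return `path`, invisibly.
#' @export
write_cds_annotation <- function(annot, path) {
  if (inherits(annot, "amplicon")) {
    seg <- annot$cds_segments
    annot <- tibble(seq_id = annot$id,
                    segment_start = seg[, "start"],
                    segment_end = seg[, "end"],
                    phase = annot$cds_phase)
  }
  if (!all(ANNOT_COLS %in% names(annot))) {
    abort("annotation needs columns seq_id, segment_start, segment_end, phase")
  }
  utils::write.table(annot[, ANNOT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assemble an amplicon from a FASTA record and its annotation
#'
#' @param fasta_path Single-record FASTA with the amplicon sequence (or a
#'   multi-record file together with `id`).
#' @param annotation_path CDS annotation TSV ([read_cds_annotation()]).
#' @param id Record to use; defaults to the first.
#' @param cds_offset Optional transcript anchor (see [amplicon()]).
#' @return An [amplicon()].
#' @export
read_amplicon <- function(fasta_path, annotation_path = NULL, id = NULL,
                          cds_offset = NULL) {
  fa <- read_fasta(fasta_path)
  if (is.null(id)) id <- fa$id[1]
  row <- fa[fa$id == id, ]
  if (nrow(row) != 1) abort(sprintf("sequence '%s' not found in %s", id, fasta_path))
  segments <- NULL
  phase <- 0L
  if (!is.null(annotation_path)) {
    ann <- read_cds_annotation(annotation_path)
    ann <- ann[ann$seq_id == id, ]
    if (nrow(ann) > 0) {
      segments <- cbind(ann$segment_start, ann$segment_end)
      phase <- ann$phase[1]
    }
  }
  amplicon(id, row$sequence, cds_segments = segments, cds_phase = phase,
           cds_offset = cds_offset)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads Tibble with columns `read_id`, `sequence`, `quality`.
#' @param path Output FASTQ file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  s <- Biostrings::DNAStringSet(stats::setNames(reads$sequence, reads$read_id))
  q <- Biostrings::BStringSet(reads$quality)
  Biostrings::writeXStringSet(s, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ file (Phred+33).
#' @return Tibble with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(read_id = names(x), sequence = unname(as.character(x)),
         quality = unname(as.character(S4Vectors::mcols(x)$qualities)))
}
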