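#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom dplyr mutate filter arrange select bind_rows group_by summarise
#'   ungroup left_join n row_number across all_of
#' @importFrom purrr map map_chr map_int map_dbl map_lgl imap list_rbind
#' @importFrom stats setNames
#' @importFrom Rcpp evalCpp
#' @useDynLib ampliko, .registration = TRUE
NULL

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

clean_dna <- function(x, what = "sequence", allow_n = TRUE) {
  x <- toupper(x)
  if (grepl("U", x, fixed = TRUE)) {
    abort(sprintf("%s contains 'U': RNA input is not supported (DNA-only model)", what))
  }
  ok <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  if (!grepl(ok, x)) {
    chars <- strsplit(x, "")[[1]]
    bad <- which(!chars %in% c(DNA_BASES, if (allow_n) "N"))[1]
    abort(sprintf("%s contains invalid base '%s' at position %d", what, chars[bad], bad))
  }
  x
}

#' Construct an amplicon with its coding-sequence annotation
#'
#' An amplicon is the PCR product spanning a CRISPR target site. Coding
#' bases within it are described by half-open, 0-based `[start, end)`
#' segments on the amplicon plus the reading-frame phase of the first
#' coding base. When the amplicon is anchored to a transcript,
#' `cds_offset` gives the 0-based index of that first coding base within
#' the full coding sequence, which lets downstream tools splice amplicon
#' edits into the transcript for protein prediction.
#'
#' @param id Amplicon identifier.
#' @param sequence DNA string (A/C/G/T/N; lowercase accepted, U rejected).
#' @param cds_segments Two-column matrix/data frame of half-open
#'   `[start, end)` intervals (0-based) on the amplicon that lie in coding
#'   sequence, or `NULL` for a wholly non-coding amplicon.
#' @param cds_phase Integer 0-2: reading-frame offset of the first coding
#'   base of the first segment (0 = first base of a codon).
#' @param cds_offset Optional 0-based coding-sequence index of the first
#'   coding base, anchoring the amplicon to a transcript. Must satisfy
#'   `cds_offset %% 3 == cds_phase`.
#' @return An object of class `"amplicon"`.
#' @export
amplicon <- function(id, sequence, cds_segments = NULL, cds_phase = 0L,
                     cds_offset = NULL) {
  sequence <- clean_dna(sequence, sprintf("amplicon '%s'", id))
  len <- nchar(sequence)
  cds_phase <- as.integer(cds_phase)
  if (!cds_phase %in% 0:2) abort("cds_phase must be 0, 1 or 2")
  if (!is.null(cds_segments)) {
    seg <- as.matrix(cds_segments)
    if (ncol(seg) != 2) abort("cds_segments needs two columns (start, end)")
    storage.mode(seg) <- "integer"
    colnames(seg) <- c("start", "end")
    if (any(seg[, "start"] >= seg[, "end"])) abort("empty or inverted cds segment")
    if (any(seg[, "start"] < 0) || any(seg[, "end"] > len)) {
      abort("cds segment outside amplicon")
    }
    if (nrow(seg) > 1) {
      o <- order(seg[, "start"])
      seg <- seg[o, , drop = FALSE]
      if (any(seg[-1, "start"] < seg[-nrow(seg), "end"])) {
        abort("cds segments overlap")
      }
    }
  } else {
    seg <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
  }
  if (!is.null(cds_offset)) {
    cds_offset <- as.integer(cds_offset)
    if (cds_offset < 0) abort("cds_offset must be >= 0")
    if (cds_offset %% 3L != cds_phase) {
      abort("cds_offset %% 3 must equal cds_phase")
    }
  }
  structure(
    list(id = id, sequence = sequence, cds_segments = seg,
         cds_phase = cds_phase, cds_offset = cds_offset),
    class = "amplicon"
  )
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("<amplicon '%s'> %d bp, %d coding segment(s), phase %d\n",
              x$id, nchar(x$sequence), nrow(x$cds_segments), x$cds_phase))
  invisible(x)
}

#' Construct a guide RNA placed on an amplicon
#'
#' `start` is the 0-based amplicon (+ strand) coordinate of the
#' protospacer's 5' base: for a "+" guide the protospacer occupies
#' `[start, start + 20)`; for a "-" guide it occupies
#' `[start - 19, start + 1)` read on the minus strand. The blunt cut
#' falls `cut_offset` bases 5' of the PAM (default 3, i.e. between
#' protospacer positions 17 and 18). `be_window` gives the 1-based
#' protospacer positions a cytosine base editor can deaminate
#' (default 4-8, PAM-distal).
#'
#' @param protospacer 20-nt DNA string (spacer sequence, protospacer strand).
#' @param pam PAM sequence observed on the amplicon (e.g. "AGG").
#' @param strand "+" or "-" relative to the amplicon.
#' @param start 0-based amplicon offset of the protospacer 5' end.
#' @param cut_offset Bases from the protospacer 3' end to the blunt cut.
#' @param be_window Length-2 integer vector, inclusive 1-based protospacer
#'   positions editable by a cytosine base editor.
#' @param amplicon Optional [amplicon()] to validate placement against
#'   (protospacer must match; PAM must match `pam_pattern`).
#' @param pam_pattern IUPAC PAM pattern used for validation ("NGG").
#' @return An object of class `"guide_rna"`.
#' @export
guide_rna <- function(protospacer, pam, strand = c("+", "-"), start,
                      cut_offset = 3L, be_window = c(4L, 8L),
                      amplicon = NULL, pam_pattern = "NGG") {
  strand <- match.arg(strand)
  protospacer <- clean_dna(protospacer, "protospacer", allow_n = FALSE)
  pam <- clean_dna(pam, "pam")
  if (nchar(protospacer) != 20) abort("protospacer must be 20 nt")
  if (nchar(pam) != nchar(pam_pattern)) abort("pam length must match pam_pattern")
  be_window <- as.integer(be_window)
  if (length(be_window) != 2 || be_window[1] > be_window[2] ||
      be_window[1] < 1 || be_window[2] > 20) {
    abort("be_window must be increasing 1-based protospacer positions in 1..20")
  }
  g <- structure(
    list(protospacer = protospacer, pam = pam, strand = strand,
         start = as.integer(start), cut_offset = as.integer(cut_offset),
         be_window = be_window),
    class = "guide_rna"
  )
  if (!is.null(amplicon)) {
    obs <- guide_observed(g, amplicon)
    if (obs$protospacer != protospacer) {
      abort("protospacer does not match the amplicon at its placement")
    }
    if (!pam_matches(obs$pam, pam_pattern)) {
      abort(sprintf("PAM '%s' at placement does not match pattern '%s'",
                    obs$pam, pam_pattern))
    }
  }
  g
}

#' @export
print.guide_rna <- function(x, ...) {
  cat(sprintf("<guide_rna> %s PAM %s (%s) start %d, cut offset %d, window %d-%d\n",
              x$protospacer, x$pam, x$strand, x$start, x$cut_offset,
              x$be_window[1], x$be_window[2]))
  invisible(x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

pam_matches <- function(pam, pattern) {
  if (nchar(pam) != nchar(pattern)) return(FALSE)
  p <- strsplit(pattern, "")[[1]]
  b <- strsplit(pam, "")[[1]]
  # N in the pattern matches any real base; N in the sequence never matches
  all(ifelse(p == "N", b %in% DNA_BASES, b == p))
}

# protospacer/PAM as read off the amplicon at the guide placement
guide_observed <- function(guide, amplicon) {
  seq <- amplicon$sequence
  len <- nchar(seq)
  if (guide$strand == "+") {
    if (guide$start < 0 || guide$start + 23 > len) abort("guide placement outside amplicon")
    list(protospacer = substr(seq, guide$start + 1, guide$start + 20),
         pam = substr(seq, guide$start + 21, guide$start + 23))
  } else {
    np <- nchar(guide$pam)
    if (guide$start - 19 - np < 0 || guide$start >= len) {
      abort("guide placement outside amplicon")
    }
    # minus-strand protospacer occupies [start - 19, start]; PAM lies 3'
    # of it on the minus strand, i.e. [start - 19 - np, start - 20] on +
    list(protospacer = revcomp(substr(seq, guide$start - 18, guide$start + 1)),
         pam = revcomp(substr(seq, guide$start - 19 - np + 1, guide$start - 19)))
  }
}

#' Cut-site boundary of a nuclease guide
#'
#' Returns the 0-based amplicon boundary index `b` of the blunt cut: the
#' cut falls between amplicon bases `b - 1` and `b`.
#'
#' @param guide A [guide_rna()].
#' @return Integer boundary index.
#' @export
guide_cut_site <- function(guide) {
  k <- 20L - guide$cut_offset
  if (guide$strand == "+") guide$start + k else guide$start - k + 1L
}

#' Base-editing window of a guide in amplicon coordinates
#'
#' @param guide A [guide_rna()].
#' @return Half-open `[start, end)` 0-based amplicon interval covered by
#'   the guide's `be_window`.
#' @export
guide_window_interval <- function(guide) {
  w <- guide$be_window
  if (guide$strand == "+") {
    c(guide$start + w[1] - 1L, guide$start + w[2])
  } else {
    c(guide$start - w[2] + 1L, guide$start - w[1] + 2L)
  }
}

#' Default CRISPR editing region of a guide
#'
#' The interval of the amplicon within which called edits are believed to
#' be CRISPR-induced. For the nuclease scheme this is the cut site plus or
#' minus `halfwidth` bases (NHEJ indels spread around the blunt cut); for
#' the base-editor scheme it is the deamination window padded by `pad`
#' bases on each side.
#'
#' @param guide A [guide_rna()].
#' @param scheme "nuclease" or "base_editor".
#' @param halfwidth Half-width (bases) around the cut boundary (nuclease).
#' @param pad Padding (bases) around the editing window (base editor).
#' @return Half-open `[start, end)` 0-based amplicon interval.
#' @export
editing_region <- function(guide, scheme = c("nuclease", "base_editor"),
                           halfwidth = 10L, pad = 2L) {
  scheme <- match.arg(scheme)
  if (scheme == "nuclease") {
    b <- guide_cut_site(guide)
    c(b - as.integer(halfwidth), b + as.integer(halfwidth))
  } else {
    w <- guide_window_interval(guide)
    c(w[1] - as.integer(pad), w[2] + as.integer(pad))
  }
}

#' Construct a transcript model
#'
#' @param id Transcript identifier.
#' @param cds Coding DNA sequence: starts with ATG, length divisible by 3,
#'   ends with a stop codon, no internal stop.
#' @param isoform_ids Optional character vector of isoform labels.
#' @return Object of class `"transcript_model"` with the derived protein.
#' @export
transcript_model <- function(id, cds, isoform_ids = NULL) {
  cds <- clean_dna(cds, sprintf("cds '%s'", id), allow_n = FALSE)
  if (nchar(cds) %% 3 != 0) abort("cds length must be divisible by 3")
  if (substr(cds, 1, 3) != "ATG") abort("cds must start with ATG")
  aa_full <- translate_cds(cds, until_stop = FALSE)
  n <- nchar(aa_full)
  if (substr(aa_full, n, n) != "*") abort("cds must end with a stop codon")
  body <- substr(aa_full, 1, n - 1)
  if (grepl("*", body, fixed = TRUE)) abort("cds contains an internal stop codon")
  structure(
    list(id = id, cds = cds, protein = body,
         isoform_ids = isoform_ids %||% character(0)),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model '%s'> %d nt CDS, %d aa protein\n",
              x$id, nchar(x$cds), nchar(x$protein)))
  invisible(x)
}

#' Translate a coding DNA sequence (standard genetic code)
#'
#' @param cds DNA string, A/C/G/T only, length at least 3. A trailing
#'   partial codon is an error.
#' @param until_stop If `TRUE` (default) return residues up to but
#'   excluding the first stop; otherwise the full-length translation with
#'   stops marked `*`.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds, until_stop = TRUE) {
  cds <- clean_dna(cds, "cds", allow_n = FALSE)
  if (nchar(cds) < 3) abort("cds shorter than one codon")
  if (nchar(cds) %% 3 != 0) abort("cds length is not a multiple of 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           no.init.codon = TRUE))
  if (until_stop) sub("\\*.*$", "", aa) else aa
}

n_coding_before <- function(amp, pos) {
  # number of coding bases of the amplicon strictly before position pos
  seg <- amp$cds_segments
  if (nrow(seg) == 0) return(0L)
  sum(pmax(0L, pmin(pos, seg[, "end"]) - seg[, "start"]))
}

in_cds <- function(amp, pos) {
  seg <- amp$cds_segments
  any(pos >= seg[, "start"] & pos < seg[, "end"])
}

cds_anchor <- function(amp) {
  if (!is.null(amp$cds_offset)) amp$cds_offset else as.integer(amp$cds_phase)
}

#' Map an amplicon position to its coding-sequence index
#'
#' Honors segment order and reading-frame phase: the returned index modulo
#' 3 is the position of the base within its codon. When the amplicon
#' carries a `cds_offset` anchor the index is the absolute 0-based index
#' within the transcript CDS; otherwise indices start at the phase value.
#' Non-coding positions map to `NA`.
#'
#' @param amp An [amplicon()].
#' @param pos Integer vector of 0-based amplicon positions.
#' @return Integer vector of 0-based CDS indices (`NA` = non-coding).
#' @export
amplicon_to_cds <- function(amp, pos) {
  len <- nchar(amp$sequence)
  if (any(pos < 0 | pos >= len)) abort("position outside amplicon")
  anchor <- cds_anchor(amp)
  vapply(as.integer(pos), function(p) {
    if (!in_cds(amp, p)) return(NA_integer_)
    anchor + n_coding_before(amp, p)
  }, integer(1))
}

#' Map a coding-sequence index back to its amplicon position
#'
#' Inverse of [amplicon_to_cds()] for indices covered by the amplicon.
#'
#' @param amp An [amplicon()].
#' @param idx Integer vector of 0-based CDS indices.
#' @return Integer vector of 0-based amplicon positions (`NA` when the
#'   index is not covered by this amplicon).
#' @export
cds_to_amplicon <- function(amp, idx) {
  anchor <- cds_anchor(amp)
  seg <- amp$cds_segments
  vapply(as.integer(idx), function(i) {
    k <- i - anchor  # coding bases before the target position
    if (k < 0) return(NA_integer_)
    for (s in seq_len(nrow(seg))) {
      w <- seg[s, "end"] - seg[s, "start"]
      if (k < w) return(seg[s, "start"] + k)
      k <- k - w
    }
    NA_integer_
  }, integer(1))
}

#' Find all placements of a protospacer on an amplicon
#'
#' Scans both strands for exact protospacer matches with a PAM
#' immediately 3'. `N` in the PAM pattern matches any base; `N` in the
#' amplicon never matches.
#'
#' @param amp An [amplicon()].
#' @param protospacer 20-nt DNA string.
#' @param pam_pattern IUPAC PAM pattern (default "NGG").
#' @return Tibble with columns `strand`, `start` (0-based offset of the
#'   protospacer 5' end, + strand coordinates), `protospacer`, `pam`.
#'   Zero rows when the guide has no placement.
#' @export
place_guide <- function(amp, protospacer, pam_pattern = "NGG") {
  protospacer <- clean_dna(protospacer, "protospacer", allow_n = FALSE)
  if (nchar(protospacer) != 20) abort("protospacer must be 20 nt")
  seq <- amp$sequence
  np <- nchar(pam_pattern)
  pat_fwd <- paste0(protospacer, pam_pattern)
  pat_rev <- revcomp(pat_fwd)
  subject <- Biostrings::DNAString(seq)
  hit_starts <- function(pattern) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subject,
                                  fixed = c(pattern = FALSE, subject = TRUE))
    Biostrings::start(m) - 1L  # 0-based
  }
  no_n <- function(s0, width) {
    !grepl("N", substr(seq, s0 + 1, s0 + width), fixed = TRUE)
  }
  fwd <- hit_starts(pat_fwd)
  fwd <- fwd[vapply(fwd, no_n, logical(1), width = 20L + np)]
  rev <- hit_starts(pat_rev)
  rev <- rev[vapply(rev, no_n, logical(1), width = 20L + np)]
  out <- bind_rows(
    tibble(strand = rep("+", length(fwd)), start = as.integer(fwd)),
    tibble(strand = rep("-", length(rev)),
           start = as.integer(rev) + 20L + np - 1L)
  )
  if (nrow(out) == 0) {
    return(tibble(strand = character(0), start = integer(0),
                  protospacer = character(0), pam = character(0)))
  }
  out$protospacer <- protospacer
  out$pam <- vapply(seq_len(nrow(out)), function(i) {
    if (out$strand[i] == "+") {
      substr(seq, out$start[i] + 21, out$start[i] + 20 + np)
    } else {
      revcomp(substr(seq, out$start[i] - 19 - np + 1, out$start[i] - 19))
    }
  }, character(1))
  arrange(out, .data$start, .data$strand)
}
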