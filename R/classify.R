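ALLELE_CLASSES <- c("WT", "IF", "KO_frameshift", "KO_stop")

# map a WT amplicon coordinate (or boundary) to the edited sequence
shift_coordinate <- function(x, edits) {
  d <- 0L
  for (i in seq_len(nrow(edits))) {
    p <- edits$pos[i]
    if (edits$kind[i] == "insertion" && p <= x) {
      d <- d + nchar(edits$seq[i])
    } else if (edits$kind[i] == "deletion") {
      len <- edits$length[i]
      if (p + len <= x) d <- d - len
      else if (p < x) d <- d - (x - p)
    }
  }
  x + d
}

# coding footprint of each edit: insertions count only when strictly
# between two coding bases; deletions count their overlap with segments
coding_deltas <- function(edits, amp) {
  seg <- amp$cds_segments
  vapply(seq_len(nrow(edits)), function(i) {
    p <- edits$pos[i]
    switch(edits$kind[i],
      insertion = {
        inside <- any(p > seg[, "start"] & p < seg[, "end"])
        if (inside) nchar(edits$seq[i]) else 0L
      },
      deletion = {
        -sum(pmax(0L, pmin(seg[, "end"], p + edits$length[i]) -
                    pmax(seg[, "start"], p)))
      },
      substitution = 0L)
  }, integer(1))
}

edit_touches_cds <- function(edits, amp) {
  seg <- amp$cds_segments
  if (nrow(seg) == 0) return(rep(FALSE, nrow(edits)))
  fp <- edit_footprints(edits)
  vapply(seq_len(nrow(edits)), function(i) {
    if (edits$kind[i] == "insertion") {
      any(edits$pos[i] > seg[, "start"] & edits$pos[i] < seg[, "end"])
    } else {
      any(fp[i, "start"] < seg[, "end"] & fp[i, "end"] > seg[, "start"])
    }
  }, logical(1))
}

# coding bases of an edited amplicon, with segment boundaries mapped
# through the edits
edited_local_cds <- function(edits, amp) {
  mut <- apply_edits(amp$sequence, edits)
  seg <- amp$cds_segments
  parts <- vapply(seq_len(nrow(seg)), function(s) {
    a <- shift_coordinate(seg[s, "start"], edits)
    b <- shift_coordinate(seg[s, "end"], edits)
    substr(mut, a + 1, b)
  }, character(1))
  paste(parts, collapse = "")
}

wt_local_cds <- function(amp) {
  seg <- amp$cds_segments
  parts <- vapply(seq_len(nrow(seg)), function(s) {
    substr(amp$sequence, seg[s, "start"] + 1, seg[s, "end"])
  }, character(1))
  paste(parts, collapse = "")
}

# splice the (possibly edited) amplicon coding bases into the full
# transcript CDS; requires a cds_offset anchor
splice_mutant_cds <- function(edits, amp, transcript) {
  if (is.null(amp$cds_offset)) {
    abort("amplicon must carry a cds_offset anchor to splice into a transcript")
  }
  wt_local <- wt_local_cds(amp)
  lo <- amp$cds_offset
  hi <- lo + nchar(wt_local)
  if (substr(transcript$cds, lo + 1, hi) != wt_local) {
    abort("amplicon coding bases do not match the transcript at cds_offset")
  }
  paste0(substr(transcript$cds, 1, lo), edited_local_cds(edits, amp),
         substr(transcript$cds, hi + 1, nchar(transcript$cds)))
}

# first in-frame stop of a (possibly frameshifted) local coding sequence;
# returns the 0-based codon index in anchor coordinates, or NA
first_local_stop <- function(local_cds, anchor) {
  lead <- (3L - anchor %% 3L) %% 3L  # bases before the first complete codon
  body <- substr(local_cds, lead + 1, nchar(local_cds))
  usable <- nchar(body) - nchar(body) %% 3L
  if (usable < 3) return(NA_integer_)
  aa <- translate_cds(substr(body, 1, usable), until_stop = FALSE)
  hit <- regexpr("*", aa, fixed = TRUE)
  if (hit < 0) return(NA_integer_)
  (anchor + lead) %/% 3L + (as.integer(hit) - 1L)
}

#' Classify an allele by its reading-frame consequence
#'
#' Applies the frame rule: the net coding indel length decides between
#' frameshift knockout (`KO_frameshift`, net not a multiple of three) and
#' an in-frame change; in-frame alleles are further scanned for a novel
#' premature stop codon (`KO_stop`, covering both base-editor C-to-T stop
#' conversions and in-frame indels that insert a stop), otherwise they
#' are `IF`. Alleles with no edit touching coding sequence are `WT`
#' (with a note when non-coding edits are present).
#'
#' @param edits An [edit_table()] in amplicon coordinates.
#' @param amp An [amplicon()] with CDS segments.
#' @param transcript Optional [transcript_model()] (with an anchored
#'   amplicon) for transcript-wide stop detection; otherwise the scan is
#'   local to the amplicon's coding bases.
#' @return One-row tibble: `class`, `net_coding_delta`,
#'   `first_novel_stop` (0-based codon index or `NA`), `note`.
#' @export
classify_allele <- function(edits, amp, transcript = NULL) {
  if (nrow(amp$cds_segments) == 0) abort("amplicon has no coding segments")
  out <- function(class, delta, stop_idx = NA_integer_, note = NA_character_) {
    tibble(class = class, net_coding_delta = as.integer(delta),
           first_novel_stop = as.integer(stop_idx), note = note)
  }
  if (nrow(edits) == 0) return(out("WT", 0L))
  touches <- edit_touches_cds(edits, amp)
  if (!any(touches)) return(out("WT", 0L, note = "non-coding edit"))
  note <- NA_character_
  fp <- edit_footprints(edits)
  seg <- amp$cds_segments
  partial <- vapply(which(touches), function(i) {
    edits$kind[i] == "deletion" &&
      !any(fp[i, "start"] >= seg[, "start"] & fp[i, "end"] <= seg[, "end"])
  }, logical(1))
  if (any(partial)) {
    warn("allele spans a CDS segment boundary partially; classified from its coding footprint only")
    note <- "partial CDS overlap"
  }
  delta <- sum(coding_deltas(edits, amp))
  stop_idx <- if (!is.null(transcript) && !is.null(amp$cds_offset)) {
    mut <- splice_mutant_cds(edits, amp, transcript)
    first_local_stop(mut, 0L)
  } else {
    first_local_stop(edited_local_cds(edits, amp), cds_anchor(amp))
  }
  if (delta %% 3L != 0L) {
    return(out("KO_frameshift", delta, stop_idx, note))
  }
  # for an in-frame allele the natural terminal stop itself shifts by
  # delta/3 codons; only a stop upstream of that shifted position is novel
  wt_stop <- if (!is.null(transcript)) {
    nchar(transcript$protein) + delta %/% 3L
  } else NA_integer_
  novel <- !is.na(stop_idx) && (is.na(wt_stop) || stop_idx < wt_stop)
  if (novel) out("KO_stop", delta, stop_idx, note) else out("IF", delta, NA, note)
}

#' Call an embryo genotype from its allele classes
#'
#' Nuclease scheme: `WT` when no allele is edited; `IF` when at least one
#' allele is edited and at least one allele (edited or not) conserves the
#' open reading frame; `KO` when every allele is knockout class.
#' Base-editor scheme: `WT` / `Hz` (mixture of functional and stop
#' alleles) / `KO` (only stop alleles); the base-editor scheme never
#' emits `IF` and the nuclease scheme never emits `Hz`. An empty class
#' list yields `"no-call"`.
#'
#' @param classes Character vector of allele classes
#'   (`WT`/`IF`/`KO_frameshift`/`KO_stop`).
#' @param scheme "nuclease" or "base_editor".
#' @return Single genotype string: WT, IF, Hz, KO or no-call.
#' @export
call_embryo <- function(classes, scheme = c("nuclease", "base_editor")) {
  scheme <- match.arg(scheme)
  if (length(classes) == 0) return("no-call")
  bad <- setdiff(classes, ALLELE_CLASSES)
  if (length(bad) > 0) abort(sprintf("unknown allele class '%s'", bad[1]))
  ko <- classes %in% c("KO_frameshift", "KO_stop")
  edited <- classes != "WT"
  if (!any(edited)) return("WT")
  if (scheme == "nuclease") {
    if (all(ko)) "KO" else "IF"
  } else {
    if (any(classes == "IF")) {
      warn("ORF-conserving edited allele under the base-editor scheme; treated as functional")
    }
    if (all(ko)) "KO" else if (any(ko)) "Hz" else "WT"
  }
}

aa_identity_matrix <- function() {
  letters <- c(Biostrings::AA_STANDARD, "X", "*")
  m <- matrix(-1, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 1
  m
}

aa_global_identities <- function(a, b) {
  if (nchar(a) == 0 || nchar(b) == 0) return(0L)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = aa_identity_matrix(),
    gapOpening = 4, gapExtension = 0.5, type = "global")
  Biostrings::nmatch(pa)
}

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- strsplit(substr(a, 1, n), "")[[1]]
  bv <- strsplit(substr(b, 1, n), "")[[1]]
  d <- which(av != bv)
  if (length(d) == 0) n else d[1] - 1L
}

#' Predict the mutant protein and its per-isoform impact
#'
#' Applies the allele's edits to the transcript CDS (via the amplicon
#' anchor), translates in the wild-type frame until the first stop, and
#' reports, against each isoform: the identical N-terminal prefix, the
#' global-alignment percent identity (identities divided by the isoform's
#' wild-type length), and the truncation fraction (mutant residues
#' attributable to the isoform divided by its length). Isoforms with an
#' alternative downstream start are compared over their own residue
#' range. An edit destroying the start codon yields an empty mutant
#' protein flagged `start_lost`.
#'
#' @param edits An [edit_table()].
#' @param amp Anchored [amplicon()].
#' @param transcript A [transcript_model()].
#' @param isoforms Optional isoform tibble (`isoform_id`, `start_codon`,
#'   `length_aa`, `protein`), e.g. from [synthetic_target()]; defaults to
#'   the transcript's own protein as a single isoform.
#' @param epitope Optional 1-based inclusive residue interval
#'   (length-2 integer) of an antibody immunogen on the canonical
#'   protein; adds an `epitope_status` column.
#' @return Tibble of class `"protein_impact"`, one row per isoform:
#'   `isoform_id`, `mutant_len`, `identical_prefix_aa`, `pct_identity`,
#'   `truncation_fraction`, `start_lost`, optionally `epitope_status`;
#'   the mutant protein string is attached as attribute
#'   `mutant_protein`.
#' @export
predict_protein <- function(edits, amp, transcript, isoforms = NULL,
                            epitope = NULL) {
  mut_cds <- splice_mutant_cds(edits, amp, transcript)
  # a frameshifted CDS ends in a partial codon; translate whole codons only
  usable <- nchar(mut_cds) - nchar(mut_cds) %% 3L
  start_lost <- substr(mut_cds, 1, 3) != "ATG"
  mutant <- if (start_lost) "" else {
    translate_cds(substr(mut_cds, 1, usable), until_stop = TRUE)
  }
  if (is.null(isoforms)) {
    isoforms <- tibble(isoform_id = transcript$id, start_codon = 0L,
                       length_aa = nchar(transcript$protein),
                       protein = transcript$protein)
  }
  rows <- list_rbind(map(seq_len(nrow(isoforms)), function(i) {
    s <- isoforms$start_codon[i]
    iso <- isoforms$protein[i]
    mut_seg <- if (nchar(mutant) > s) substr(mutant, s + 1, nchar(mutant)) else ""
    tibble(
      isoform_id = isoforms$isoform_id[i],
      mutant_len = nchar(mutant),
      identical_prefix_aa = common_prefix_len(mut_seg, iso),
      pct_identity = 100 * aa_global_identities(mut_seg, iso) /
        isoforms$length_aa[i],
      truncation_fraction = max(0L, nchar(mutant) - s) / isoforms$length_aa[i],
      start_lost = start_lost
    )
  }))
  if (!is.null(epitope)) {
    rows$epitope_status <- epitope_retention(mutant, transcript$protein, epitope)
  }
  attr(rows, "mutant_protein") <- mutant
  class(rows) <- c("protein_impact", class(rows))
  rows
}

#' Epitope retention of a mutant protein
#'
#' Position-wise comparison of the mutant against the wild-type protein
#' over a 1-based inclusive residue interval (e.g. an antibody immunogen
#' region): `"full"` when every interval residue is identical,
#' `"partial"` when some are, `"none"` when none is.
#'
#' @param mutant Mutant amino-acid string (wild-type frame coordinates).
#' @param wt Wild-type amino-acid string.
#' @param interval Length-2 integer vector, 1-based inclusive residues.
#' @return `"full"`, `"partial"` or `"none"`.
#' @export
epitope_retention <- function(mutant, wt, interval) {
  lo <- as.integer(interval[1])
  hi <- as.integer(interval[2])
  if (lo < 1 || hi > nchar(wt) || lo > hi) {
    abort("epitope interval must lie within the wild-type protein")
  }
  same <- vapply(lo:hi, function(i) {
    i <= nchar(mutant) && substr(mutant, i, i) == substr(wt, i, i)
  }, logical(1))
  if (all(same)) "full" else if (any(same)) "partial" else "none"
}
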