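enumerate_placements <- function(seq, pam_pattern = "NGG") {
  len <- nchar(seq)
  np <- nchar(pam_pattern)
  w <- 20L + np
  if (len < w) return(tibble(strand = character(0), start = integer(0)))
  starts <- 0:(len - w)
  fwd_ok <- vapply(starts, function(s) {
    pam_matches(substr(seq, s + 21, s + 20 + np), pam_pattern) &&
      !grepl("N", substr(seq, s + 1, s + 20), fixed = TRUE)
  }, logical(1))
  rev_pat <- revcomp(paste0(strrep("A", 20), pam_pattern))
  rev_pam <- substr(rev_pat, 1, np)  # PAM pattern as seen on the + strand
  rev_ok <- vapply(starts, function(s) {
    pam_matches(substr(seq, s + 1, s + np), rev_pam) &&
      !grepl("N", substr(seq, s + np + 1, s + w), fixed = TRUE)
  }, logical(1))
  bind_rows(
    tibble(strand = "+", start = starts[fwd_ok]),
    tibble(strand = "-", start = starts[rev_ok] + w - 1L)
  )
}

window_cytosines <- function(seq, strand, start, be_window) {
  w1 <- be_window[1]
  w2 <- be_window[2]
  if (strand == "+") {
    pos <- (start + w1 - 1L):(start + w2 - 1L)
    pos[substring(seq, pos + 1, pos + 1) == "C"]
  } else {
    pos <- (start - w2 + 1L):(start - w1 + 1L)
    pos[substring(seq, pos + 1, pos + 1) == "G"]  # C on the minus strand
  }
}

codon_change <- function(amp, pos, all_edits) {
  idx <- amplicon_to_cds(amp, pos)
  if (is.na(idx)) return(list(codon = NA_integer_, consequence = "non_coding"))
  codon <- idx %/% 3L
  cod_pos <- cds_to_amplicon(amp, (codon * 3L):(codon * 3L + 2L))
  if (anyNA(cod_pos)) return(list(codon = codon, consequence = "edge"))
  wt <- paste(substring(amp$sequence, cod_pos + 1, cod_pos + 1), collapse = "")
  bases <- substring(amp$sequence, cod_pos + 1, cod_pos + 1)
  for (i in seq_len(nrow(all_edits))) {
    hit <- which(cod_pos == all_edits$pos[i])
    if (length(hit) == 1) bases[hit] <- all_edits$seq[i]
  }
  mut <- paste(bases, collapse = "")
  cons <- if (mut == wt) "silent" else {
    aw <- translate_cds(wt, until_stop = FALSE)
    am <- translate_cds(mut, until_stop = FALSE)
    if (am == "*") "nonsense" else if (am == aw) "silent" else "missense"
  }
  list(codon = codon, consequence = cons)
}

#' Find cytosine-base-editor guides that install premature stop codons
#'
#' Enumerates every 20-mer protospacer on both strands of the amplicon
#' with a matching PAM, converts the editing-window cytosines of the
#' protospacer strand to thymine (all of them simultaneously by default -
#' the worst-case bystander model; `mode = "single_c"` instead tries each
#' window cytosine alone), and reports a candidate whenever the edited
#' coding sequence gains an in-frame premature stop. Sense-strand edits
#' can convert CAA/CAG/CGA into stops; antisense-strand edits (G-to-A on
#' the coding strand) can convert TGG. Candidates whose novel stop
#' coincides with the natural stop or falls in the final sense codon are
#' discarded (no truncation).
#'
#' @param amp An [amplicon()] covering the coding model (with enough
#'   flanking context that PAMs near the CDS ends are findable).
#' @param transcript Optional [transcript_model()] anchor for
#'   transcript-wide stop detection and the natural-stop guard.
#' @param pam_pattern IUPAC PAM pattern (default "NGG").
#' @param be_window Editing window, 1-based protospacer positions.
#' @param mode `"all_c"` (default) or `"single_c"`.
#' @return Tibble of candidates: `protospacer`, `pam`, `strand`, `start`,
#'   `edited_strand` ("sense"/"antisense"), `n_window_c`,
#'   `window_positions`, `target_codon` (0-based codon index of the novel
#'   stop), `original_codon`, `converted_codon`, `bystanders`, and an
#'   `edits` list-column with the planted C-to-T substitutions.
#' @export
find_stop_guides <- function(amp, transcript = NULL, pam_pattern = "NGG",
                             be_window = c(4L, 8L), mode = c("all_c", "single_c")) {
  mode <- match.arg(mode)
  seq <- amp$sequence
  pl <- enumerate_placements(seq, pam_pattern)
  wt_stop <- if (!is.null(transcript)) nchar(transcript$protein) else NA_integer_
  rows <- list()
  for (i in seq_len(nrow(pl))) {
    strand <- pl$strand[i]
    start <- pl$start[i]
    cs <- window_cytosines(seq, strand, start, be_window)
    if (length(cs) == 0) next
    edit_sets <- if (mode == "all_c") list(cs) else as.list(cs)
    alt <- if (strand == "+") "T" else "A"
    for (set in edit_sets) {
      ed <- edit_table(kind = rep("substitution", length(set)), pos = set,
                       seq = alt)
      stop_idx <- if (!is.null(transcript) && !is.null(amp$cds_offset)) {
        first_local_stop(splice_mutant_cds(ed, amp, transcript), 0L)
      } else {
        first_local_stop(edited_local_cds(ed, amp), cds_anchor(amp))
      }
      if (is.na(stop_idx)) next
      if (!is.na(wt_stop) && stop_idx >= wt_stop - 1L) next  # no truncation
      cod_pos <- cds_to_amplicon(amp, (stop_idx * 3L):(stop_idx * 3L + 2L))
      if (anyNA(cod_pos)) next
      orig <- paste(substring(seq, cod_pos + 1, cod_pos + 1), collapse = "")
      conv <- paste(
        ifelse(cod_pos %in% set, alt, substring(seq, cod_pos + 1, cod_pos + 1)),
        collapse = "")
      if (!conv %in% STOP_CODONS) next  # stop arose outside the window edits
      byst <- setdiff(set, cod_pos)
      byst_lab <- if (length(byst) == 0) "" else {
        paste(vapply(byst, function(p) {
          cc <- codon_change(amp, p, ed)
          sprintf("%d:%s", p, cc$consequence)
        }, character(1)), collapse = ";")
      }
      g <- if (strand == "+") {
        list(proto = substr(seq, start + 1, start + 20),
             pam = substr(seq, start + 21, start + 20 + nchar(pam_pattern)))
      } else {
        np <- nchar(pam_pattern)
        list(proto = revcomp(substr(seq, start - 18, start + 1)),
             pam = revcomp(substr(seq, start - 19 - np + 1, start - 19)))
      }
      rows[[length(rows) + 1L]] <- tibble(
        protospacer = g$proto, pam = g$pam, strand = strand, start = start,
        edited_strand = if (strand == "+") "sense" else "antisense",
        n_window_c = length(set),
        window_positions = paste(set, collapse = ","),
        target_codon = stop_idx, original_codon = orig,
        converted_codon = conv, bystanders = byst_lab, edits = list(ed))
    }
  }
  if (length(rows) == 0) {
    return(tibble(protospacer = character(0), pam = character(0),
                  strand = character(0), start = integer(0),
                  edited_strand = character(0), n_window_c = integer(0),
                  window_positions = character(0), target_codon = integer(0),
                  original_codon = character(0), converted_codon = character(0),
                  bystanders = character(0), edits = list()))
  }
  arrange(list_rbind(rows), .data$start, .data$strand)
}

#' Rank stop-guide candidates by truncation severity across isoforms
#'
#' Attaches per-isoform truncation metrics (truncated length and fraction
#' of the isoform truncated protein retains) and sorts candidates
#' ascending by their maximum truncation fraction across isoforms, so
#' guides installing earlier stops rank first. Candidates whose stop
#' falls at or upstream of an isoform's alternative start codon are
#' flagged as escape risks: that isoform would still translate its full
#' protein from the downstream start.
#'
#' @param candidates Output of [find_stop_guides()].
#' @param isoforms Isoform tibble (`isoform_id`, `start_codon`,
#'   `length_aa`, `protein`).
#' @return `candidates` with added columns `max_truncation_fraction`,
#'   `escape_risk` and a `truncations` list-column (per-isoform tibble:
#'   `isoform_id`, `truncated_aa`, `truncation_fraction`, `escape`),
#'   sorted by increasing `max_truncation_fraction`.
#' @export
rank_candidates <- function(candidates, isoforms) {
  if (nrow(isoforms) == 0) abort("need at least one isoform")
  no_atg <- substr(isoforms$protein, 1, 1) != "M"
  if (any(no_atg)) {
    warn(sprintf("isoform(s) without an initial methionine dropped: %s",
                 paste(isoforms$isoform_id[no_atg], collapse = ", ")))
    isoforms <- isoforms[!no_atg, , drop = FALSE]
    if (nrow(isoforms) == 0) abort("no isoform with a start codon left")
  }
  tr <- map(candidates$target_codon, function(stop_idx) {
    tibble(isoform_id = isoforms$isoform_id,
           truncated_aa = pmax(0L, stop_idx - isoforms$start_codon),
           truncation_fraction = pmax(0L, stop_idx - isoforms$start_codon) /
             isoforms$length_aa,
           escape = stop_idx <= isoforms$start_codon)
  })
  candidates$truncations <- tr
  candidates$max_truncation_fraction <-
    map_dbl(tr, ~ max(.x$truncation_fraction))
  candidates$escape_risk <- map_lgl(tr, ~ any(.x$escape))
  arrange(candidates, .data$max_truncation_fraction, .data$start)
}

#' Annotate a Cas9 nuclease guide with its expected frameshift impact
#'
#' Reports the codon containing the blunt cut and, for each frameshift
#' phase (+1 and +2, modelled by 1-bp and 2-bp insertion archetypes at
#' the cut), the predicted truncated protein via [predict_protein()],
#' summarized as the maximum identical N-terminal prefix and percent
#' identity across phases and isoforms.
#'
#' @param guide A [guide_rna()] placed on a coding amplicon.
#' @param amp Anchored [amplicon()].
#' @param transcript A [transcript_model()].
#' @param isoforms Optional isoform tibble (default: transcript protein).
#' @return List with `cut_codon` (0-based), `impacts` (tibble per
#'   phase and isoform), `max_identical_prefix_aa`, `max_pct_identity`.
#' @export
annotate_nuclease_guide <- function(guide, amp, transcript, isoforms = NULL) {
  b <- guide_cut_site(guide)
  idx <- amplicon_to_cds(amp, b)
  if (is.na(idx)) abort("guide cut site is non-coding")
  archetypes <- list(`+1` = "A", `+2` = "AT")
  impacts <- list_rbind(imap(archetypes, function(ins, phase) {
    ed <- edit_table("insertion", b, seq = ins)
    imp <- predict_protein(ed, amp, transcript, isoforms = isoforms)
    imp$phase <- phase
    as_tibble(imp)
  }))
  list(cut_codon = idx %/% 3L,
       impacts = select(impacts, "phase", dplyr::everything()),
       max_identical_prefix_aa = max(impacts$identical_prefix_aa),
       max_pct_identity = max(impacts$pct_identity))
}
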