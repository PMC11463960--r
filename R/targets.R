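#' Synthetic gene-ablation target loci
#'
#' Deterministic, fully synthetic loci whose geometry mirrors the two
#' gene-ablation strategies the package supports, at sizes chosen so the
#' headline truncation arithmetic is easy to verify by hand:
#'
#' * `"bovine_nuclease"` - a 500-codon coding model with a Cas9 guide
#'   whose blunt cut falls at the start of codon 111. The sequence is
#'   engineered so that both +1 and +2 frameshifts hit a premature stop
#'   within a few codons, giving frameshift proteins with a maximal
#'   identical N-terminal prefix of 110 aa (22% of the 500-aa protein)
#'   across both synthetic isoforms. This emulates an exon-targeting
#'   nuclease knockout design.
#' * `"rabbit_base_editor"` - a 360-codon coding model carrying a CAG
#'   codon at codon 163 whose cytosine sits at protospacer position 6 of
#'   an NGG guide, so a cytosine base editor converts CAG to the TAG stop
#'   and truncates the protein to 162 aa (45% of its length) in all
#'   synthetic isoforms. This emulates a CBE stop-codon knockout design.
#'
#' Both targets expose a ~240-bp amplicon (30-bp non-coding flanks around
#' a 180-bp coding segment) anchored to the full transcript CDS, the
#' placed guide, and a small synthetic isoform table.
#'
#' @param target Which locus to build.
#' @return A list of class `"ko_target"` with elements `name`, `scheme`,
#'   `amplicon`, `guide`, `transcript`, `isoforms` (tibble: `isoform_id`,
#'   `start_codon`, `length_aa`, `protein`).
#' @export
synthetic_target <- function(target = c("bovine_nuclease", "rabbit_base_editor")) {
  target <- match.arg(target)
  if (target == "bovine_nuclease") build_bovine_target() else build_rabbit_target()
}

FILLER_CODONS <- c("GAT", "GAA", "TTG", "GCA", "AGA", "ACC")

filler_cds <- function(n_codons, cassette = NULL) {
  # codon 1 = ATG, last codon = TAA, filler cycle in between;
  # cassette = named list of 1-based codon index -> codon
  codons <- c("ATG", rep_len(FILLER_CODONS, n_codons - 1), "TAA")
  for (i in seq_along(cassette)) {
    codons[as.integer(names(cassette)[i])] <- cassette[[i]]
  }
  paste(codons, collapse = "")
}

build_bovine_target <- function() {
  # codons 111-114 are engineered: the guide PAM is the AGG of codon 112,
  # the +1 frameshift frame reads TAG at CDS 332-334 and the +2 frame
  # reads TGA at CDS 337-339, while the in-frame codons stay sense.
  cds <- filler_cds(500, cassette = list(`111` = "GCT", `112` = "AGG",
                                         `113` = "ATG", `114` = "AAG"))
  tx <- transcript_model("TX_SYN_BOV", cds,
                         isoform_ids = c("ISO_SYN_BOV_1", "ISO_SYN_BOV_2"))
  flank5 <- "TTCAGCATTGGACCTCGAGTAAGGTTCCAA"
  flank3 <- "GGTTAACCTTGAGAGCTTCAACTTGGATCC"
  cds_lo <- 240L
  cds_hi <- 420L
  amp_seq <- paste0(flank5, substr(cds, cds_lo + 1, cds_hi), flank3)
  amp <- amplicon("AMP_SYN_BOV", amp_seq,
                  cds_segments = cbind(30L, 30L + (cds_hi - cds_lo)),
                  cds_phase = cds_lo %% 3L, cds_offset = cds_lo)
  start <- 103L  # cut boundary at amplicon 120 <-> CDS 330 (codon 111 start)
  proto <- substr(amp_seq, start + 1, start + 20)
  pam <- substr(amp_seq, start + 21, start + 23)
  guide <- guide_rna(proto, pam, "+", start, amplicon = amp)
  stopifnot(guide_cut_site(guide) == 120L,
            nrow(place_guide(amp, proto)) == 1L)
  protein <- tx$protein
  isoforms <- tibble(
    isoform_id = c("ISO_SYN_BOV_1", "ISO_SYN_BOV_2"),
    start_codon = c(0L, 20L),
    length_aa = c(nchar(protein), nchar(protein) - 20L),
    protein = c(protein, substr(protein, 21, nchar(protein)))
  )
  structure(list(name = "bovine_nuclease", scheme = "nuclease",
                 amplicon = amp, guide = guide, transcript = tx,
                 isoforms = isoforms),
            class = "ko_target")
}

build_rabbit_target <- function() {
  # codon 163 is the CAG whose C (CDS index 486) sits at protospacer
  # position 6; codon 162 = GAA keeps the editing window free of
  # bystander cytosines and codon 168 = CGG provides the NGG PAM.
  cds <- filler_cds(360, cassette = list(`162` = "GAA", `163` = "CAG",
                                         `168` = "CGG"))
  tx <- transcript_model("TX_SYN_RAB", cds,
                         isoform_ids = paste0("ISO_SYN_RAB_", 1:3))
  flank5 <- "ACGTTAGCCAATGGTCTTCGAGACCATTGG"
  flank3 <- "CCTTAAGGCACTTCAGATCGGAAGAGCACA"
  cds_lo <- 420L
  cds_hi <- 600L
  amp_seq <- paste0(flank5, substr(cds, cds_lo + 1, cds_hi), flank3)
  amp <- amplicon("AMP_SYN_RAB", amp_seq,
                  cds_segments = cbind(30L, 30L + (cds_hi - cds_lo)),
                  cds_phase = cds_lo %% 3L, cds_offset = cds_lo)
  start <- 91L  # target C at amplicon 96 (CDS 486), window positions 94-98
  proto <- substr(amp_seq, start + 1, start + 20)
  pam <- substr(amp_seq, start + 21, start + 23)
  guide <- guide_rna(proto, pam, "+", start, amplicon = amp)
  w <- guide_window_interval(guide)
  window_seq <- substr(amp_seq, w[1] + 1, w[2])
  stopifnot(substr(amp_seq, 97, 97) == "C",
            identical(stringr::str_count(window_seq, "C"), 1L),
            nrow(place_guide(amp, proto)) == 1L)
  protein <- tx$protein
  isoforms <- tibble(
    isoform_id = paste0("ISO_SYN_RAB_", 1:3),
    start_codon = 0L,
    length_aa = nchar(protein),
    protein = protein
  )
  structure(list(name = "rabbit_base_editor", scheme = "base_editor",
                 amplicon = amp, guide = guide, transcript = tx,
                 isoforms = isoforms),
            class = "ko_target")
}

#' @export
print.ko_target <- function(x, ...) {
  cat(sprintf("<ko_target '%s'> scheme %s, amplicon %d bp, CDS %d nt\n",
              x$name, x$scheme, nchar(x$amplicon$sequence),
              nchar(x$transcript$cds)))
  invisible(x)
}

#' Canonical allele library of a synthetic target
#'
#' Left-normalized edit tables for the alleles used by the cohort
#' fixtures: for the nuclease target a 3-bp in-frame insertion (`if3`),
#' two 1-bp frameshift insertions (`ko_ins1`, `ko_ins1t`) and a 2-bp
#' frameshift deletion (`ko_del2`), all at the cut site; for the
#' base-editor target the single C-to-T stop conversion (`stop`). `wt`
#' is the empty edit table.
#'
#' @param target A [synthetic_target()].
#' @return Named list of edit tables with an `intended_class` attribute
#'   ("WT", "IF" or "KO") on each element.
#' @export
target_alleles <- function(target) {
  seq <- target$amplicon$sequence
  mk <- function(ed, class) {
    ed <- normalize_edits(ed, seq)
    attr(ed, "intended_class") <- class
    ed
  }
  if (target$scheme == "nuclease") {
    cut <- guide_cut_site(target$guide)
    list(
      wt = mk(no_edits(), "WT"),
      if3 = mk(edit_table("insertion", cut, seq = "GCT"), "IF"),
      ko_ins1 = mk(edit_table("insertion", cut, seq = "A"), "KO"),
      ko_ins1t = mk(edit_table("insertion", cut, seq = "T"), "KO"),
      ko_del2 = mk(edit_table("deletion", cut - 2L, length = 2L), "KO")
    )
  } else {
    w <- guide_window_interval(target$guide)
    cpos <- w[1] + which(strsplit(substr(seq, w[1] + 1, w[2]), "")[[1]] == "C") - 1L
    list(
      wt = mk(no_edits(), "WT"),
      stop = mk(edit_table("substitution", cpos[1], seq = "T"), "KO")
    )
  }
}
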