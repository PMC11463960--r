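# Independent oracles used across the suite. Each re-derives a result by
# the most direct route available (lookup tables, exhaustive scans,
# textbook formulas) without touching the package's implementation path.

# codon-by-codon lookup translation against the standard genetic code
oracle_translate <- function(cds) {
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}

# full-matrix affine-gap DP, read aligned end to end, reference end gaps
# free; score only (plain R, no banding, no heuristics)
oracle_align_score <- function(read, ref, match = 2, mismatch = -3,
                               open = 5, ext = 1) {
  rd <- strsplit(read, "")[[1]]
  rf <- strsplit(ref, "")[[1]]
  n <- length(rd)
  m <- length(rf)
  M <- matrix(-Inf, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  M[1, ] <- 0
  for (i in 1:n) {
    for (j in 0:m) {
      jj <- j + 1
      if (j > 0) {
        s <- if (rd[i] == rf[j] && rd[i] != "N") match else mismatch
        best <- max(M[i, jj - 1], Ix[i, jj - 1], Iy[i, jj - 1])
        if (is.finite(best)) M[i + 1, jj] <- best + s
        Iy[i + 1, jj] <- max(M[i + 1, jj - 1] - (open + ext),
                             Iy[i + 1, jj - 1] - ext)
      }
      Ix[i + 1, jj] <- max(M[i, jj] - (open + ext), Ix[i, jj] - ext)
    }
  }
  max(M[n + 1, ], Ix[n + 1, ])
}

# scan every offset on both strands with a character-by-character matcher
oracle_place_scan <- function(seq, protospacer, pam_pattern = "NGG") {
  rc <- function(x) chartr("ACGTN", "TGCAN",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  np <- nchar(pam_pattern)
  w <- 20L + np
  hits <- list()
  matches_at <- function(target, s) {
    win <- substr(seq, s + 1, s + w)
    if (nchar(win) < w || grepl("N", win, fixed = TRUE)) return(FALSE)
    tc <- strsplit(target, "")[[1]]
    wc <- strsplit(win, "")[[1]]
    all(ifelse(tc == "N", wc %in% c("A", "C", "G", "T"), wc == tc))
  }
  fwd <- paste0(protospacer, pam_pattern)
  rev <- rc(fwd)
  for (s in 0:(nchar(seq) - w)) {
    if (matches_at(fwd, s)) {
      hits[[length(hits) + 1]] <- data.frame(strand = "+", start = s)
    }
    if (matches_at(rev, s)) {
      hits[[length(hits) + 1]] <- data.frame(strand = "-", start = s + w - 1L)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(strand = character(0), start = integer(0)))
  }
  do.call(rbind, hits)
}

# textbook Pearson chi-squared statistic on a 2x2 table
oracle_chisq_stat <- function(k1, n1, k2, n2) {
  obs <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  sum((obs - expd)^2 / expd)
}

# two-sided Fisher p by exhaustive enumeration of all 2x2 tables with the
# observed margins (hypergeometric probabilities summed over tables no
# more probable than the observed one)
oracle_fisher_p <- function(k1, n1, k2, n2) {
  k_total <- k1 + k2
  support <- max(0, k_total - n2):min(n1, k_total)
  pr <- stats::dhyper(support, n1, n2, k_total)
  p_obs <- stats::dhyper(k1, n1, n2, k_total)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# brute-force stop-guide enumeration: every offset x strand with a
# matching PAM, convert every editing-window cytosine of the protospacer
# strand, re-translate the coding bases by table lookup, and report any
# novel premature in-frame stop (amplicon with a single coding segment)
oracle_stop_guides <- function(amp, transcript, pam_pattern = "NGG",
                               be_window = c(4, 8)) {
  seq <- amp$sequence
  seg <- amp$cds_segments
  stopifnot(nrow(seg) == 1)
  offset <- amp$cds_offset
  wt_prot <- oracle_translate(transcript$cds)
  wt_stop_at <- as.integer(regexpr("*", wt_prot, fixed = TRUE)) - 1L
  cds_of <- function(p) {
    if (p < seg[1, 1] || p >= seg[1, 2]) return(NA_integer_)
    offset + (p - seg[1, 1])
  }
  res <- list()
  np <- nchar(pam_pattern)
  w <- 20L + np
  pam_ok <- function(x) {
    pc <- strsplit(pam_pattern, "")[[1]]
    xc <- strsplit(x, "")[[1]]
    nchar(x) == np && all(ifelse(pc == "N", xc %in% c("A", "C", "G", "T"),
                                 xc == pc))
  }
  rc1 <- function(x) chartr("ACGT", "TGCA", x)
  for (s in 0:(nchar(seq) - w)) {
    for (strand in c("+", "-")) {
      if (strand == "+") {
        if (!pam_ok(substr(seq, s + 21, s + 20 + np))) next
        window <- (s + be_window[1] - 1):(s + be_window[2] - 1)
        cs <- window[substring(seq, window + 1, window + 1) == "C"]
        alt <- "T"
        start5 <- s
      } else {
        pam_plus <- substr(seq, s + 1, s + np)
        pam_minus <- paste(rev(strsplit(rc1(pam_plus), "")[[1]]), collapse = "")
        if (!pam_ok(pam_minus)) next
        start5 <- s + w - 1L
        window <- (start5 - be_window[2] + 1):(start5 - be_window[1] + 1)
        cs <- window[substring(seq, window + 1, window + 1) == "G"]
        alt <- "A"
      }
      if (length(cs) == 0) next
      # apply all window conversions to the full CDS and re-translate
      cds_chars <- strsplit(transcript$cds, "")[[1]]
      idx <- vapply(cs, cds_of, integer(1))
      for (k in seq_along(cs)) {
        if (!is.na(idx[k])) cds_chars[idx[k] + 1] <- alt
      }
      mut_prot <- oracle_translate(paste(cds_chars, collapse = ""))
      stop_at <- as.integer(regexpr("*", mut_prot, fixed = TRUE)) - 1L
      if (stop_at < 0 || stop_at >= wt_stop_at - 1L) next
      mut_codon <- substring(paste(cds_chars, collapse = ""),
                             stop_at * 3 + 1, stop_at * 3 + 3)
      # the novel stop must have been created by the window edits
      if (!any(!is.na(idx) & idx %/% 3L == stop_at)) next
      res[[length(res) + 1]] <- data.frame(
        strand = strand, start = start5, target_codon = stop_at,
        converted_codon = mut_codon)
    }
  }
  if (length(res) == 0) {
    return(data.frame(strand = character(0), start = integer(0),
                      target_codon = integer(0),
                      converted_codon = character(0)))
  }
  out <- do.call(rbind, res)
  out[order(out$start, out$strand), , drop = FALSE]
}

# fixed 10-codon CDS used by start-loss tests
random_cds_fixed30 <- function() {
  "ATGGCTGAAGATCATATTCCTAGAACTTAA"
}

# fixed 60-bp toy sequence used by coordinate-mapping tests
random_dna_fixed60 <- function() {
  paste0("ACGGTTCAGATCCGATTACGGTACCAGTTG",
         "GATCCATTGGCAAGTACCGGATTCAGCTAA")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random stop-free CDS of n codons (ATG start, TAA terminal stop); the
# pool includes the stop-convertible codons CAA/CAG/CGA/TGG so designer
# fixtures carry editable sites
random_cds <- function(n_codons) {
  codons <- c("GCT", "GCC", "GAT", "GAA", "TTT", "GGA", "CAT", "ATT",
              "AAA", "CTT", "AAT", "CCT", "CAA", "AGA", "TCT",
              "ACT", "GTT", "TGG", "TAT", "TGT", "CAG", "CGA", "ATG")
  paste0("ATG",
         paste(sample(codons, n_codons - 2, replace = TRUE), collapse = ""),
         "TAA")
}

# amplicon wrapping a full CDS with random non-coding flanks
cds_amplicon <- function(cds, flank = 25L) {
  amplicon("ORACLE_AMP", paste0(random_dna(flank), cds, random_dna(flank)),
           cds_segments = cbind(flank, flank + nchar(cds)),
           cds_phase = 0L, cds_offset = 0L)
}
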