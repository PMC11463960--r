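ALN_MATCH <- 2
ALN_MISMATCH <- -3
ALN_GAP_OPEN <- 5   # a length-L gap scores -(gapOpen + L * gapExtend)
ALN_GAP_EXTEND <- 1

#' Align reads against an amplicon
#'
#' Affine-gap alignment of each read (globally, end to end) against the
#' amplicon, whose ends are free (the read may cover a sub-interval of
#' the amplicon). Scoring: match +2, mismatch -3, a gap of length L
#' costs 5 + L. `N` bases never match. Reads consisting only of `N` are
#' flagged unalignable. Identical sequences are aligned once.
#'
#' @param sequences Character vector of read sequences.
#' @param amp An [amplicon()].
#' @return Tibble with one row per *unique* sequence: `sequence`,
#'   `ref_start` (0-based amplicon position of the first aligned base),
#'   `score`, `cigar` (M/I/D over read columns), `unalignable`.
#' @export
align_reads <- function(sequences, amp) {
  uniq <- unique(sequences)
  bad <- !nzchar(gsub("N", "", uniq, fixed = TRUE))
  out <- tibble(sequence = uniq, ref_start = NA_integer_, score = NA_real_,
                cigar = NA_character_, unalignable = bad)
  for (i in which(!bad)) {
    a <- .gotoh_semiglobal(uniq[i], amp$sequence, ALN_MATCH, ALN_MISMATCH,
                           ALN_GAP_OPEN, ALN_GAP_EXTEND)
    out$ref_start[i] <- a$ref_start
    out$score[i] <- a$score
    out$cigar[i] <- paste0(a$lengths, a$values, collapse = "")
  }
  out
}

parse_cigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  vals <- regmatches(cigar, gregexpr("[MID]", cigar))[[1]]
  list(lengths = lens, values = vals)
}

# raw (unfiltered) edits of one alignment; indels left-normalized against
# the amplicon. read_pos (0-based) is kept for substitutions so per-read
# base qualities can gate them later.
alignment_edits <- function(read_seq, cigar, ref_start, amp) {
  ops <- parse_cigar(cigar)
  rd <- strsplit(read_seq, "")[[1]]
  rf <- strsplit(amp$sequence, "")[[1]]
  ref_pos <- ref_start
  read_pos <- 0L
  kind <- character(0); pos <- integer(0); sq <- character(0)
  len <- integer(0); rp <- integer(0)
  for (k in seq_along(ops$values)) {
    L <- ops$lengths[k]
    v <- ops$values[k]
    if (v == "M") {
      a <- rd[(read_pos + 1):(read_pos + L)]
      b <- rf[(ref_pos + 1):(ref_pos + L)]
      mm <- which(a != b & a != "N")  # an N base never seeds a call
      if (length(mm) > 0) {
        kind <- c(kind, rep("substitution", length(mm)))
        pos <- c(pos, ref_pos + mm - 1L)
        sq <- c(sq, a[mm])
        len <- c(len, rep(1L, length(mm)))
        rp <- c(rp, read_pos + mm - 1L)
      }
      ref_pos <- ref_pos + L
      read_pos <- read_pos + L
    } else if (v == "I") {
      kind <- c(kind, "insertion")
      pos <- c(pos, ref_pos)
      sq <- c(sq, paste(rd[(read_pos + 1):(read_pos + L)], collapse = ""))
      len <- c(len, L)
      rp <- c(rp, NA_integer_)
      read_pos <- read_pos + L
    } else {
      kind <- c(kind, "deletion")
      pos <- c(pos, ref_pos)
      sq <- c(sq, NA_character_)
      len <- c(len, L)
      rp <- c(rp, NA_integer_)
      ref_pos <- ref_pos + L
    }
  }
  ed <- tibble(kind = kind, pos = pos, seq = sq, length = len, read_pos = rp)
  if (nrow(ed) == 0) return(ed)
  normalize_edits(ed, amp$sequence)
}

#' Filter called edits to the CRISPR editing region with a quality check
#'
#' Drops any edit whose (left-normalized) footprint lies wholly outside
#' the editing region, and any substitution whose read base quality is
#' below `min_base_q`. Indels are left-normalized before the region test,
#' which uses footprint overlap, not the start position alone.
#'
#' @param edits Edit table from an alignment (with a `read_pos` column
#'   for substitutions).
#' @param region Half-open `[start, end)` editing-region interval
#'   ([editing_region()]).
#' @param quality Phred+33 quality string of the read (`NULL` skips the
#'   quality gate).
#' @param min_base_q Minimum base quality for a substitution call.
#' @return The filtered edit table.
#' @export
call_edits <- function(edits, region, quality = NULL, min_base_q = 20L) {
  if (nrow(edits) == 0) return(edits)
  fp <- edit_footprints(edits)
  keep <- fp[, "start"] < region[2] & fp[, "end"] > region[1]
  edits <- edits[keep, , drop = FALSE]
  if (!is.null(quality) && nrow(edits) > 0 && "read_pos" %in% names(edits)) {
    q <- utf8ToInt(quality) - 33L
    is_sub <- edits$kind == "substitution"
    lowq <- is_sub & q[edits$read_pos + 1L] < min_base_q
    edits <- edits[!lowq, , drop = FALSE]
  }
  edits
}

edit_signature <- function(edits) {
  if (nrow(edits) == 0) return("WT")
  ed <- edits[order(edits$pos, edits$kind), , drop = FALSE]
  paste(sprintf("%s:%d:%s:%d", ed$kind, ed$pos,
                ifelse(is.na(ed$seq), "-", ed$seq), ed$length),
        collapse = "|")
}

#' Reconstruct an embryo's allele set from per-read edit calls
#'
#' Groups reads with identical (region-filtered, quality-passed) edit
#' lists into candidate alleles and keeps those supported by at least
#' `min_support_reads` reads *and* at least `min_support_fraction` of the
#' embryo's passing reads; the wild-type (edit-free) allele passes the
#' same thresholds. Mosaic embryos may report more than two alleles:
#' the thresholds are a sequencing-noise floor, not a ploidy prior.
#' Fractions of the reported alleles are renormalized to sum to one.
#'
#' @param read_calls Tibble with one row per passing read: `read_id`,
#'   `signature`, and an `edits` list-column.
#' @param min_support_reads Minimum supporting reads per allele.
#' @param min_support_fraction Minimum fraction of passing reads.
#' @return Tibble with one row per reported allele: `allele_id`,
#'   `signature`, `edits` (list-column), `support_reads`,
#'   `support_fraction` (of passing reads), `fraction` (renormalized);
#'   zero rows when no candidate passes.
#' @export
reconstruct_alleles <- function(read_calls, min_support_reads = 5L,
                                min_support_fraction = 0.10) {
  n_pass <- nrow(read_calls)
  if (n_pass == 0) abort("no passing reads: embryo is a no-call")
  grp <- read_calls |>
    group_by(.data$signature) |>
    summarise(support_reads = n(), edits = .data$edits[1], .groups = "drop") |>
    mutate(support_fraction = .data$support_reads / n_pass) |>
    filter(.data$support_reads >= min_support_reads,
           .data$support_fraction >= min_support_fraction) |>
    arrange(dplyr::desc(.data$support_reads), .data$signature)
  grp |>
    mutate(allele_id = sprintf("A%d", row_number()),
           fraction = .data$support_reads / sum(.data$support_reads)) |>
    select("allele_id", "signature", "edits", "support_reads",
           "support_fraction", "fraction")
}

decode_qual <- function(quality) utf8ToInt(quality) - 33L

# per-read signatures for all reads sharing one aligned sequence:
# only substitutions are quality-gated, so the signature depends only on
# the read's quality characters at the substitution read positions
signatures_for_group <- function(edits, qualities, min_base_q) {
  subs <- which(edits$kind == "substitution")
  if (length(subs) == 0) {
    sig <- edit_signature(edits)
    return(list(signature = rep(sig, length(qualities)),
                edits_by_sig = stats::setNames(list(edits), sig)))
  }
  qmin <- intToUtf8(min_base_q + 33L)
  keep_mat <- vapply(subs, function(s) {
    substring(qualities, edits$read_pos[s] + 1L, edits$read_pos[s] + 1L) >= qmin
  }, logical(length(qualities)))
  if (length(qualities) == 1) keep_mat <- matrix(keep_mat, nrow = 1)
  key <- apply(keep_mat, 1, function(x) paste(as.integer(x), collapse = ""))
  edits_by_sig <- list()
  signature <- character(length(qualities))
  for (k in unique(key)) {
    drop <- subs[strsplit(k, "")[[1]] == "0"]
    ed <- if (length(drop) > 0) edits[-drop, , drop = FALSE] else edits
    sig <- edit_signature(ed)
    signature[key == k] <- sig
    edits_by_sig[[sig]] <- ed
  }
  list(signature = signature, edits_by_sig = edits_by_sig)
}

#' Genotype embryos from amplicon reads
#'
#' The full allele-calling pipeline: align reads to the amplicon, call
#' edits, restrict them to the CRISPR editing region with a base-quality
#' check, reconstruct each embryo's allele set, classify alleles by frame
#' consequence, and call the embryo genotype under the experiment's
#' scheme. Reads with more than `max_lowq_frac` low-quality bases are
#' dropped from the denominator; embryos with no passing reads are
#' reported as `no-call`.
#'
#' @param reads Tibble with columns `embryo_id`, `read_id`, `sequence`,
#'   `quality` (e.g. `simulate_cohort()$reads` or [read_fastq()] output
#'   with an `embryo_id` column added).
#' @param target A [synthetic_target()]-style list supplying `amplicon`,
#'   `guide`, `scheme` and `transcript`; alternatively pass those
#'   components individually.
#' @param amplicon,guide,scheme,transcript Individual components
#'   (override `target`).
#' @param region Editing region override (half-open interval); default
#'   [editing_region()] of the guide under the scheme.
#' @param region_halfwidth,window_pad Region geometry, see
#'   [editing_region()].
#' @param min_base_q Minimum base quality for substitution calls.
#' @param max_lowq_frac Maximum tolerated fraction of bases below
#'   `min_base_q` before a read is dropped.
#' @param min_support_reads,min_support_fraction Allele support
#'   thresholds, see [reconstruct_alleles()].
#' @return Object of class `"embryo_genotypes"`: a list with `genotypes`
#'   (tibble: `embryo_id`, `call`, `n_alleles`, `n_reads`,
#'   `n_passing`), `alleles` (tibble: `embryo_id`, `allele_id`, `hgvs`,
#'   `edits`, `class`, `net_coding_delta`, `first_novel_stop`,
#'   `support_reads`, `support_fraction`, `fraction`) and `params`.
#' @export
genotype_embryos <- function(reads, target = NULL, amplicon = NULL,
                             guide = NULL, scheme = NULL, transcript = NULL,
                             region = NULL, region_halfwidth = 10L,
                             window_pad = 2L, min_base_q = 20L,
                             max_lowq_frac = 0.10, min_support_reads = 5L,
                             min_support_fraction = 0.10) {
  amp <- amplicon %||% target$amplicon
  guide <- guide %||% target$guide
  scheme <- scheme %||% target$scheme
  transcript <- transcript %||% target$transcript
  if (is.null(amp) || is.null(guide) || is.null(scheme)) {
    abort("need an amplicon, a guide and a scheme (or a target supplying them)")
  }
  region <- region %||% editing_region(guide, scheme,
                                       halfwidth = region_halfwidth,
                                       pad = window_pad)
  lowq_frac <- vapply(reads$quality, function(q) {
    mean(utf8ToInt(q) < min_base_q + 33L)
  }, numeric(1), USE.NAMES = FALSE)
  reads$pass_qc <- lowq_frac <= max_lowq_frac
  aln <- align_reads(reads$sequence[reads$pass_qc], amp)
  aln_ok <- aln[!aln$unalignable, ]
  edits_by_seq <- stats::setNames(
    map(seq_len(nrow(aln_ok)), function(i) {
      ed <- alignment_edits(aln_ok$sequence[i], aln_ok$cigar[i],
                            aln_ok$ref_start[i], amp)
      call_edits(ed, region, quality = NULL, min_base_q = min_base_q)
    }),
    aln_ok$sequence)
  genos <- list()
  allele_rows <- list()
  for (id in unique(reads$embryo_id)) {
    sub <- reads[reads$embryo_id == id, ]
    pass <- sub[sub$pass_qc & sub$sequence %in% aln_ok$sequence, ]
    n_reads <- nrow(sub)
    if (nrow(pass) == 0) {
      genos[[id]] <- tibble(embryo_id = id, call = "no-call",
                            n_alleles = 0L, n_reads = n_reads, n_passing = 0L)
      next
    }
    pass$signature <- NA_character_
    sig_edits <- list()
    for (s in unique(pass$sequence)) {
      sel <- pass$sequence == s
      grp <- signatures_for_group(edits_by_seq[[s]], pass$quality[sel],
                                  min_base_q)
      pass$signature[sel] <- grp$signature
      sig_edits[names(grp$edits_by_sig)] <- grp$edits_by_sig
    }
    calls <- tibble(read_id = pass$read_id, signature = pass$signature,
                    edits = unname(sig_edits[pass$signature]))
    alleles <- reconstruct_alleles(calls, min_support_reads,
                                   min_support_fraction)
    if (nrow(alleles) == 0) {
      genos[[id]] <- tibble(embryo_id = id, call = "no-call",
                            n_alleles = 0L, n_reads = n_reads,
                            n_passing = nrow(pass))
      next
    }
    cls <- list_rbind(map(alleles$edits, classify_allele, amp = amp,
                          transcript = transcript))
    alleles <- dplyr::bind_cols(alleles, cls)
    alleles$hgvs <- unname(map_chr(alleles$edits, format_edits,
                                   sequence = amp$sequence))
    alleles$embryo_id <- id
    allele_rows[[id]] <- alleles
    genos[[id]] <- tibble(embryo_id = id,
                          call = call_embryo(alleles$class, scheme),
                          n_alleles = nrow(alleles), n_reads = n_reads,
                          n_passing = nrow(pass))
  }
  structure(
    list(genotypes = list_rbind(unname(genos)),
         alleles = if (length(allele_rows) > 0) {
           list_rbind(unname(allele_rows)) |>
             select("embryo_id", "allele_id", "hgvs", "edits", "class",
                    "net_coding_delta", "first_novel_stop", "support_reads",
                    "support_fraction", "fraction")
         } else tibble(),
         params = list(scheme = scheme, region = region,
                       min_base_q = min_base_q,
                       max_lowq_frac = max_lowq_frac,
                       min_support_reads = min_support_reads,
                       min_support_fraction = min_support_fraction)),
    class = "embryo_genotypes"
  )
}

#' @export
print.embryo_genotypes <- function(x, ...) {
  tab <- table(x$genotypes$call)
  cat(sprintf("<embryo_genotypes> %d embryos (%s), scheme %s, region [%d, %d)\n",
              nrow(x$genotypes),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              x$params$scheme, x$params$region[1], x$params$region[2]))
  invisible(x)
}

#' Export read alignments as minimal SAM
#'
#' Single-reference SAM with the amplicon as the reference; mapped reads
#' get MAPQ 60, unalignable reads are emitted unmapped (flag 4).
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @param amp An [amplicon()].
#' @param path Output SAM file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, amp, path) {
  aln <- align_reads(reads$sequence, amp)
  lut <- stats::setNames(seq_len(nrow(aln)), aln$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", amp$id, nchar(amp$sequence))),
             con)
  for (i in seq_len(nrow(reads))) {
    a <- aln[lut[[reads$sequence[i]]], ]
    if (a$unalignable) {
      writeLines(sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s",
                         reads$read_id[i], reads$sequence[i],
                         reads$quality[i]), con)
    } else {
      writeLines(sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                         reads$read_id[i], amp$id, a$ref_start + 1L,
                         a$cigar, reads$sequence[i], reads$quality[i]), con)
    }
  }
  invisible(path)
}
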