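# a 40-bp toy amplicon with a central "cut site" at position 20
toy_amp <- amplicon("TOY", "ACGGTTCAGATCCGATTACGGTACCAGTTGGATCCATTGC")
toy_cut <- 20L

test_that("an identical read aligns with no edits and full score", {
  aln <- align_reads(toy_amp$sequence, toy_amp)
  expect_false(aln$unalignable)
  expect_equal(aln$ref_start, 0L)
  expect_equal(aln$score, 2 * 40)
  expect_equal(aln$cigar, "40M")
  ed <- alignment_edits(aln$sequence, aln$cigar, aln$ref_start, toy_amp)
  expect_equal(nrow(ed), 0)
})

test_that("a planted 1-bp insertion is called as one insertion at the cut", {
  ins <- edit_table("insertion", toy_cut, seq = "A")
  read <- apply_edits(toy_amp$sequence, ins)
  aln <- align_reads(read, toy_amp)
  expect_equal(aln$score, 2 * 40 - (5 + 1))
  ed <- alignment_edits(read, aln$cigar, aln$ref_start, toy_amp)
  expect_equal(nrow(ed), 1)
  expect_equal(ed[, c("kind", "pos", "seq", "length")],
               normalize_edits(ins, toy_amp$sequence))
})

test_that("alignment is placement-invariant: repeat-context indels left-normalize", {
  # amplicon with a homopolymer run; plant the deletion at its right end
  amp <- amplicon("HOM", "ACGTACGTAAAAAACGTACGTACGTACGTACG")
  del_right <- edit_table("deletion", 12L, length = 2L)
  read <- apply_edits(amp$sequence, del_right)
  aln <- align_reads(read, amp)
  ed <- alignment_edits(read, aln$cigar, aln$ref_start, amp)
  expect_equal(ed$kind, "deletion")
  expect_equal(ed$pos, 8L)  # leftmost placement in the A-run
  expect_equal(apply_edits(amp$sequence, ed), read)
})

test_that("alignment scores equal the full-matrix DP oracle on random pairs", {
  withr::with_seed(99, {
    for (i in 1:200) {
      n <- sample(5:30, 1)
      m <- sample(5:30, 1)
      read <- random_dna(n)
      ref <- random_dna(m)
      got <- align_reads(read, amplicon("R", ref))$score
      expect_equal(got, oracle_align_score(read, ref))
    }
    # also on near-identical pairs, the realistic regime
    for (i in 1:50) {
      ref <- random_dna(30)
      read <- apply_edits(ref, edit_table("insertion", sample(29, 1),
                                          seq = random_dna(sample(3, 1))))
      expect_equal(align_reads(read, amplicon("R", ref))$score,
                   oracle_align_score(read, ref))
    }
  })
})

test_that("all-N reads are flagged unalignable", {
  aln <- align_reads(c(strrep("N", 30), toy_amp$sequence), toy_amp)
  expect_equal(aln$unalignable, c(TRUE, FALSE))
})

test_that("call_edits keeps only edits overlapping the editing region", {
  region <- c(toy_cut - 10L, toy_cut + 10L)
  ins <- edit_table("insertion", toy_cut, seq = "A")
  ins$read_pos <- NA_integer_
  expect_equal(nrow(call_edits(ins, region)), 1)
  far <- edit_table("deletion", 2L, length = 1L)  # ~18 bp from the cut edge
  far$read_pos <- NA_integer_
  expect_equal(nrow(call_edits(far, region)), 0)
  # footprint overlap, not start position: deletion straddling the edge
  straddle <- edit_table("deletion", region[1] - 2L, length = 4L)
  straddle$read_pos <- NA_integer_
  expect_equal(nrow(call_edits(straddle, region)), 1)
})

test_that("low-quality bases cannot seed substitution calls", {
  region <- c(0L, 40L)
  sub <- edit_table("substitution", 21L, seq = "T")
  sub$read_pos <- 21L
  q_good <- strrep("F", 40)                     # Q37 everywhere
  q_bad <- paste0(strrep("F", 21), "-", strrep("F", 18))  # Q12 at the site
  expect_equal(nrow(call_edits(sub, region, q_good, 20L)), 1)
  expect_equal(nrow(call_edits(sub, region, q_bad, 20L)), 0)
})

test_that("reconstruct_alleles applies support thresholds and renormalizes", {
  wt_ed <- no_edits()
  mut_ed <- edit_table("insertion", toy_cut, seq = "A")
  mk_calls <- function(n_wt, n_mut, n_spur = 0) {
    tibble::tibble(
      read_id = sprintf("r%03d", seq_len(n_wt + n_mut + n_spur)),
      signature = c(rep("WT", n_wt),
                    rep(edit_signature(mut_ed), n_mut),
                    rep("spur", n_spur)),
      edits = c(rep(list(wt_ed), n_wt), rep(list(mut_ed), n_mut),
                rep(list(edit_table("deletion", 15L, length = 1L)), n_spur)))
  }
  # all wild type: single allele at fraction 1
  al <- reconstruct_alleles(mk_calls(50, 0))
  expect_equal(nrow(al), 1)
  expect_equal(al$fraction, 1)
  # 70/30 mixture at depth 200: both alleles recovered
  al <- reconstruct_alleles(mk_calls(140, 60))
  expect_equal(nrow(al), 2)
  expect_equal(sort(al$support_reads), c(60, 140))
  expect_equal(sum(al$fraction), 1)
  # one spurious read at depth 201 is suppressed by both thresholds
  al <- reconstruct_alleles(mk_calls(140, 60, 1))
  expect_equal(nrow(al), 2)
  expect_false("spur" %in% al$signature)
  expect_error(reconstruct_alleles(mk_calls(0, 0)), "no-call")
})

test_that("raising min_support_fraction never increases reported alleles", {
  withr::with_seed(31, {
    sigs <- sample(c("WT", "a", "b", "c"), 120, replace = TRUE,
                   prob = c(0.5, 0.25, 0.15, 0.1))
    calls <- tibble::tibble(
      read_id = sprintf("r%03d", 1:120), signature = sigs,
      edits = lapply(sigs, function(s) no_edits()))
    n_prev <- Inf
    for (f in c(0.02, 0.05, 0.12, 0.2, 0.3, 0.6)) {
      n <- nrow(reconstruct_alleles(calls, min_support_reads = 1L,
                                    min_support_fraction = f))
      expect_lte(n, n_prev)
      n_prev <- n
    }
  })
})

test_that("genotype_embryos recovers a planted mosaic and flags no-calls", {
  bov <- synthetic_target("bovine_nuclease")
  emb <- dplyr::bind_rows(
    embryo_spec("m1", c(wt = 0.5, if3 = 0.5), bov),
    embryo_spec("m2", c(ko_ins1 = 0.6, ko_del2 = 0.4), bov))
  cfg <- cohort_config(emb, bov, reads_per_embryo = 120L, seed = 8L)
  sim <- simulate_cohort(cfg)
  # append an embryo whose reads are unalignable -> no-call
  nn <- tibble::tibble(embryo_id = "nn", read_id = sprintf("nn_%d", 1:5),
                       sequence = strrep("N", 40), quality = strrep("F", 40))
  geno <- genotype_embryos(dplyr::bind_rows(sim$reads, nn), bov)
  calls <- setNames(geno$genotypes$call, geno$genotypes$embryo_id)
  expect_equal(calls[["m1"]], "IF")
  expect_equal(calls[["m2"]], "KO")
  expect_equal(calls[["nn"]], "no-call")
  m2 <- geno$alleles[geno$alleles$embryo_id == "m2", ]
  expect_setequal(m2$class, "KO_frameshift")
  expect_equal(sort(m2$net_coding_delta), c(-2L, 1L))
  # planted allele sets equal reconstructed ones (by edit signature)
  lib <- target_alleles(bov)
  expect_setequal(m2$hgvs,
                  unname(vapply(lib[c("ko_ins1", "ko_del2")], format_edits,
                                character(1),
                                sequence = bov$amplicon$sequence)))
})

test_that("SAM export round-trips through an external-style parser", {
  reads <- tibble::tibble(
    read_id = c("ok", "nn"),
    sequence = c(apply_edits(toy_amp$sequence,
                             edit_table("deletion", 10L, length = 2L)),
                 strrep("N", 10)),
    quality = c(strrep("F", 38), strrep("F", 10)))
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(reads, toy_amp, f)
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "@")), 2)
  body <- strsplit(lines[!startsWith(lines, "@")], "\t")
  expect_equal(body[[1]][6], "10M2D28M")
  expect_equal(body[[1]][4], "1")
  expect_equal(body[[2]][2], "4")  # unmapped flag for the all-N read
})
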