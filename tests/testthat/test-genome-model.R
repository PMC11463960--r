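test_that("translate_cds handles minimal ORFs and stop semantics", {
  expect_equal(translate_cds("ATGTAA"), "M")
  expect_equal(translate_cds("ATGCAGTAA"), "MQ")
  expect_equal(translate_cds("ATGCAGTAA", until_stop = FALSE), "MQ*")
  expect_equal(translate_cds("atgtaa"), "M")  # lowercase accepted
  expect_error(translate_cds("AT"), "codon")
  expect_error(translate_cds("ATGU"), "RNA|U")
  expect_error(translate_cds("ATGXAA"), "position 4")
  expect_error(translate_cds("ATGCA"), "multiple of 3")
})

test_that("translate_cds agrees with a codon-table lookup oracle", {
  withr::with_seed(42, {
    codons <- replicate(1000, random_dna(3))
    expect_equal(
      vapply(codons, function(cd) translate_cds(cd, until_stop = FALSE),
             character(1), USE.NAMES = FALSE),
      vapply(codons, oracle_translate, character(1), USE.NAMES = FALSE))
    cds <- random_cds(360)
    aa <- translate_cds(cds)
    expect_equal(nchar(aa), 359)  # start + 358 body codons, stop excluded
    expect_equal(paste0(aa, "*"), oracle_translate(cds))
  })
})

test_that("amplicon construction enforces its invariants", {
  expect_s3_class(amplicon("a", "ACGTACGT", cbind(0L, 6L)), "amplicon")
  expect_error(amplicon("a", "ACGUACGU"), "RNA|U")
  expect_error(amplicon("a", "ACGT", cbind(0L, 5L)), "outside")
  expect_error(amplicon("a", "ACGTACGT", rbind(c(0L, 4L), c(3L, 8L))),
               "overlap")
  expect_error(amplicon("a", "ACGTACGT", cbind(4L, 4L)), "empty")
  expect_error(amplicon("a", "ACGTACGT", cds_phase = 3), "phase")
  expect_error(amplicon("a", "ACGTACGT", cbind(0L, 6L), cds_phase = 1L,
                        cds_offset = 6L), "cds_offset")
  # lowercase input is uppercased on read
  expect_equal(amplicon("a", "acgt")$sequence, "ACGT")
})

test_that("amplicon/CDS coordinate mapping honors segments and phase", {
  a1 <- amplicon("a1", strrep("ACGT", 10), cbind(0L, 30L))
  expect_equal(amplicon_to_cds(a1, 0L), 0L)
  expect_true(is.na(amplicon_to_cds(a1, 35L)))
  expect_error(amplicon_to_cds(a1, 40L), "outside")

  # two segments with phase 2 on a 60-bp toy: exhaustive hand-built table
  seg <- rbind(c(5L, 20L), c(30L, 45L))
  a2 <- amplicon("a2", random_dna_fixed60(), seg, cds_phase = 2L)
  expected <- rep(NA_integer_, 60)
  idx <- 2L  # anchor = phase when no transcript offset is given
  for (p in c(5:19, 30:44)) {
    expected[p + 1] <- idx
    idx <- idx + 1L
  }
  expect_equal(amplicon_to_cds(a2, 0:59), expected)
  # coordinate round-trip over every coding position
  coding <- which(!is.na(expected)) - 1L
  expect_equal(cds_to_amplicon(a2, amplicon_to_cds(a2, coding)), coding)
  # anchored variant: indices shift by the anchor, phase consistency kept
  a3 <- amplicon("a3", random_dna_fixed60(), seg, cds_phase = 2L,
                 cds_offset = 146L)
  expect_equal(amplicon_to_cds(a3, 5L), 146L)
  expect_equal(cds_to_amplicon(a3, 146L + 14L), 19L)
})

test_that("place_guide finds exact placements with PAM on both strands", {
  proto <- "ACGTACGTACGTACGTACGT"
  amp <- amplicon("p", paste0("TTTT", proto, "AGG", "TTTT"))
  hits <- place_guide(amp, proto)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$strand, "+")
  expect_equal(hits$start, 4L)
  expect_equal(hits$pam, "AGG")
  # absent protospacer: empty result is valid
  expect_equal(nrow(place_guide(amp, strrep("G", 20))), 0)
  # a guide placed on the minus strand is found with its PAM read 5'->3'
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  amp2 <- amplicon("m", paste0("TTTT", rc(paste0(proto, "TGG")), "TTTT"))
  hits2 <- place_guide(amp2, proto)
  expect_equal(hits2$strand, "-")
  expect_equal(hits2$pam, "TGG")
  # N in the amplicon never matches
  ampN <- amplicon("n", paste0("TTTT", sub("A", "N", proto), "AGG", "TTTT"))
  expect_equal(nrow(place_guide(ampN, proto)), 0)
  # self-reverse-complementary protospacer flanked by PAMs on both sides
  # yields one placement per strand
  amp3 <- amplicon("pal", paste0("TT", "CCT", proto, "AGG", "TT"))
  hits3 <- place_guide(amp3, proto)
  expect_equal(nrow(hits3), 2)
  expect_setequal(hits3$strand, c("+", "-"))
  expect_setequal(hits3$start, c(5L, 24L))
})

test_that("place_guide agrees with a naive full-offset scan", {
  withr::with_seed(7, {
    for (len in c(500, 2000, 5000)) {
      seq <- random_dna(len)
      amp <- amplicon("r", seq)
      # take real 20-mers from the sequence so hits actually occur
      for (k in 1:4) {
        s0 <- sample(len - 25, 1)
        proto <- substr(seq, s0, s0 + 19)
        got <- place_guide(amp, proto)
        want <- oracle_place_scan(seq, proto)
        expect_equal(nrow(got), nrow(want))
        if (nrow(got) > 0) {
          expect_equal(got$start, want$start)
          expect_equal(got$strand, want$strand)
        }
      }
    }
  })
})

test_that("guide geometry: cut site and editing window on both strands", {
  amp <- amplicon("g", random_dna_fixed60())
  gp <- guide_rna(strrep("A", 20), "AGG", "+", 10L)
  expect_equal(guide_cut_site(gp), 27L)  # between protospacer 17 and 18
  expect_equal(guide_window_interval(gp), c(13L, 18L))  # positions 4-8
  gm <- guide_rna(strrep("A", 20), "AGG", "-", 40L)
  expect_equal(guide_cut_site(gm), 24L)
  expect_equal(guide_window_interval(gm), c(33L, 38L))
  # editing regions: cut +/- 10 vs padded window footprint
  expect_equal(editing_region(gp, "nuclease"), c(17L, 37L))
  expect_equal(editing_region(gp, "base_editor"), c(11L, 20L))
  # placement validation catches a wrong protospacer
  tg <- synthetic_target("bovine_nuclease")
  expect_error(guide_rna(strrep("A", 20), "AGG", "+", 103L,
                         amplicon = tg$amplicon), "does not match")
})

test_that("transcript_model validates ORF structure", {
  expect_error(transcript_model("t", "ATGAAA"), "stop")
  expect_error(transcript_model("t", "AAATAA"), "ATG")
  expect_error(transcript_model("t", "ATGTAATAA"), "internal stop")
  tx <- transcript_model("t", "ATGCAGGCTTAA")
  expect_equal(tx$protein, "MQA")
})

test_that("FASTA, annotation and FASTQ round-trips preserve content", {
  d <- withr::local_tempdir()
  tg <- synthetic_target("rabbit_base_editor")
  fa <- file.path(d, "amp.fasta")
  write_fasta(tibble::tibble(id = tg$amplicon$id,
                             sequence = tg$amplicon$sequence), fa)
  expect_equal(read_fasta(fa)$sequence, tg$amplicon$sequence)
  expect_true(all(nchar(readLines(fa)[-1]) <= 60))  # 60-column wrap
  ann <- file.path(d, "amp.tsv")
  write_cds_annotation(tg$amplicon, ann)
  back <- read_cds_annotation(ann)
  expect_equal(back$segment_start, 30)
  expect_equal(back$segment_end, 210)
  amp2 <- read_amplicon(fa, ann, cds_offset = 420L)
  expect_equal(amp2$cds_segments, tg$amplicon$cds_segments)
  expect_equal(amp2$cds_phase, tg$amplicon$cds_phase)
  # header line is required
  writeLines(c("30\t210", "x\ty"), ann)
  expect_error(read_cds_annotation(ann), "header")
  fq <- file.path(d, "r.fastq")
  reads <- tibble::tibble(read_id = c("r1", "r2"),
                          sequence = c("ACGT", "GGCC"),
                          quality = c("FFFF", "F-F-"))
  write_fastq(reads, fq)
  expect_equal(read_fastq(fq), reads)
})
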