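bov <- synthetic_target("bovine_nuclease")
rab <- synthetic_target("rabbit_base_editor")
cut <- guide_cut_site(bov$guide)

test_that("frame rule: canonical worked examples classify correctly", {
  # 3-bp coding insertion conserves the frame
  c3 <- classify_allele(edit_table("insertion", cut, seq = "GCT"),
                        bov$amplicon, bov$transcript)
  expect_equal(c3$class, "IF")
  expect_equal(c3$net_coding_delta, 3L)
  # 1-bp coding insertion disrupts it
  c1 <- classify_allele(edit_table("insertion", cut, seq = "A"),
                        bov$amplicon, bov$transcript)
  expect_equal(c1$class, "KO_frameshift")
  expect_equal(c1$net_coding_delta, 1L)
  # C-to-T at position 1 of a CAG codon installs a TAG stop
  lib <- target_alleles(rab)
  cs <- classify_allele(lib$stop, rab$amplicon, rab$transcript)
  expect_equal(cs$class, "KO_stop")
  expect_equal(cs$first_novel_stop, 162L)
  # no edits at all
  expect_equal(classify_allele(no_edits(), bov$amplicon)$class, "WT")
  # edits entirely in the non-coding flank are class WT with a note
  nc <- classify_allele(edit_table("insertion", 5L, seq = "A"), bov$amplicon)
  expect_equal(nc$class, "WT")
  expect_equal(nc$note, "non-coding edit")
})

test_that("an in-frame indel that installs a stop codon is KO_stop, not IF", {
  # inserting a TAA at a codon boundary keeps the frame but kills the ORF
  cstop <- classify_allele(edit_table("insertion", cut, seq = "TAA"),
                           bov$amplicon, bov$transcript)
  expect_equal(cstop$class, "KO_stop")
  expect_equal(cstop$net_coding_delta, 3L)
  expect_equal(cstop$first_novel_stop, 110L)
})

test_that("classification depends only on net delta mod 3 for pure indels", {
  for (d in -9:9) {
    ed <- if (d == 0) {
      no_edits()
    } else if (d > 0) {
      edit_table("insertion", cut, seq = strrep("G", d))
    } else {
      edit_table("deletion", cut, length = -d)
    }
    cl <- classify_allele(ed, bov$amplicon, bov$transcript)
    expect_equal(cl$net_coding_delta, as.integer(d))
    expected <- if (d == 0) "WT" else if (d %% 3 == 0) "IF" else "KO_frameshift"
    expect_equal(cl$class, expected,
                 label = sprintf("class at net delta %d", d))
  }
})

test_that("frame rule is total over random in-region edit sets", {
  withr::with_seed(12, {
    one_edit <- function(pos) {
      kind <- sample(c("insertion", "deletion", "substitution"), 1)
      switch(kind,
        insertion = edit_table("insertion", pos,
                               seq = random_dna(sample(4, 1))),
        deletion = edit_table("deletion", pos, length = sample(3, 1)),
        substitution = edit_table("substitution", pos,
                                  seq = sample(c("A", "C", "G", "T"), 1)))
    }
    for (i in 1:60) {
      # scatter edits widely enough that footprints cannot overlap
      positions <- sample(c(cut - 9L, cut, cut + 7L), sample(1:3, 1))
      eds <- dplyr::bind_rows(lapply(positions, one_edit))
      cl <- classify_allele(eds, bov$amplicon, bov$transcript)
      expect_true(cl$class %in% c("WT", "IF", "KO_frameshift", "KO_stop"))
      expect_equal(nrow(cl), 1)
    }
  })
})

test_that("embryo calls follow the scheme rules and are order-invariant", {
  expect_equal(call_embryo(c("KO_frameshift", "KO_frameshift"), "nuclease"),
               "KO")
  expect_equal(call_embryo(c("IF", "KO_frameshift"), "nuclease"), "IF")
  expect_equal(call_embryo(c("KO_frameshift", "IF"), "nuclease"), "IF")
  expect_equal(call_embryo(c("WT", "KO_frameshift"), "nuclease"), "IF")
  expect_equal(call_embryo("WT", "nuclease"), "WT")
  expect_equal(call_embryo(c("WT", "KO_stop"), "base_editor"), "Hz")
  expect_equal(call_embryo(c("KO_stop", "WT"), "base_editor"), "Hz")
  expect_equal(call_embryo(c("KO_stop", "KO_stop"), "base_editor"), "KO")
  expect_equal(call_embryo("WT", "base_editor"), "WT")
  expect_equal(call_embryo(character(0), "nuclease"), "no-call")
  expect_error(call_embryo("whatever", "nuclease"), "unknown")
  # three-allele mosaics: any ORF-conserving allele rescues the embryo
  expect_equal(call_embryo(c("KO_frameshift", "KO_stop", "IF"), "nuclease"),
               "IF")
  expect_warning(
    out <- call_embryo(c("IF", "KO_stop"), "base_editor"), "functional")
  expect_equal(out, "Hz")
})

test_that("predict_protein reproduces the truncation arithmetic", {
  # wild type against itself
  wt <- predict_protein(no_edits(), rab$amplicon, rab$transcript)
  expect_equal(wt$pct_identity, 100)
  expect_equal(wt$identical_prefix_aa, nchar(rab$transcript$protein))
  expect_equal(wt$truncation_fraction, 1)
  # stop at codon 163 of the 360-codon model: 162 aa, 45% of length
  lib <- target_alleles(rab)
  imp <- predict_protein(lib$stop, rab$amplicon, rab$transcript,
                         isoforms = rab$isoforms)
  expect_equal(imp$mutant_len, rep(162L, 3))
  expect_equal(imp$truncation_fraction, rep(0.45, 3))
  expect_equal(imp$identical_prefix_aa, rep(162L, 3))
  expect_equal(attr(imp, "mutant_protein"),
               substr(rab$transcript$protein, 1, 162))
  # 1-bp insertion at codon 111 of the 500-codon model: the shifted frame
  # stops within a few codons; prefix 110 aa and identity below 25%
  fs <- predict_protein(edit_table("insertion", cut, seq = "A"),
                        bov$amplicon, bov$transcript)
  expect_equal(fs$identical_prefix_aa, 110L)
  expect_lt(fs$pct_identity, 25)
})

test_that("start-codon loss is flagged and yields an empty protein", {
  cds <- random_cds_fixed30()
  amp <- amplicon("S", paste0("TTTTT", cds, "AAAAA"),
                  cds_segments = cbind(5L, 5L + nchar(cds)),
                  cds_phase = 0L, cds_offset = 0L)
  tx <- transcript_model("TS", cds)
  imp <- predict_protein(edit_table("substitution", 5L, seq = "C"), amp, tx)
  expect_true(imp$start_lost)
  expect_equal(imp$mutant_len, 0L)
  expect_equal(attr(imp, "mutant_protein"), "")
})

test_that("epitope retention distinguishes full, partial and absent overlap", {
  wt <- strrep("A", 400)
  expect_equal(epitope_retention(wt, wt, c(150, 250)), "full")
  expect_equal(epitope_retention(substr(wt, 1, 162), wt, c(150, 250)),
               "partial")
  expect_equal(epitope_retention(substr(wt, 1, 100), wt, c(150, 250)), "none")
  expect_error(epitope_retention(wt, wt, c(390, 410)), "within")
  # through predict_protein: the 162-aa stop mutant partially retains a
  # 150-250 immunogen interval
  lib <- target_alleles(rab)
  imp <- predict_protein(lib$stop, rab$amplicon, rab$transcript,
                         epitope = c(150L, 250L))
  expect_equal(imp$epitope_status, "partial")
})
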