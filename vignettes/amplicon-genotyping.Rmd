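---
title: "Genotyping CRISPR knockout embryos from amplicon reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping CRISPR knockout embryos from amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliko)
library(dplyr)
```

## The problem

Gene-ablation experiments in mammalian embryos inject CRISPR reagents
into zygotes and later ask, embryo by embryo, what happened at the
target locus. Two chemistries are covered here:

* **Cas9 nuclease**: double-strand breaks repaired by non-homologous end
  joining leave random indels near the cut site. An indel whose net
  coding length is not a multiple of three shifts the reading frame and
  truncates the protein (a *KO* allele); a multiple-of-three indel
  conserves the frame (*IF*).
* **Cytosine base editor (CBE/BE3)**: a Cas9-nickase–deaminase fusion
  converts C→T inside a protospacer window (canonically positions 4–8,
  PAM-distal) without cutting. Aimed at a CAA/CAG/CGA codon (or a TGG
  via the antisense strand) it installs a premature stop.

Because editing can happen after the first cleavage divisions, an embryo
is a *mosaic*: it may carry one to several distinct alleles at arbitrary
fractions. The embryo-level genotype is therefore a function of its
allele *set*:

* nuclease scheme — **WT** (no edited allele), **IF** (edited, but at
  least one allele, edited or not, conserves the ORF), **KO** (every
  allele is frame-disrupting);
* base-editor scheme — **WT**, **Hz** (mixture of functional and stop
  alleles), **KO** (only stop alleles). The nuclease scheme never emits
  Hz and the base-editor scheme never emits IF.

The package implements the full loop: guide design (stop-installing CBE
guides and nuclease-guide truncation annotation), a seeded synthetic
cohort generator, amplicon-read genotyping, and the cohort-level
efficiency statistics with the proportion tests used to compare
developmental rates.

## The genotyping model

Reads are aligned to the amplicon with an affine-gap Gotoh aligner
(compiled code; match +2, mismatch −3, a gap of length $L$ costs
$5 + L$). The read aligns end to end; the amplicon's ends are free, so a
read may cover a sub-interval. At equal score the dynamic program
prefers a diagonal step (match/mismatch) over opening a gap, and every
extracted indel is then left-normalized to its leftmost equivalent
placement (the VCF convention), so edit placement in homopolymer or
repeat context is deterministic and placement-invariant.

Edits are then filtered to the **CRISPR editing region** — the interval
where guide-induced edits are expected:

* nuclease: cut site ± 10 bp (`region_halfwidth`), covering NHEJ indel
  spread without capturing distal sequencing artifacts;
* base editor: the deamination-window footprint ± 2 bp (`window_pad`).

The region test uses the normalized footprint's *overlap* with the
region, not its start alone; an insertion's footprint covers both
flanking bases. A quality check accompanies the region filter: bases
with Phred < 20 (`min_base_q`) cannot seed a substitution call, and
reads with more than 10% low-quality bases are dropped from the
denominator.

Reads with identical surviving edit lists are grouped into candidate
alleles; an allele is reported if supported by ≥ 5 reads
(`min_support_reads`) **and** ≥ 10% of the embryo's passing reads
(`min_support_fraction`). Embryos are few-cell mosaics, so more than two
alleles are admissible — the thresholds are a sequencing-noise floor,
not a ploidy prior. The original study called variants with an external
mapper/caller stack and then filtered VCFs to the editing region with a
quality check; here the same selection logic is implemented as explicit,
testable thresholds.

Classification is frame arithmetic on the coding footprint: insertions
count fully when they fall strictly between two coding bases, deletions
count their overlap with coding segments, and in-frame alleles are
additionally scanned for a novel premature stop (a C→T stop conversion,
or an in-frame indel that happens to insert a stop codon — classed
`KO_stop`, since the ORF is not conserved, even though the common
shorthand equates multiple-of-three with IF). The natural terminal stop
shifts by $\delta/3$ codons under an in-frame indel and is not counted
as novel.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cut_offset` | 3 | blunt cut 3 bp 5′ of the PAM (between protospacer 17\|18) |
| `be_window` | 4–8 | CBE deamination window, 1-based protospacer positions |
| `region_halfwidth` | 10 bp | editing region half-width (nuclease) |
| `window_pad` | 2 bp | editing-region padding (base editor) |
| `min_base_q` | 20 | Phred floor for substitution calls |
| `max_lowq_frac` | 0.10 | read-level low-quality tolerance |
| `min_support_reads` | 5 | allele support floor (reads) |
| `min_support_fraction` | 0.10 | allele support floor (fraction) |

The cut offset and editing window are the canonical SpCas9/BE3 values;
the editing-region and quality defaults are conventional amplicon-QC
choices, made explicit and configurable because published pipelines
rarely state them.

## What the simulator emulates — and what it does not

`simulate_cohort()` draws each read from one of the embryo's alleles by
its mixing fraction, then corrupts it with per-base substitutions
(default rate 0.002) and uniformly placed single-base indels (default
2×10⁻⁴). Error-free bases carry Phred 37, error-injected bases Phred 12,
so the quality gate sees the same signal a base caller would provide.
Reads are single-end, full-amplicon — typical amplicons are short
PCR products, and paired-end merging is out of scope. A fixed seed gives
byte-identical FASTQ output, and the planted truth is written as a
sidecar table rather than encoded in filenames.

The canonical allele set mirrors the worked examples: a 3-bp insertion
as the in-frame allele, 1-bp insertions and a 2-bp deletion as
frameshift alleles, and the CAG→TAG conversion as the stop allele, all
at the cut site / editing window. Mosaic embryos mix one to three
alleles at fractions of 0.3–1.0, comfortably above the 0.10 support
floor — the fixtures test the calling logic under realistic mosaicism,
not the breakdown point of the thresholds.

`reported_cohorts()` freezes four cohort compositions to the reported
counts: bovine day-8 (33 embryos: 2 WT, 17 IF, 14 KO), day-12 (45: 22
IF, 23 KO), embryonic-day-14 (26: 3 WT, 10 IF, 13 KO) and rabbit day-5
under the base-editor scheme (10: 2 Hz, 8 KO). Passing the end-to-end
recovery tests on these fixtures shows the pipeline is *internally
consistent* — that planted alleles at these depths and error rates are
recovered exactly. It does not certify performance on real MiSeq data,
which adds PCR chimeras, position-dependent error profiles, primer
artifacts and genuine biological ambiguity the error model deliberately
omits.

## Synthetic target loci

Real target sequences (bovine/rabbit TEAD4 exons and their RefSeq
isoforms) are not bundled; `synthetic_target()` builds two fully
synthetic loci whose geometry reproduces the design arithmetic exactly:

* `bovine_nuclease` — 500-codon coding model, cut at the start of codon
  111, with stops engineered a few codons into both shifted frames, so
  frameshift proteins share a maximal 110-aa N-terminal prefix = 22%
  identity (identities / wild-type isoform length) across both synthetic
  isoforms (the second isoform models an alternative start at codon 21).
* `rabbit_base_editor` — 360-codon model with a CAG at codon 163 whose C
  sits at protospacer position 6 of an NGG guide; conversion truncates
  to 162 aa = 45% of protein length in all three synthetic isoforms.

The sizes (500 and 360 codons) were chosen so these printed ratios come
out exactly; real TEAD4 isoforms are 430–460 aa. Percent identity uses
the wild-type isoform length as denominator (truncations score low even
with a perfect prefix) and the identical-prefix count is reported
separately — both conventions are needed because published homology
figures mix them.

## A worked run

```{r run, eval = FALSE}
run <- run_cohort("bovine_d8", seed = 1)
run
#> <cohort_run 'bovine_d8'> 33 genotyped: 2 WT, 17 IF, 0 Hz, 14 KO
#>   edit efficiency 93.9%; KO 45.2% of edited, 42.4% of total; truth recovered 33/33
glance(run)        # one-row cohort summary
tidy(run)          # per-allele table
autoplot(run$genotypes)
```

Both knockout-efficiency denominators are reported, because both appear
in practice: `ko_of_edited_pct` (KO / edited embryos) and
`ko_of_total_pct` (KO / all genotyped). Percentages carry one decimal;
display rounding to integers is left to the caller.

## Numerical and design choices

* Coordinates are 0-based half-open on the amplicon + strand throughout;
  guide `start` is the protospacer 5′ base in + coordinates for either
  strand.
* `N` in a PAM pattern matches any base; `N` in a sequence never
  matches, and an `N` read base never seeds a substitution call.
* The designer's default editing model converts **all** window cytosines
  simultaneously (worst-case bystander model — deaminase processivity
  makes the all-C outcome the design-relevant one); `mode = "single_c"`
  gives the optimistic per-cytosine enumeration. Candidates whose novel
  stop coincides with the natural stop or falls in the final sense codon
  are discarded (no truncation), and a stop at or upstream of an
  isoform's alternative start flags that isoform as an escape risk.
* The proportion test uses Pearson's χ² without continuity correction
  when every expected count exceeds 5, otherwise Fisher's exact test;
  identical small proportions (5/10 vs 5/10) therefore go to the exact
  test. A `correct` flag enables Yates' correction.
* An in-frame edited allele under the base-editor scheme (impossible
  from pure C→T chemistry, possible from an artifact) is treated as
  functional, with a warning.
* Degenerate inputs: embryos with zero passing reads are `no-call` and
  excluded from every denominator (but counted); all-`N` reads are
  flagged unalignable; a zero-edit allele is WT; edits only partially
  overlapping a coding segment are classified from their coding
  footprint with a warning.

Problem sizes: the bundled cohort fixtures use 200 reads per embryo
(114 embryos across the four cohorts), where every planted genotype is
recovered exactly; the alignment oracle checks run on 1,000 random pairs
of up to 30 bp, and designer completeness is verified against exhaustive
enumeration on 100-codon coding models.

## Known limitations

* Single-end, full-length reads; no paired-end merging, UMIs, or primer
  trimming.
* The error model is uniform; real Illumina profiles are
  position-dependent and context-dependent.
* No nonsense-mediated-decay or splice-disruption prediction — frame
  arithmetic and stop scanning only.
* Heterozygous calls are made from reconstructed allele sets; Sanger
  trace deconvolution is out of scope.
* Off-target search and editing-efficiency prediction are out of scope
  for the designer.
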