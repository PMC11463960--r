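#' Specify a mosaic embryo for simulation
#'
#' @param id Embryo identifier.
#' @param alleles Named numeric vector of mixing fractions (must sum to
#'   1), names drawn from the target's allele library
#'   ([target_alleles()]), e.g. `c(wt = 0.5, if3 = 0.5)`.
#' @param target A [synthetic_target()].
#' @return One-row tibble with `embryo_id`, `true_genotype` and an
#'   `alleles` list-column (tibble: `allele`, `intended_class`,
#'   `fraction`, `edits` list-column).
#' @export
embryo_spec <- function(id, alleles, target) {
  lib <- target_alleles(target)
  if (is.null(names(alleles)) || !all(names(alleles) %in% names(lib))) {
    abort(sprintf("allele names must be among: %s",
                  paste(names(lib), collapse = ", ")))
  }
  if (abs(sum(alleles) - 1) > 1e-8) abort("mixing fractions must sum to 1")
  classes <- vapply(names(alleles), function(a) attr(lib[[a]], "intended_class"),
                    character(1))
  tab <- tibble(allele = names(alleles),
                intended_class = unname(classes),
                fraction = unname(alleles),
                edits = unname(lib[names(alleles)]))
  tibble(embryo_id = id,
         true_genotype = planted_genotype(classes, target$scheme),
         alleles = list(tab))
}

# the planted truth restated from intended classes (kept independent of
# the classifier module so end-to-end recovery tests are two-route)
planted_genotype <- function(classes, scheme) {
  if (all(classes == "WT")) return("WT")
  if (scheme == "nuclease") {
    if (any(classes %in% c("WT", "IF"))) "IF" else "KO"
  } else {
    if (any(classes == "WT")) "Hz" else "KO"
  }
}

#' Configure a simulated embryo cohort
#'
#' @param embryos Tibble of [embryo_spec()] rows.
#' @param target A [synthetic_target()].
#' @param reads_per_embryo Reads simulated per embryo.
#' @param sub_error Per-base substitution sequencing-error rate (0-0.1).
#' @param indel_error Per-base single-base indel sequencing-error rate
#'   (0-0.1).
#' @param read_length `NULL` for full-amplicon single-end reads
#'   (default), or an integer prefix length.
#' @param seed Integer RNG seed; a fixed seed gives byte-identical output.
#' @param name Cohort label.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(embryos, target, reads_per_embryo = 200L,
                          sub_error = 0.002, indel_error = 2e-4,
                          read_length = NULL, seed = 1L, name = "cohort") {
  if (sub_error < 0 || sub_error > 0.1 || indel_error < 0 || indel_error > 0.1) {
    abort("error rates must lie in [0, 0.1]")
  }
  if (reads_per_embryo < 1) abort("reads_per_embryo must be positive")
  if (nrow(embryos) < 1) abort("cohort needs at least one embryo")
  structure(
    list(name = name, embryos = embryos, target = target,
         reads_per_embryo = as.integer(reads_per_embryo),
         sub_error = sub_error, indel_error = indel_error,
         read_length = read_length, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config '%s'> %d embryos x %d reads, sub %.4g, indel %.4g, seed %d\n",
              x$name, nrow(x$embryos), x$reads_per_embryo, x$sub_error,
              x$indel_error, x$seed))
  invisible(x)
}

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Build the DNA sequence of a planted allele
#'
#' @param amp An [amplicon()].
#' @param edits An [edit_table()] (an element of [target_alleles()]).
#' @return The allele's DNA sequence.
#' @export
build_allele_sequence <- function(amp, edits) {
  apply_edits(amp$sequence, edits)
}

corrupt_read <- function(bases, quals, sub_error, indel_error) {
  L <- length(bases)
  if (sub_error > 0) {
    hit <- which(stats::runif(L) < sub_error)
    for (p in hit) {
      bases[p] <- sample(setdiff(DNA_BASES, bases[p]), 1L)
      quals[p] <- 12L
    }
  }
  if (indel_error > 0) {
    hit <- which(stats::runif(length(bases)) < indel_error)
    for (p in rev(hit)) {
      if (stats::runif(1) < 0.5) {  # single-base insertion before p
        bases <- append(bases, sample(DNA_BASES, 1L), after = p - 1L)
        quals <- append(quals, 12L, after = p - 1L)
      } else {                      # single-base deletion of p
        bases <- bases[-p]
        quals <- quals[-p]
      }
    }
  }
  list(bases = bases, quals = quals)
}

#' Simulate amplicon reads for a cohort of mosaic embryos
#'
#' Each read is drawn from one of the embryo's alleles according to the
#' mixing fractions, then corrupted by the sequencing error model:
#' per-base substitutions at `sub_error` and uniformly placed single-base
#' indels at `indel_error`. Error-free bases carry Phred quality 37,
#' error-injected bases quality 12 (Phred+33 encoding on write). Output
#' is byte-deterministic for a fixed config.
#'
#' @param config A [cohort_config()].
#' @return List of class `"cohort_sim"`: `reads` (tibble `embryo_id`,
#'   `read_id`, `sequence`, `quality`), `truth` (tibble `embryo_id`,
#'   `allele`, `allele_edits`, `fraction`, `true_genotype`), plus the
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  target <- config$target
  amp <- target$amplicon
  embryos <- config$embryos
  with_seed(config$seed, {
    reads_by_embryo <- vector("list", nrow(embryos))
    for (e in seq_len(nrow(embryos))) {
      tab <- embryos$alleles[[e]]
      if (nrow(tab) == 0) abort("embryo with zero alleles")
      allele_seqs <- lapply(tab$edits, function(ed) {
        s <- build_allele_sequence(amp, ed)
        if (!is.null(config$read_length)) s <- substr(s, 1, config$read_length)
        strsplit(s, "")[[1]]
      })
      R <- config$reads_per_embryo
      pick <- sample.int(nrow(tab), R, replace = TRUE, prob = tab$fraction)
      seqs <- character(R)
      quals <- character(R)
      for (r in seq_len(R)) {
        b <- allele_seqs[[pick[r]]]
        q <- rep.int(37L, length(b))
        cr <- corrupt_read(b, q, config$sub_error, config$indel_error)
        seqs[r] <- paste(cr$bases, collapse = "")
        quals[r] <- rawToChar(as.raw(cr$quals + 33L))
      }
      reads_by_embryo[[e]] <- tibble(
        embryo_id = embryos$embryo_id[e],
        read_id = sprintf("%s_read%04d", embryos$embryo_id[e], seq_len(R)),
        sequence = seqs, quality = quals)
    }
    reads <- list_rbind(reads_by_embryo)
    truth <- embryos |>
      mutate(tab = .data$alleles) |>
      select(-"alleles") |>
      tidyr::unnest("tab") |>
      mutate(allele_edits = map_chr(.data$edits, format_edits,
                                    sequence = amp$sequence)) |>
      select("embryo_id", "allele", "allele_edits", "fraction",
             "true_genotype")
    structure(list(reads = reads, truth = truth, config = config),
              class = "cohort_sim")
  })
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim '%s'> %d reads over %d embryos\n",
              x$config$name, nrow(x$reads),
              length(unique(x$reads$embryo_id))))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits one Phred+33 FASTQ per embryo (`<embryo_id>.fastq`) plus a
#' `truth.tsv` table (embryo_id, allele, allele_edits, fraction,
#' true_genotype) so downstream checks never reconstruct intent from
#' filenames.
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in unique(sim$reads$embryo_id)) {
    write_fastq(sim$reads[sim$reads$embryo_id == id, ],
                file.path(dir, paste0(id, ".fastq")))
  }
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

cohort_from_counts <- function(name, target, n_wt, n_if, n_hz, n_ko, prefix,
                               seed, ...) {
  lib_patterns <- if (target$scheme == "nuclease") {
    list(
      WT = list(c(wt = 1)),
      IF = list(c(if3 = 1), c(wt = 0.5, if3 = 0.5),
                c(if3 = 0.6, ko_ins1 = 0.4)),
      KO = list(c(ko_ins1 = 1), c(ko_ins1 = 0.5, ko_del2 = 0.5),
                c(ko_ins1 = 0.4, ko_del2 = 0.3, ko_ins1t = 0.3))
    )
  } else {
    list(WT = list(c(wt = 1)), Hz = list(c(wt = 0.5, stop = 0.5)),
         KO = list(c(stop = 1)))
  }
  plan <- c(rep("WT", n_wt), rep("IF", n_if), rep("Hz", n_hz), rep("KO", n_ko))
  embryos <- list_rbind(imap(plan, function(cls, i) {
    pats <- lib_patterns[[cls]]
    embryo_spec(sprintf("%s_%02d", prefix, i),
                pats[[(i - 1L) %% length(pats) + 1L]], target)
  }))
  cohort_config(embryos, target, seed = seed, name = name, ...)
}

#' Cohort fixtures with the reported embryo-count compositions
#'
#' Deterministic cohort configurations whose planted genotype
#' compositions reproduce the reported counts: `bovine_d8` (33 embryos:
#' 2 WT, 17 IF, 14 KO; 94% edited, 45% of edited KO), `bovine_d12` (45:
#' 0 WT, 22 IF, 23 KO; 51% KO), `bovine_e14` (26: 3 WT, 10 IF, 13 KO;
#' 88% edited, 50% KO of total) and `rabbit_d5` (10 blastocysts under the
#' base-editor scheme: 2 heterozygous WT/stop, 8 KO; 80% KO). Embryos
#' cycle through mosaic allele patterns of one to three alleles.
#'
#' @param reads_per_embryo,sub_error,indel_error,seed Passed to
#'   [cohort_config()]; each cohort's seed is offset from `seed` so the
#'   four cohorts draw distinct read noise.
#' @return Named list of [cohort_config()] objects.
#' @export
reported_cohorts <- function(reads_per_embryo = 200L, sub_error = 0.002,
                          indel_error = 2e-4, seed = 101L) {
  bov <- synthetic_target("bovine_nuclease")
  rab <- synthetic_target("rabbit_base_editor")
  args <- list(reads_per_embryo = reads_per_embryo, sub_error = sub_error,
               indel_error = indel_error)
  list(
    bovine_d8 = do.call(cohort_from_counts,
      c(list("bovine_d8", bov, 2L, 17L, 0L, 14L, "D8", seed), args)),
    bovine_d12 = do.call(cohort_from_counts,
      c(list("bovine_d12", bov, 0L, 22L, 0L, 23L, "D12", seed + 1L), args)),
    bovine_e14 = do.call(cohort_from_counts,
      c(list("bovine_e14", bov, 3L, 10L, 0L, 13L, "E14", seed + 2L), args)),
    rabbit_d5 = do.call(cohort_from_counts,
      c(list("rabbit_d5", rab, 0L, 0L, 2L, 8L, "D5", seed + 3L), args))
  )
}
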