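#' Run the full pipeline on a (simulated) cohort
#'
#' Simulates the cohort's reads and runs alignment, edit calling, allele
#' reconstruction, classification and cohort summary, then compares the
#' called genotypes with the planted truth.
#'
#' @param cohort A [cohort_config()], or the name of one of the
#'   [reported_cohorts()] fixtures (`"bovine_d8"`, `"bovine_d12"`,
#'   `"bovine_e14"`, `"rabbit_d5"`).
#' @param seed Optional seed overriding the cohort's (when `cohort` is a
#'   fixture name, the fixture set is rebuilt with this base seed).
#' @param ... For fixture names: passed to [reported_cohorts()]
#'   (`reads_per_embryo`, `sub_error`, `indel_error`); otherwise passed
#'   to [genotype_embryos()].
#' @return List of class `"cohort_run"`: `sim`, `genotypes`
#'   (`embryo_genotypes`), `summary` ([summarize_cohort()] row),
#'   `comparison` (tibble: `embryo_id`, `true_genotype`, `call`,
#'   `match`).
#' @export
run_cohort <- function(cohort, seed = NULL, ...) {
  dots <- list(...)
  if (is.character(cohort)) {
    ca <- dots[names(dots) %in% c("reads_per_embryo", "sub_error", "indel_error")]
    dots <- dots[!names(dots) %in% names(ca)]
    if (!is.null(seed)) ca$seed <- seed
    cohorts <- do.call(reported_cohorts, ca)
    if (!cohort %in% names(cohorts)) {
      abort(sprintf("unknown cohort '%s'; available: %s", cohort,
                    paste(names(cohorts), collapse = ", ")))
    }
    cohort <- cohorts[[cohort]]
  } else if (!is.null(seed)) {
    cohort$seed <- as.integer(seed)
  }
  sim <- simulate_cohort(cohort)
  geno <- do.call(genotype_embryos,
                  c(list(reads = sim$reads, target = cohort$target), dots))
  truth <- dplyr::distinct(sim$truth, .data$embryo_id, .data$true_genotype)
  comparison <- geno$genotypes |>
    left_join(truth, by = "embryo_id") |>
    mutate(match = .data$call == .data$true_genotype) |>
    select("embryo_id", "true_genotype", "call", "match")
  structure(list(sim = sim, genotypes = geno,
                 summary = summarize_cohort(geno), comparison = comparison),
            class = "cohort_run")
}

#' @export
print.cohort_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cohort_run '%s'> %d genotyped: %d WT, %d IF, %d Hz, %d KO\n",
              x$sim$config$name, s$n_genotyped, s$n_wt, s$n_if, s$n_hz, s$n_ko))
  cat(sprintf("  edit efficiency %.1f%%; KO %.1f%% of edited, %.1f%% of total; truth recovered %d/%d\n",
              s$edit_efficiency_pct, s$ko_of_edited_pct, s$ko_of_total_pct,
              sum(x$comparison$match), nrow(x$comparison)))
  invisible(x)
}

#' Genotype a directory of per-embryo FASTQ files
#'
#' Each `*.fastq` file is treated as one embryo (the basename is the
#' embryo id), mirroring per-specimen demultiplexed amplicon sequencing.
#'
#' @param dir Directory of FASTQ files.
#' @param target,... Passed to [genotype_embryos()].
#' @return An `embryo_genotypes` object.
#' @export
genotype_fastq_dir <- function(dir, target = NULL, ...) {
  files <- list.files(dir, pattern = "\\.fastq$", full.names = TRUE)
  if (length(files) == 0) abort(sprintf("no .fastq files in %s", dir))
  reads <- list_rbind(map(files, function(f) {
    r <- read_fastq(f)
    r$embryo_id <- sub("\\.fastq$", "", basename(f))
    r
  }))
  genotype_embryos(reads, target = target, ...)
}

#' Write genotyping reports to disk
#'
#' Emits the per-allele report (`alleles.tsv`: embryo, allele id, edits
#' in compact HGVS-like notation, class, support), the per-embryo
#' genotype report (`genotypes.tsv`) and the cohort summary
#' (`summary.tsv` and `summary.json`).
#'
#' @param geno An `embryo_genotypes` object (or `cohort_run`).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_genotype_reports <- function(geno, dir) {
  if (inherits(geno, "cohort_run")) geno <- geno$genotypes
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) utils::write.table(d, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  al <- geno$alleles
  if (nrow(al) > 0) al <- select(al, -"edits")
  wt(al, "alleles.tsv")
  wt(geno$genotypes, "genotypes.tsv")
  s <- summarize_cohort(geno)
  wt(s, "summary.tsv")
  jsonlite::write_json(as.list(s), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
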