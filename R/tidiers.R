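#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the allele table of a genotyping result
#'
#' @param x An `embryo_genotypes` object.
#' @param ... Unused.
#' @return Tibble with one row per reported allele (edits list-column
#'   dropped; the HGVS-like `hgvs` column identifies the edits).
#' @export
tidy.embryo_genotypes <- function(x, ...) {
  if (nrow(x$alleles) == 0) return(x$alleles)
  select(x$alleles, -"edits")
}

#' One-row cohort summary of a genotyping result
#'
#' @param x An `embryo_genotypes` object.
#' @param ... Unused.
#' @return A [summarize_cohort()] row.
#' @export
glance.embryo_genotypes <- function(x, ...) summarize_cohort(x)

#' @export
tidy.cohort_run <- function(x, ...) tidy(x$genotypes, ...)

#' @export
glance.cohort_run <- function(x, ...) x$summary

#' @export
tidy.protein_impact <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "protein_impact")
  out
}
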