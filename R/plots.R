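#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_hline
#'   labs scale_fill_manual facet_wrap theme_minimal position_stack
NULL

#' @export
ggplot2::autoplot

GENOTYPE_FILL <- c(WT = "#4d9221", IF = "#b8b8b8", Hz = "#fdb863",
                   KO = "#b2182b", `no-call` = "#666666")

#' Plot genotype composition of a genotyped cohort
#'
#' Stacked counts of embryo genotype calls.
#'
#' @param object An `embryo_genotypes` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.embryo_genotypes <- function(object, ...) {
  d <- dplyr::count(object$genotypes, .data$call)
  d$call <- factor(d$call, levels = names(GENOTYPE_FILL))
  ggplot(d, aes(x = "cohort", y = .data$n, fill = .data$call)) +
    geom_col(position = position_stack()) +
    scale_fill_manual(values = GENOTYPE_FILL, drop = TRUE, name = "genotype") +
    labs(x = NULL, y = "embryos") +
    theme_minimal()
}

#' Plot cohort efficiency summary
#'
#' Bars for the editing efficiency and both knockout-efficiency
#' denominator conventions.
#'
#' @param object A [summarize_cohort()] row.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cohort_summary <- function(object, ...) {
  d <- tibble(
    metric = factor(c("edited / genotyped", "KO / edited", "KO / genotyped"),
                    levels = c("edited / genotyped", "KO / edited",
                               "KO / genotyped")),
    pct = c(object$edit_efficiency_pct, object$ko_of_edited_pct,
            object$ko_of_total_pct))
  ggplot(d[!is.na(d$pct), ], aes(x = .data$metric, y = .data$pct)) +
    geom_col(fill = "#2166ac") +
    labs(x = NULL, y = "percent of embryos") +
    theme_minimal()
}

#' Per-embryo allele support plot
#'
#' Support fractions of the reported alleles, colored by allele class,
#' with the support-fraction threshold drawn as a reference line.
#'
#' @param geno An `embryo_genotypes` object.
#' @return A ggplot.
#' @export
plot_allele_support <- function(geno) {
  d <- geno$alleles
  if (nrow(d) == 0) abort("no alleles to plot")
  ggplot(d, aes(x = .data$embryo_id, y = .data$support_fraction,
                colour = .data$class)) +
    geom_point(size = 2) +
    geom_hline(yintercept = geno$params$min_support_fraction,
               linetype = "dashed", colour = "grey40") +
    labs(x = "embryo", y = "allele support fraction", colour = "class") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
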