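#' Summarize editing and knockout efficiencies of a genotyped cohort
#'
#' Counts genotype calls and derives the efficiency ratios used to
#' report gene-ablation experiments: the editing efficiency (share of
#' genotyped embryos carrying at least one edited allele) and the
#' knockout-generation efficiency under both denominator conventions -
#' `ko_of_edited_pct` (KO embryos over edited embryos) and
#' `ko_of_total_pct` (KO embryos over all genotyped embryos). No-calls
#' are excluded from every denominator and reported separately.
#' Percentages are reported at one decimal.
#'
#' @param x An `embryo_genotypes` object, a `cohort_run`, or a tibble
#'   with a `call` column (values WT/IF/Hz/KO/no-call).
#' @return One-row tibble of class `"cohort_summary"`: `n_genotyped`,
#'   `n_no_call`, `n_wt`, `n_if`, `n_hz`, `n_ko`, `n_edited`,
#'   `edit_efficiency_pct`, `ko_of_edited_pct`, `ko_of_total_pct`.
#' @export
summarize_cohort <- function(x) {
  calls <- if (inherits(x, "cohort_run")) x$genotypes$genotypes$call
    else if (inherits(x, "embryo_genotypes")) x$genotypes$call
    else if (is.data.frame(x)) x$call
    else abort("cannot extract genotype calls from x")
  n_no_call <- sum(calls == "no-call")
  calls <- calls[calls != "no-call"]
  n <- length(calls)
  if (n == 0) abort("zero genotyped embryos")
  n_wt <- sum(calls == "WT")
  n_if <- sum(calls == "IF")
  n_hz <- sum(calls == "Hz")
  n_ko <- sum(calls == "KO")
  n_edited <- n - n_wt
  out <- tibble(
    n_genotyped = n, n_no_call = n_no_call, n_wt = n_wt, n_if = n_if,
    n_hz = n_hz, n_ko = n_ko, n_edited = n_edited,
    edit_efficiency_pct = round(100 * n_edited / n, 1),
    ko_of_edited_pct = if (n_edited > 0) round(100 * n_ko / n_edited, 1) else NA_real_,
    ko_of_total_pct = round(100 * n_ko / n, 1)
  )
  class(out) <- c("cohort_summary", class(out))
  out
}

expected_counts_2x2 <- function(k1, n1, k2, n2) {
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  outer(rowSums(tab), colSums(tab)) / sum(tab)
}

#' Compare two proportions (chi-squared or Fisher's exact test)
#'
#' Pearson's chi-squared test without continuity correction when every
#' expected count of the 2x2 table exceeds 5, otherwise Fisher's exact
#' test (two-sided, hypergeometric). The method actually used is
#' returned alongside the statistic.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @param method `"auto"` (default rule above), `"chisq"` or `"fisher"`.
#' @param correct Apply Yates continuity correction to the chi-squared
#'   test (off by default).
#' @return One-row tibble: `method`, `statistic` (`NA` for Fisher),
#'   `df`, `p_value`, `p1`, `p2`.
#' @export
compare_proportions <- function(k1, n1, k2, n2,
                                method = c("auto", "chisq", "fisher"),
                                correct = FALSE) {
  method <- match.arg(method)
  counts <- c(k1, n1, k2, n2)
  if (any(counts < 0) || k1 > n1 || k2 > n2 || n1 == 0 || n2 == 0) {
    abort("need 0 <= k <= n with n > 0 in both groups")
  }
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  if (method == "auto") {
    method <- if (all(expected_counts_2x2(k1, n1, k2, n2) > 5)) "chisq" else "fisher"
  }
  if (method == "chisq") {
    ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    tibble(method = "chisq", statistic = unname(ht$statistic),
           df = unname(ht$parameter), p_value = ht$p.value,
           p1 = k1 / n1, p2 = k2 / n2)
  } else {
    ht <- stats::fisher.test(tab, alternative = "two.sided")
    tibble(method = "fisher", statistic = NA_real_, df = NA_real_,
           p_value = ht$p.value, p1 = k1 / n1, p2 = k2 / n2)
  }
}
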