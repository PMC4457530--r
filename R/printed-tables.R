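#' Published summary tables of the study cohort
#'
#' The package bundles, as plain CSV, the published per-gene summary tables
#' of the 30-patient CLL cohort: group means, fold-change ratios, p-values
#' and CVs. They serve as worked-example inputs (the raw cohort itself is
#' not redistributed) and seed the synthetic generator's fold changes.
#'
#' @param name one of `table1` (B-cell preferential genes), `table2a`
#'   (44-gene CLL signature with CVs), `table2b` (genes underexpressed in
#'   CLL), `table3` (surface-protein transcripts), `table4` (IgVH
#'   mutation-status genes), `table5` (LDOC1-correlated genes).
#' @return the table as a `data.frame`.
#' @export
printed_table <- function(name = c("table1", "table2a", "table2b", "table3",
                                   "table4", "table5")) {
  name <- match.arg(name)
  file <- c(table1 = "table1_bcell_genes.csv",
            table2a = "table2a_cll_genes.csv",
            table2b = "table2b_cll_under_genes.csv",
            table3 = "table3_surface_proteins.csv",
            table4 = "table4_mutation_genes.csv",
            table5 = "table5_ldoc1_genes.csv")[[name]]
  path <- system.file("extdata", "printed", file, package = "lymphsig")
  if (path == "") stop("bundled table not found: ", file)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Recompute report-style ratios from printed group means
#'
#' Reproduces the fold-change cells of the published tables from their
#' printed group means, using the report rounding convention (1 decimal
#' place, half away from zero). Because the published ratios were computed
#' from unrounded means, a few cells differ in the last decimal; the
#' returned table flags agreement.
#'
#' @param tab a `data.frame` with two mean columns.
#' @param num,den names of the numerator and denominator mean columns.
#' @param printed name of the printed ratio column to compare against.
#' @return `tab` with `ratio_recomputed` and `ratio_agrees` columns.
#' @export
recompute_printed_ratios <- function(tab, num, den, printed = "ratio") {
  tab$ratio_recomputed <- round_half_up(tab[[num]] / tab[[den]], 1)
  tab$ratio_agrees <- tab$ratio_recomputed == tab[[printed]]
  tab
}

#' The homogeneous core signature from the printed CV column
#'
#' Applies the CV homogeneity cutoff to the printed CV values of the
#' 44-gene CLL signature table, yielding the 13-gene core classifier.
#'
#' @param cv_max strict CV cutoff (default 0.5).
#' @return sorted character vector of core gene ids.
#' @export
core_genes_printed <- function(cv_max = 0.5) {
  t2a <- printed_table("table2a")
  sort_genes(t2a$gene[t2a$cv < cv_max])
}
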