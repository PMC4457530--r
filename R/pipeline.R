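#' Run the full analysis pipeline on a cohort
#'
#' End-to-end composition: read (or accept in-memory) raw counts, code set
#' and sample sheet; background-correct from negative controls; rank the
#' normalization candidates with geNorm and normalize by the geometric mean
#' of the selected references; derive the gene signatures; compute the
#' per-sample ratio-marker calls; and, when the cohort has the groups for
#' it, classify CLL against the pooled remaining disorder groups on the
#' diagnostic signature. All outputs are written as CSV/JSON into
#' `out_dir` together with a provenance record sufficient to re-run the
#' pipeline bit-identically.
#'
#' @param config a list with elements `counts` (path to a counts CSV or a
#'   raw [count_matrix()]), `codeset` (path or code-set data.frame; ignored
#'   when `counts` is in-memory), `samples` (path or sample-sheet
#'   data.frame), `out_dir`, and optional parameters `hk_candidates`,
#'   `n_hk` (default 3), `floor` (50), `fc` (2), `alpha` (0.05), `cv_max`
#'   (0.5), `absence_threshold` (50), `ratio_cut` (1).
#' @return invisible list with the normalized matrix, stability ranking,
#'   signatures, marker calls and (possibly NULL) classification report.
#' @export
run_pipeline <- function(config) {
  need <- c("counts", "samples", "out_dir")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    stop("pipeline config lacks: ", paste(missing, collapse = ", "))
  }
  p <- function(nm, default) config[[nm]] %||% default
  if (is.character(config$counts)) {
    if (!file.exists(config$counts)) stop("counts file not found: ",
                                          config$counts)
    codeset <- if (is.character(config$codeset)) {
      read_codeset_csv(config$codeset)
    } else config$codeset
    cm <- read_counts_csv(config$counts, codeset, stage = "raw")
  } else cm <- config$counts
  sheet <- if (is.character(config$samples)) {
    read_sample_sheet(config$samples)
  } else config$samples

  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  qc <- qc_positive_controls(cm)
  bc <- background_correct(cm)
  ranking <- genorm_rank(bc, candidates = p("hk_candidates", NULL),
                         n_select = p("n_hk", 3))
  norm <- normalize_counts(bc, ranking$selected)
  sigs <- derive_signatures(norm, sheet, floor = p("floor", 50),
                            fc = p("fc", 2), alpha = p("alpha", 0.05),
                            cv_max = p("cv_max", 0.5))
  markers <- marker_calls(norm, sheet,
                          absence_threshold = p("absence_threshold", 50),
                          ratio_cut = p("ratio_cut", 1))
  report <- NULL
  others <- setdiff(unique(sheet$group), c("CLL", "normal_PB", "pure_B"))
  if (!is.null(sigs$Diag) && length(sigs$Diag$genes) >= 2 &&
      sum(sheet$group == "CLL") >= 2 && length(others) > 0) {
    pool <- sheet[sheet$group %in% c("CLL", others), , drop = FALSE]
    pool$truth2 <- ifelse(pool$group == "CLL", "CLL", "B_CLPD")
    report <- cluster_classify(subset_samples(norm, pool$sample_id),
                               sigs$Diag$genes, pool, truth_field = "truth2")
  }

  write_counts_csv(norm, file.path(out_dir, "normalized.csv"))
  utils::write.csv(qc, file.path(out_dir, "qc_positive_controls.csv"),
                   row.names = FALSE)
  utils::write.csv(norm$norm_factors$factors,
                   file.path(out_dir, "normalization_factors.csv"),
                   row.names = FALSE)
  utils::write.csv(markers, file.path(out_dir, "marker_calls.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(unclass(sigs), function(s) list(name = s$name, genes = s$genes,
                                           provenance = s$provenance)),
    file.path(out_dir, "signatures.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(report)) {
    utils::write.csv(report$calls,
                     file.path(out_dir, "classification_calls.csv"),
                     row.names = FALSE)
  }
  prov <- list(
    parameters = list(hk_candidates = ranking$candidates,
                      hk_selected = ranking$selected,
                      n_hk = p("n_hk", 3), floor = p("floor", 50),
                      fc = p("fc", 2), alpha = p("alpha", 0.05),
                      cv_max = p("cv_max", 0.5),
                      absence_threshold = p("absence_threshold", 50),
                      ratio_cut = p("ratio_cut", 1)),
    inputs = list(
      counts = if (is.character(config$counts)) config$counts else "<in-memory>",
      samples = if (is.character(config$samples)) config$samples else "<in-memory>",
      n_genes = nrow(cm$counts), n_samples = ncol(cm$counts)))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(normalized = norm, ranking = ranking, qc = qc,
                 signatures = sigs, markers = markers, report = report))
}

#' Reproduce the study cohort's headline quantities from supplied data
#'
#' Runs the pipeline on a user-supplied cohort directory (the package does
#' not redistribute the deposited data) and recomputes the quantities the
#' study reports: the number of genes preferentially expressed by B cells,
#' the sizes of the diagnostic intersection and core signatures, the
#' mutated-vs-unmutated cascade survivor count, and the CD38 protein/mRNA
#' correlation.
#'
#' @param dir directory containing `counts.csv`, `codeset.csv` and
#'   `samples.csv` in the package's fixture layout (see
#'   [write_fixture()]); counts may be raw or already normalized.
#' @param normalized logical: the counts CSV already holds normalized
#'   values (preprocessing is skipped).
#' @return list: `n_b_cell`, `n_diag`, `n_core`, `n_mut`, `cd38_r`,
#'   `cd38_n`.
#' @export
reproduce_study_cohort <- function(dir, normalized = FALSE) {
  counts_path <- file.path(dir, "counts.csv")
  if (!file.exists(counts_path)) {
    stop("study cohort data not found under ", dir,
         "; supply counts.csv, codeset.csv and samples.csv")
  }
  codeset <- read_codeset_csv(file.path(dir, "codeset.csv"))
  sheet <- read_sample_sheet(file.path(dir, "samples.csv"))
  if (normalized) {
    norm <- read_counts_csv(counts_path, codeset, stage = "normalized")
  } else {
    cm <- read_counts_csv(counts_path, codeset, stage = "raw")
    bc <- background_correct(cm)
    norm <- normalize_counts(bc, genorm_rank(bc)$selected)
  }
  sigs <- suppressWarnings(derive_signatures(norm, sheet))
  cd38 <- tryCatch(protein_mrna_correlation(norm, sheet, "CD38"),
                   error = function(e) list(r = NA_real_, n = 0L))
  list(n_b_cell = length(sigs$B_cell$genes %||% character()),
       n_diag = length(sigs$Diag$genes %||% character()),
       n_core = length(sigs$Core$genes %||% character()),
       n_mut = length(sigs$Mut$genes %||% character()),
       cd38_r = cd38$r, cd38_n = cd38$n)
}

#' Render a comparison table in the report style
#'
#' Formats a [compare_groups()] table the way the published per-gene tables
#' are printed: ratios at one decimal place rounded half away from zero,
#' p-values at a fixed number of decimals, rows sorted by descending ratio.
#'
#' @param tab a [compare_groups()] table.
#' @param ratio_digits decimals for the ratio (default 1).
#' @param p_digits decimals for the p-value (default 3).
#' @param genes optional subset/order of genes to keep.
#' @return a `data.frame` of formatted character columns.
#' @export
render_comparison <- function(tab, ratio_digits = 1, p_digits = 3,
                              genes = NULL) {
  if (!is.null(genes)) tab <- tab[match(genes, tab$gene), , drop = FALSE]
  tab <- tab[order(-tab$ratio), , drop = FALSE]
  data.frame(
    gene = tab$gene,
    mean_a = sprintf("%.2f", tab$mean_a),
    mean_b = sprintf("%.2f", tab$mean_b),
    ratio = sprintf(paste0("%.", ratio_digits, "f"),
                    round_half_up(tab$ratio, ratio_digits)),
    p_value = sprintf(paste0("%.", p_digits, "f"), tab$p),
    stringsAsFactors = FALSE)
}

#' Write report-style tables for a completed run
#'
#' Re-derives the group comparisons on the normalized matrix and writes one
#' CSV per available report table shape: B-cell preferential genes (pure B
#' vs normal PB), the CLL signature comparisons, and the mutation-status
#' comparison.
#'
#' @param norm normalized [count_matrix()].
#' @param sheet sample sheet.
#' @param out_dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
render_tables <- function(norm, sheet, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(tab, file) {
    path <- file.path(out_dir, file)
    utils::write.csv(render_comparison(tab), path, row.names = FALSE,
                     quote = FALSE)
    written <<- c(written, path)
  }
  grp <- function(g) sum(sheet$group == g) >= 2
  if (grp("pure_B") && grp("normal_PB")) {
    emit(compare_groups(norm, sheet, "normal_PB", "pure_B"),
         "table_bcell_vs_pb.csv")
  }
  if (grp("CLL") && grp("normal_PB")) {
    emit(compare_groups(norm, sheet, "normal_PB", "CLL"),
         "table_cll_vs_pb.csv")
  }
  if (grp("CLL") && grp("pure_B")) {
    emit(compare_groups(norm, sheet, "pure_B", "CLL"),
         "table_cll_vs_pureb.csv")
  }
  mut_n <- sum(sheet$group == "CLL" & sheet$igvh_status == "mutated")
  unmut_n <- sum(sheet$group == "CLL" & sheet$igvh_status == "unmutated")
  if (mut_n >= 2 && unmut_n >= 2) {
    sub <- sheet[sheet$group == "CLL" &
                   sheet$igvh_status %in% c("mutated", "unmutated"), ]
    sub$group <- ifelse(sub$igvh_status == "mutated", "CLL", "other")
    emit(compare_groups(subset_samples(norm, sub$sample_id), sub,
                        "CLL", "other"), "table_unmut_vs_mut.csv")
  }
  invisible(written)
}
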