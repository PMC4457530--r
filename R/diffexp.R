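#' Per-gene two-group comparison
#'
#' For every endogenous and housekeeping gene, computes group means and SDs,
#' the expression ratio `mean_B / mean_A` (orientation explicit in the
#' argument order), and a two-sided two-sample Student t-test p-value with
#' pooled variance on linear normalized counts (Welch and log2-scale modes
#' available). Genes with zero variance in both groups get p = 1 and a flag.
#'
#' @param cm normalized [count_matrix()].
#' @param sheet sample sheet covering the matrix's samples.
#' @param group_a,group_b group labels to compare; the ratio is B over A.
#' @param genes optional subset of gene ids (default: all non-control genes).
#' @param var_equal pooled-variance Student test (default) or Welch.
#' @param log_scale test on log2(count + 1) instead of linear counts
#'   (means/ratios stay linear).
#' @return a `data.frame` of class `comparison_table` with columns `gene`,
#'   `mean_a`, `sd_a`, `mean_b`, `sd_b`, `ratio`, `t`, `p`,
#'   `zero_variance`; attributes record the groups and sample sizes.
#' @export
compare_groups <- function(cm, sheet, group_a, group_b, genes = NULL,
                           var_equal = TRUE, log_scale = FALSE) {
  stopifnot(inherits(cm, "count_matrix"))
  sheet <- sheet[match(colnames(cm$counts), sheet$sample_id), , drop = FALSE]
  if (any(is.na(sheet$sample_id))) stop("sample sheet does not cover all samples")
  a_ids <- sheet$sample_id[sheet$group == group_a]
  b_ids <- sheet$sample_id[sheet$group == group_b]
  if (length(a_ids) < 2 || length(b_ids) < 2) {
    stop("each group needs >= 2 samples (", group_a, ": ", length(a_ids),
         ", ", group_b, ": ", length(b_ids), ")")
  }
  if (is.null(genes)) {
    genes <- cm$probes$gene_id[cm$probes$probe_class %in%
                                 c("endogenous", "housekeeping")]
  }
  xa <- cm$counts[genes, a_ids, drop = FALSE]
  xb <- cm$counts[genes, b_ids, drop = FALSE]
  na <- length(a_ids); nb <- length(b_ids)
  mean_a <- rowMeans(xa); mean_b <- rowMeans(xb)
  sd_a <- sqrt(rowSums((xa - mean_a)^2) / (na - 1))
  sd_b <- sqrt(rowSums((xb - mean_b)^2) / (nb - 1))
  ta <- if (log_scale) log2(xa + 1) else xa
  tb <- if (log_scale) log2(xb + 1) else xb
  ma <- rowMeans(ta); mb <- rowMeans(tb)
  va <- rowSums((ta - ma)^2) / (na - 1)
  vb <- rowSums((tb - mb)^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(genes))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  zero_var <- se == 0 | !is.finite(se)
  tstat <- ifelse(zero_var, NA_real_, (mb - ma) / se)
  p <- ifelse(zero_var, 1, 2 * stats::pt(-abs(tstat), df))
  out <- data.frame(gene = genes, mean_a = mean_a, sd_a = sd_a,
                    mean_b = mean_b, sd_b = sd_b,
                    ratio = ifelse(mean_a > 0, mean_b / mean_a,
                                   ifelse(mean_b > 0, Inf, NA_real_)),
                    t = tstat, p = p, zero_variance = zero_var,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "group_a") <- group_a
  attr(out, "group_b") <- group_b
  attr(out, "n_a") <- na
  attr(out, "n_b") <- nb
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Three-threshold differential-expression filter cascade
#'
#' Keeps genes passing all of: the expression floor on the mean of the
#' higher-expressing group of the requested direction, the fold-change
#' threshold, and the t-test significance level. `up_in_b` keeps genes with
#' `mean_b >= floor`, `ratio >= fc`, `p <= alpha`; `down_in_b` keeps genes
#' with `mean_a >= floor`, `ratio <= 1/fc`, `p <= alpha`.
#'
#' @param tab a [compare_groups()] table.
#' @param floor expression floor in normalized counts (default 50).
#' @param fc fold-change threshold (default 2).
#' @param alpha significance threshold (default 0.05).
#' @param direction `up_in_b` or `down_in_b`.
#' @return sorted character vector of surviving gene ids; the flagged table
#'   (with `pass_floor`, `pass_fc`, `pass_p`) is attached as attribute
#'   `"flags"`.
#' @export
apply_cascade <- function(tab, floor = 50, fc = 2, alpha = 0.05,
                          direction = c("up_in_b", "down_in_b")) {
  direction <- match.arg(direction)
  stopifnot(floor > 0, fc > 0, alpha > 0)
  if (direction == "up_in_b") {
    pass_floor <- tab$mean_b >= floor
    pass_fc <- !is.na(tab$ratio) & tab$ratio >= fc
  } else {
    pass_floor <- tab$mean_a >= floor
    pass_fc <- !is.na(tab$ratio) & tab$ratio <= 1 / fc
  }
  pass_p <- tab$p <= alpha
  flags <- cbind(tab, pass_floor = pass_floor, pass_fc = pass_fc,
                 pass_p = pass_p)
  keep <- pass_floor & pass_fc & pass_p
  out <- sort_genes(tab$gene[keep])
  attr(out, "flags") <- flags
  attr(out, "thresholds") <- list(floor = floor, fc = fc, alpha = alpha,
                                  direction = direction)
  out
}

#' Set algebra over gene lists
#'
#' Exact set semantics with deterministic lexicographic output order.
#'
#' @param lists a list of character vectors of gene ids.
#' @param op `intersect`, `union` or `difference` (first list minus the
#'   union of the rest).
#' @return sorted character vector.
#' @export
gene_set_op <- function(lists, op = c("intersect", "union", "difference")) {
  op <- match.arg(op)
  stopifnot(is.list(lists), length(lists) >= 1)
  lists <- lapply(lists, as.character)
  out <- switch(op,
    intersect = Reduce(intersect, lists),
    union = Reduce(union, lists),
    difference = setdiff(lists[[1]], Reduce(union, lists[-1], character())))
  sort_genes(out)
}

#' Coefficient-of-variation homogeneity filter
#'
#' CV = sample SD / mean across one group's samples; genes with CV strictly
#' below `cv_max` are kept. Genes with zero mean are excluded and flagged.
#'
#' @param cm normalized [count_matrix()].
#' @param sheet sample sheet.
#' @param genes gene ids to filter.
#' @param group group whose samples define the CV (>= 2 samples).
#' @param cv_max strict CV cutoff (default 0.5).
#' @return sorted character vector of kept genes; attribute `"cv"` carries
#'   the per-gene CV table with a `zero_mean` flag.
#' @export
cv_filter <- function(cm, sheet, genes, group, cv_max = 0.5) {
  ids <- sheet$sample_id[sheet$group == group]
  ids <- intersect(ids, colnames(cm$counts))
  if (length(ids) < 2) stop("group ", group, " has < 2 samples")
  x <- cm$counts[genes, ids, drop = FALSE]
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / (length(ids) - 1))
  cv <- ifelse(m > 0, s / m, NA_real_)
  tab <- data.frame(gene = genes, mean = m, sd = s, cv = cv,
                    zero_mean = m <= 0, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- sort_genes(genes[!is.na(cv) & cv < cv_max])
  attr(out, "cv") <- tab
  out
}

#' Derive the named gene signatures from a normalized cohort
#'
#' Orchestrates the comparisons end-to-end:
#' * `B_cell`: up in pure B cells vs normal PB (floor/fc/alpha cascade);
#' * `CLL_vs_PB_up` and `CLL_vs_pureB_up`: up in CLL vs each normal group;
#' * `Diag`: intersection of the two CLL up-lists (the diagnostic
#'   signature; 44 genes in the study cohort);
#' * `Core`: Diag genes homogeneously expressed in CLL (CV < `cv_max`;
#'   13 genes in the study cohort);
#' * `CLL_under`: down in CLL vs pure B cells;
#' * `Mut`: differential between IgVH-mutated and unmutated CLL
#'   (borderline excluded), both directions pooled (24 genes in the study
#'   cohort), with the two directions kept in the provenance.
#' Signatures whose required groups are missing are skipped with a warning.
#'
#' @param cm normalized [count_matrix()].
#' @param sheet sample sheet.
#' @param floor,fc,alpha cascade thresholds (see [apply_cascade()]).
#' @param cv_max CV cutoff for the core signature.
#' @return a named list of class `signature_set`; each element has `name`,
#'   `genes` and a `provenance` list sufficient to re-derive it.
#' @export
derive_signatures <- function(cm, sheet, floor = 50, fc = 2, alpha = 0.05,
                              cv_max = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  have <- function(g, n = 2) sum(sheet$group == g) >= n
  sigs <- list()
  mk <- function(name, genes, ...) {
    list(name = name, genes = genes,
         provenance = c(list(floor = floor, fc = fc, alpha = alpha), ...))
  }
  if (have("pure_B") && have("normal_PB")) {
    t_b <- compare_groups(cm, sheet, "normal_PB", "pure_B")
    sigs$B_cell <- mk("B_cell", apply_cascade(t_b, floor, fc, alpha, "up_in_b"),
                      comparison = "pure_B vs normal_PB", direction = "up_in_b")
  } else warning("B_cell signature skipped: needs pure_B and normal_PB")
  if (have("CLL") && have("normal_PB")) {
    t_pb <- compare_groups(cm, sheet, "normal_PB", "CLL")
    sigs$CLL_vs_PB_up <- mk("CLL_vs_PB_up",
                            apply_cascade(t_pb, floor, fc, alpha, "up_in_b"),
                            comparison = "CLL vs normal_PB",
                            direction = "up_in_b")
  }
  if (have("CLL") && have("pure_B")) {
    t_pb2 <- compare_groups(cm, sheet, "pure_B", "CLL")
    sigs$CLL_vs_pureB_up <- mk("CLL_vs_pureB_up",
                               apply_cascade(t_pb2, floor, fc, alpha, "up_in_b"),
                               comparison = "CLL vs pure_B",
                               direction = "up_in_b")
    sigs$CLL_under <- mk("CLL_under",
                         apply_cascade(t_pb2, floor, fc, alpha, "down_in_b"),
                         comparison = "CLL vs pure_B", direction = "down_in_b")
  } else {
    warning("Diag / CLL_under signatures skipped: need CLL and pure_B")
  }
  if (!is.null(sigs$CLL_vs_PB_up) && !is.null(sigs$CLL_vs_pureB_up)) {
    diag <- gene_set_op(list(sigs$CLL_vs_PB_up$genes,
                             sigs$CLL_vs_pureB_up$genes), "intersect")
    sigs$Diag <- mk("Diag", diag,
                    comparison = "intersection(CLL_vs_PB_up, CLL_vs_pureB_up)")
    core <- cv_filter(cm, sheet, diag, "CLL", cv_max)
    sigs$Core <- mk("Core", as.character(core), cv_max = cv_max,
                    comparison = "CV filter on Diag within CLL")
  }
  mut_ids <- sheet$group == "CLL" & sheet$igvh_status == "mutated"
  unmut_ids <- sheet$group == "CLL" & sheet$igvh_status == "unmutated"
  if (sum(mut_ids) >= 2 && sum(unmut_ids) >= 2) {
    # borderline cases excluded by construction of the two label sets
    sub <- sheet[mut_ids | unmut_ids, , drop = FALSE]
    sub$group <- ifelse(sub$igvh_status == "mutated", "CLL", "other")
    t_mut <- compare_groups(subset_samples(cm, sub$sample_id), sub,
                            "CLL", "other")
    up_unmut <- apply_cascade(t_mut, floor, fc, alpha, "up_in_b")
    up_mut <- apply_cascade(t_mut, floor, fc, alpha, "down_in_b")
    sigs$Mut <- mk("Mut", gene_set_op(list(up_unmut, up_mut), "union"),
                   comparison = "unmutated vs mutated CLL (borderline excluded)",
                   up_in_unmutated = as.character(up_unmut),
                   up_in_mutated = as.character(up_mut))
  } else warning("Mut signature skipped: needs >= 2 mutated and unmutated CLL")
  class(sigs) <- "signature_set"
  sigs
}

#' @export
print.signature_set <- function(x, ...) {
  cat("signature set:\n")
  for (s in x) cat(sprintf("  %-16s %d genes\n", s$name, length(s$genes)))
  invisible(x)
}
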