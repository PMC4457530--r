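PROBE_CLASSES <- c("endogenous", "housekeeping", "positive", "negative")
SAMPLE_GROUPS <- c("normal_PB", "pure_B", "CLL", "MCL", "MZL", "FL", "HCL", "other")
IGVH_LEVELS <- c("mutated", "unmutated", "borderline", "unknown")

#' The nine candidate normalization genes of the code set
#' @export
HK_CANDIDATES <- c("ACTB", "TBP", "RPL19", "RPLP0", "G6PD", "ABCF1", "B2M",
                   "TPT1", "RPS23")

#' Construct a probe code-set table
#'
#' @param gene_id character vector of unique probe names.
#' @param probe_class one of `endogenous`, `housekeeping`, `positive`,
#'   `negative` per probe. Unknown classes are mapped to `endogenous` with a
#'   warning.
#' @param note free-text annotation (nominal concentrations for positive
#'   controls are parsed from the gene name, e.g. `POS_A(128)`).
#' @return a `data.frame` with columns `gene_id`, `probe_class`, `note`.
#' @export
probe_def <- function(gene_id, probe_class, note = "") {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene_id in code set: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  }
  raw_class <- as.character(probe_class)
  probe_class <- tolower(raw_class)
  unknown <- !(probe_class %in% PROBE_CLASSES)
  if (any(unknown)) {
    warning("unknown probe classes mapped to endogenous: ",
            paste(unique(raw_class[unknown]), collapse = ", "))
    probe_class[unknown] <- "endogenous"
  }
  data.frame(gene_id = gene_id, probe_class = probe_class,
             note = rep_len(as.character(note), length(gene_id)),
             stringsAsFactors = FALSE)
}

#' Construct a count matrix with probe annotation
#'
#' The container every pipeline stage transforms: a genes x samples matrix of
#' nonnegative counts plus the probe code-set table and a stage flag.
#'
#' @param counts numeric genes x samples matrix with row and column names.
#' @param probes code-set table from [probe_def()]; every row of `counts`
#'   must appear in it.
#' @param stage one of `raw`, `background_corrected`, `normalized`. Raw
#'   counts must be integers.
#' @return an object of class `count_matrix`.
#' @export
count_matrix <- function(counts, probes, stage = "raw") {
  stage <- match.arg(stage, c("raw", "background_corrected", "normalized"))
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene row names and sample column names")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene_id in counts: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids in counts")
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be nonnegative and complete")
  }
  if (stage == "raw" && any(counts != round(counts))) {
    stop("raw counts must be integers")
  }
  missing <- setdiff(rownames(counts), probes$gene_id)
  if (length(missing)) {
    stop("genes absent from code set: ", paste(missing, collapse = ", "))
  }
  probes <- probes[match(rownames(counts), probes$gene_id), , drop = FALSE]
  rownames(probes) <- NULL
  structure(list(counts = counts, probes = probes, stage = stage,
                 background = NULL, norm_factors = NULL),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d probes x %d samples (stage: %s)\n",
              nrow(x$counts), ncol(x$counts), x$stage))
  cat("probe classes:",
      paste(sprintf("%s=%d", names(table(x$probes$probe_class)),
                    table(x$probes$probe_class)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

# gene ids of a given probe class
class_genes <- function(cm, probe_class) {
  cm$probes$gene_id[cm$probes$probe_class == probe_class]
}

#' Subset a count matrix to a set of samples
#'
#' @param cm a [count_matrix()].
#' @param sample_ids sample ids to keep, in the requested order.
#' @return a `count_matrix` with the same probes and stage.
#' @export
subset_samples <- function(cm, sample_ids) {
  missing <- setdiff(sample_ids, colnames(cm$counts))
  if (length(missing)) {
    stop("samples absent from matrix: ", paste(missing, collapse = ", "))
  }
  out <- cm
  out$counts <- cm$counts[, sample_ids, drop = FALSE]
  out
}

#' Build a sample sheet
#'
#' @param sample_id character vector of unique sample ids.
#' @param group sample group (`normal_PB`, `pure_B`, `CLL`, `MCL`, `MZL`,
#'   `FL`, `HCL`, `other`); case-insensitive.
#' @param igvh_status IgVH mutation status (`mutated`, `unmutated`,
#'   `borderline`, `unknown`); meaningful only for CLL samples.
#' @param pct_cd38_pos,pct_malignant flow-cytometry percentages in 0..100,
#'   `NA` when not measured.
#' @param zap70_status `pos`, `neg` or `unknown`.
#' @return a validated `data.frame`.
#' @export
sample_sheet <- function(sample_id, group, igvh_status = "unknown",
                         pct_cd38_pos = NA_real_, pct_malignant = NA_real_,
                         zap70_status = "unknown") {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample_id in sample sheet")
  n <- length(sample_id)
  norm_enum <- function(x, levels, what) {
    x <- rep_len(as.character(x), n)
    idx <- match(tolower(x), tolower(levels))
    if (any(is.na(idx))) {
      stop("invalid ", what, ": ", paste(unique(x[is.na(idx)]), collapse = ", "))
    }
    levels[idx]
  }
  group <- norm_enum(group, SAMPLE_GROUPS, "group")
  igvh_status <- norm_enum(igvh_status, IGVH_LEVELS, "igvh_status")
  zap70_status <- norm_enum(zap70_status, c("pos", "neg", "unknown"),
                            "zap70_status")
  chk_pct <- function(x, what) {
    x <- suppressWarnings(as.numeric(rep_len(x, n)))
    bad <- !is.na(x) & (x < 0 | x > 100)
    if (any(bad)) stop(what, " outside [0, 100] for: ",
                       paste(sample_id[bad], collapse = ", "))
    x
  }
  if (any(igvh_status != "unknown" & group != "CLL")) {
    warning("igvh_status set for non-CLL samples; it is only meaningful for CLL")
  }
  data.frame(sample_id = sample_id, group = group, igvh_status = igvh_status,
             pct_cd38_pos = chk_pct(pct_cd38_pos, "pct_cd38_pos"),
             pct_malignant = chk_pct(pct_malignant, "pct_malignant"),
             zap70_status = zap70_status, stringsAsFactors = FALSE)
}
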