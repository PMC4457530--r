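# shared transform for embedding/clustering: log2(x+1), per-gene z-score;
# constant genes are dropped with a warning. Returns samples x genes.
transform_for_embedding <- function(cm, genes) {
  missing <- setdiff(genes, rownames(cm$counts))
  if (length(missing)) {
    stop("signature genes absent from matrix: ",
         paste(missing, collapse = ", "))
  }
  x <- log2(cm$counts[genes, , drop = FALSE] + 1)
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning("constant genes dropped from embedding: ",
            paste(genes[sds == 0], collapse = ", "))
    x <- x[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- (x - rowMeans(x)) / sds
  t(z)
}

#' PCA embedding of samples on a gene signature
#'
#' Counts are transformed log2(x + 1) and per-gene standardized before the
#' principal-component decomposition. Component signs follow a deterministic
#' convention: the largest-magnitude loading of each component is positive.
#'
#' @param cm normalized [count_matrix()] with >= 3 samples.
#' @param genes signature gene ids.
#' @param n_components number of components to return.
#' @return list with `scores` (samples x components), `loadings`,
#'   `explained_variance` (all components' variances, descending) and
#'   `prop_variance`.
#' @export
embed_pca <- function(cm, genes, n_components = 3) {
  stopifnot(inherits(cm, "count_matrix"))
  if (ncol(cm$counts) < 3) stop("PCA embedding needs >= 3 samples")
  z <- transform_for_embedding(cm, genes)
  pr <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pr$rotation))
  flip <- vapply(seq_len(ncol(pr$rotation)), function(j) {
    l <- pr$rotation[, j]
    sign(l[which.max(abs(l))])
  }, 0)
  flip[flip == 0] <- 1
  scores <- sweep(pr$x, 2, flip, `*`)[, seq_len(k), drop = FALSE]
  loadings <- sweep(pr$rotation, 2, flip, `*`)[, seq_len(k), drop = FALSE]
  ev <- pr$sdev^2
  list(scores = scores, loadings = loadings, explained_variance = ev,
       prop_variance = ev / sum(ev))
}

#' Unsupervised two-class sample classification by hierarchical clustering
#'
#' Hierarchically clusters the samples (Euclidean distance on the
#' log2/z-score transformed signature matrix, average linkage), cuts the
#' tree into two clusters, and maps clusters to the two truth labels by
#' maximum agreement.
#'
#' @param cm normalized [count_matrix()].
#' @param genes signature gene ids.
#' @param sheet sample sheet; rows are matched to the matrix's samples.
#' @param truth_field sheet column holding the truth label (default
#'   `group`); must take exactly two values with >= 2 samples each.
#' @param positive label treated as positive for sensitivity/specificity
#'   (default `CLL` if present, else the lexicographically first label).
#' @return list of class `classification_report`: `calls` (per-sample
#'   predicted and truth label), `confusion`, `accuracy`, `sensitivity`,
#'   `specificity`, `embedding` (first PCs).
#' @export
cluster_classify <- function(cm, genes, sheet, truth_field = "group",
                             positive = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  sheet <- sheet[match(colnames(cm$counts), sheet$sample_id), , drop = FALSE]
  truth <- as.character(sheet[[truth_field]])
  labels <- sort_genes(truth)
  if (length(labels) != 2) {
    stop("truth field must take exactly 2 values (got ",
         length(labels), "); pool classes or use one-vs-rest recoding")
  }
  if (any(table(truth) < 2)) stop("each truth class needs >= 2 samples")
  z <- transform_for_embedding(cm, genes)
  hc <- stats::hclust(stats::dist(z, method = "euclidean"),
                      method = "average")
  cl <- stats::cutree(hc, k = 2)
  # map clusters to labels by maximum agreement over the two assignments
  acc_for <- function(map) mean(map[cl] == truth)
  maps <- list(stats::setNames(labels, 1:2), stats::setNames(rev(labels), 1:2))
  accs <- vapply(maps, acc_for, 0)
  map <- maps[[which.max(accs)]]
  pred <- unname(map[as.character(cl)])
  if (is.null(positive)) {
    positive <- if ("CLL" %in% labels) "CLL" else labels[1]
  }
  negative <- setdiff(labels, positive)
  tp <- sum(pred == positive & truth == positive)
  tn <- sum(pred == negative & truth == negative)
  fp <- sum(pred == positive & truth == negative)
  fn <- sum(pred == negative & truth == positive)
  conf <- matrix(c(tp, fn, fp, tn), 2, 2,
                 dimnames = list(predicted = c(positive, negative),
                                 truth = c(positive, negative)))
  structure(list(
    calls = data.frame(sample_id = colnames(cm$counts), truth = truth,
                       predicted = pred, stringsAsFactors = FALSE),
    confusion = conf,
    accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    positive = positive,
    embedding = embed_pca(cm, genes, n_components = min(3, ncol(cm$counts) - 1))$scores
  ), class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("classification: accuracy %.3f, sensitivity %.3f, specificity %.3f (positive: %s)\n",
              x$accuracy, x$sensitivity, x$specificity, x$positive))
  print(x$confusion)
  invisible(x)
}

#' Nearest-centroid classification of new samples
#'
#' Supervised counterpart of [cluster_classify()]: centroids of the
#' transformed signature matrix are computed per truth class on the training
#' cohort and new samples are assigned to the nearest centroid (Euclidean).
#' The new samples are transformed with the training genes' log2/z-score
#' parameters.
#'
#' @param cm training [count_matrix()].
#' @param genes signature gene ids.
#' @param sheet training sample sheet.
#' @param newdata [count_matrix()] of samples to label.
#' @param truth_field sheet column with training labels.
#' @return data.frame: sample_id, predicted.
#' @export
centroid_classify <- function(cm, genes, sheet, newdata,
                              truth_field = "group") {
  sheet <- sheet[match(colnames(cm$counts), sheet$sample_id), , drop = FALSE]
  truth <- as.character(sheet[[truth_field]])
  x <- log2(cm$counts[genes, , drop = FALSE] + 1)
  mu <- rowMeans(x); sds <- apply(x, 1, stats::sd)
  keep <- sds > 0
  genes <- genes[keep]; mu <- mu[keep]; sds <- sds[keep]
  z <- t((x[keep, , drop = FALSE] - mu) / sds)
  centroids <- do.call(rbind, lapply(split(seq_len(nrow(z)), truth),
                                     function(i) colMeans(z[i, , drop = FALSE])))
  zn <- t((log2(newdata$counts[genes, , drop = FALSE] + 1) - mu) / sds)
  d <- as.matrix(stats::dist(rbind(centroids, zn)))
  d <- d[-seq_len(nrow(centroids)), seq_len(nrow(centroids)), drop = FALSE]
  data.frame(sample_id = colnames(newdata$counts),
             predicted = rownames(centroids)[apply(d, 1, which.min)],
             stringsAsFactors = FALSE)
}

#' Kappa/lambda light-chain clonality call
#'
#' The clonality ratio is kappa counts over lambda counts. A sample is
#' polyclonal when the ratio lies inside the polyclonal reference interval
#' mean +/- 2 SD; above it, monoclonal kappa; below it, monoclonal lambda.
#' The study's reference interval is mean 0.89, SD 0.22. Zero lambda with
#' positive kappa yields an infinite ratio (monoclonal kappa, flagged);
#' both chains zero is indeterminate.
#'
#' @param kappa,lambda numeric vectors of normalized light-chain counts.
#' @param ref_mean,ref_sd polyclonal reference parameters; alternatively
#'   supply `polyclonal_ratios` to estimate them.
#' @param polyclonal_ratios optional vector of ratios from known polyclonal
#'   samples; overrides `ref_mean`/`ref_sd`.
#' @param sample_id optional ids for the output.
#' @return data.frame: sample_id, ratio, interval_low, interval_high, call
#'   (`polyclonal`, `monoclonal_kappa`, `monoclonal_lambda`,
#'   `indeterminate`), flag.
#' @export
clonality_call <- function(kappa, lambda, ref_mean = 0.89, ref_sd = 0.22,
                           polyclonal_ratios = NULL, sample_id = NULL) {
  stopifnot(length(kappa) == length(lambda))
  if (!is.null(polyclonal_ratios)) {
    ref_mean <- mean(polyclonal_ratios)
    ref_sd <- stats::sd(polyclonal_ratios)
  }
  lo <- ref_mean - 2 * ref_sd
  hi <- ref_mean + 2 * ref_sd
  ratio <- ifelse(lambda > 0, kappa / lambda,
                  ifelse(kappa > 0, Inf, NA_real_))
  call <- ifelse(is.na(ratio), "indeterminate",
                 ifelse(ratio > hi, "monoclonal_kappa",
                        ifelse(ratio < lo, "monoclonal_lambda", "polyclonal")))
  flag <- ifelse(is.na(ratio), "both_chains_zero",
                 ifelse(is.infinite(ratio), "lambda_zero", ""))
  data.frame(sample_id = sample_id %||% seq_along(kappa), ratio = ratio,
             interval_low = lo, interval_high = hi, call = call, flag = flag,
             stringsAsFactors = FALSE)
}

#' LDOC1/ADAM29 trichotomy and LPL/ADAM29 surrogate call
#'
#' The LDOC1/ADAM29 pattern separates CLL samples into three subclasses:
#' LDOC1-expressing (unmutated-type), ADAM29-expressing (mutated-type), and
#' a double-negative group with both markers below the absence threshold.
#' The LPL/ADAM29 ratio is the published surrogate for IgVH status:
#' `unmutated_like` when the ratio exceeds `ratio_cut`. When ADAM29 is 0 a
#' pseudo-count of 1 is added to the denominator (flagged); double-negative
#' samples get an indeterminate surrogate call.
#'
#' @param ldoc1,adam29,lpl numeric vectors of normalized counts.
#' @param absence_threshold marker absence threshold in normalized counts
#'   (default 50, the pipeline's expression floor).
#' @param ratio_cut LPL/ADAM29 decision cut (default 1).
#' @param sample_id optional ids.
#' @return data.frame: sample_id, ldoc1, adam29, lpl, trichotomy
#'   (`ldoc1_high`, `adam29_high`, `double_negative`), lpl_adam29_ratio,
#'   lpl_call (`unmutated_like`, `mutated_like`, `indeterminate`), flag.
#' @export
mut_marker_call <- function(ldoc1, adam29, lpl, absence_threshold = 50,
                            ratio_cut = 1.0, sample_id = NULL) {
  stopifnot(all(ldoc1 >= 0), all(adam29 >= 0), all(lpl >= 0))
  trich <- ifelse(ldoc1 < absence_threshold & adam29 < absence_threshold,
                  "double_negative",
                  ifelse(ldoc1 >= adam29, "ldoc1_high", "adam29_high"))
  denom0 <- adam29 == 0
  ratio <- lpl / ifelse(denom0, 1, adam29)
  lpl_call <- ifelse(trich == "double_negative", "indeterminate",
                     ifelse(ratio > ratio_cut, "unmutated_like",
                            "mutated_like"))
  data.frame(sample_id = sample_id %||% seq_along(ldoc1), ldoc1 = ldoc1,
             adam29 = adam29, lpl = lpl, trichotomy = trich,
             lpl_adam29_ratio = ratio, lpl_call = lpl_call,
             flag = ifelse(denom0, "adam29_zero_pseudocount", ""),
             stringsAsFactors = FALSE)
}

#' Per-sample ratio-marker calls for a cohort
#'
#' Convenience wrapper computing [clonality_call()] and [mut_marker_call()]
#' for every sample of a normalized matrix. The polyclonal reference is
#' estimated from the cohort's normal samples when >= 3 are present, else
#' the study's printed parameters are used.
#'
#' @param cm normalized [count_matrix()] containing `kappa`, `lambda`,
#'   `LDOC1`, `ADAM29`, `LPL` rows.
#' @param sheet sample sheet.
#' @param absence_threshold,ratio_cut see [mut_marker_call()].
#' @return merged per-sample data.frame of both marker calls.
#' @export
marker_calls <- function(cm, sheet, absence_threshold = 50, ratio_cut = 1.0) {
  need <- c("kappa", "lambda", "LDOC1", "ADAM29", "LPL")
  missing <- setdiff(need, rownames(cm$counts))
  if (length(missing)) {
    stop("marker genes absent: ", paste(missing, collapse = ", "))
  }
  sheet <- sheet[match(colnames(cm$counts), sheet$sample_id), , drop = FALSE]
  norm_ids <- sheet$sample_id[sheet$group %in% c("normal_PB", "pure_B")]
  poly <- NULL
  if (length(norm_ids) >= 3) {
    poly <- cm$counts["kappa", norm_ids] / cm$counts["lambda", norm_ids]
  }
  clon <- clonality_call(cm$counts["kappa", ], cm$counts["lambda", ],
                         polyclonal_ratios = poly,
                         sample_id = colnames(cm$counts))
  mut <- mut_marker_call(cm$counts["LDOC1", ], cm$counts["ADAM29", ],
                         cm$counts["LPL", ], absence_threshold, ratio_cut,
                         sample_id = colnames(cm$counts))
  merge(clon, mut, by = "sample_id", sort = FALSE,
        suffixes = c("_clonality", "_mut"))
}

#' Correlation between flow-cytometry protein measurements and mRNA counts
#'
#' @param cm normalized [count_matrix()].
#' @param sheet sample sheet with the percentage column.
#' @param gene gene id of the transcript.
#' @param field sheet column with the protein measurement (default
#'   `pct_cd38_pos`).
#' @param method `pearson` (default) or `spearman`.
#' @return list: `r`, `n`, `method`. Pairs with missing values are dropped;
#'   zero variance in either vector is an error.
#' @export
protein_mrna_correlation <- function(cm, sheet, gene,
                                     field = "pct_cd38_pos",
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  sheet <- sheet[match(colnames(cm$counts), sheet$sample_id), , drop = FALSE]
  x <- sheet[[field]]
  y <- cm$counts[gene, ]
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 3) stop("need >= 3 samples with both measurements")
  if (stats::sd(x[keep]) == 0 || stats::sd(y[keep]) == 0) {
    stop("zero variance: correlation undefined")
  }
  list(r = stats::cor(x[keep], y[keep], method = method), n = sum(keep),
       method = method)
}
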