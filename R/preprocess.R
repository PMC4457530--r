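#' Background-correct raw counts from negative-control probes
#'
#' For each sample the background threshold is the mean of the
#' negative-control counts plus two standard deviations (sample SD, n-1
#' denominator), computed per lane. Every non-negative-control count `c` is
#' replaced by `max(0, c - threshold)`; negative-control rows are retained
#' unchanged for audit. Results are fractional (no re-rounding).
#'
#' @param cm raw-stage [count_matrix()] with at least two negative-control
#'   probes.
#' @return the corrected `count_matrix` (stage `background_corrected`) whose
#'   `$background` element holds the per-sample background model
#'   (`neg_mean`, `neg_sd`, `threshold`).
#' @export
background_correct <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (cm$stage != "raw") stop("background_correct expects raw-stage counts")
  neg <- class_genes(cm, "negative")
  if (length(neg) < 2) {
    stop("need >= 2 negative-control probes to estimate background SD")
  }
  negm <- cm$counts[neg, , drop = FALSE]
  neg_mean <- colMeans(negm)
  neg_sd <- apply(negm, 2, stats::sd)
  threshold <- neg_mean + 2 * neg_sd
  corrected <- sweep(cm$counts, 2, threshold, `-`)
  corrected[corrected < 0] <- 0
  corrected[neg, ] <- cm$counts[neg, ]  # keep controls for audit
  out <- cm
  out$counts <- corrected
  out$stage <- "background_corrected"
  out$background <- data.frame(sample_id = colnames(cm$counts),
                               neg_mean = neg_mean, neg_sd = neg_sd,
                               threshold = threshold, row.names = NULL,
                               stringsAsFactors = FALSE)
  out
}

#' Rank candidate reference genes by geNorm stability
#'
#' The stability measure M of a candidate j is the mean, over all other
#' remaining candidates k, of the across-sample standard deviation of
#' log2(x_j / x_k). The least stable gene (highest M) is eliminated
#' iteratively until `n_select` genes remain; the final pair is never split.
#' Ties break lexicographically on gene id so the ranking is deterministic.
#' Counts at or below zero among candidates are replaced by `pseudo_count`
#' with a warning before taking log-ratios.
#'
#' @param cm a [count_matrix()] (any stage).
#' @param candidates candidate reference gene ids (default the platform's
#'   nine normalization candidates present in the matrix).
#' @param n_select number of reference genes to keep (>= 2).
#' @param pseudo_count replacement for nonpositive candidate counts.
#' @return a list of class `stability_ranking` with `selected` (sorted),
#'   `elimination` (data.frame: step, gene, M at elimination) and `m_values`
#'   (list of named M vectors, one per step, step 1 = all candidates).
#' @export
genorm_rank <- function(cm, candidates = NULL, n_select = 3,
                        pseudo_count = 0.5) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(candidates)) {
    candidates <- intersect(HK_CANDIDATES, rownames(cm$counts))
  }
  if (n_select < 2) stop("n_select must be >= 2")
  if (length(candidates) <= n_select) {
    stop("need more candidates than n_select")
  }
  missing <- setdiff(candidates, rownames(cm$counts))
  if (length(missing)) {
    stop("candidates absent from matrix: ", paste(missing, collapse = ", "))
  }
  x <- cm$counts[candidates, , drop = FALSE]
  if (any(x <= 0)) {
    warning("nonpositive candidate counts replaced by pseudo-count ",
            pseudo_count)
    x[x <= 0] <- pseudo_count
  }
  lg <- log2(x)
  m_of <- function(idx) {
    # M_j = mean_k sd_samples(log2 x_j - log2 x_k), k != j
    vapply(idx, function(j) {
      others <- setdiff(idx, j)
      mean(vapply(others, function(k) stats::sd(lg[j, ] - lg[k, ]), 0))
    }, 0)
  }
  remaining <- candidates
  m_values <- list()
  elim <- data.frame(step = integer(), gene = character(), M = numeric(),
                     stringsAsFactors = FALSE)
  step <- 1L
  while (length(remaining) > n_select) {
    m <- m_of(remaining)
    names(m) <- remaining
    m_values[[step]] <- m
    # eliminate highest M; ties lexicographic so ranking is reproducible
    worst_m <- max(m)
    worst <- sort_genes(names(m)[m == worst_m])[1]
    elim <- rbind(elim, data.frame(step = step, gene = worst, M = worst_m,
                                   stringsAsFactors = FALSE))
    remaining <- setdiff(remaining, worst)
    step <- step + 1L
  }
  m <- m_of(remaining)
  names(m) <- remaining
  m_values[[step]] <- m
  structure(list(candidates = candidates, selected = sort_genes(remaining),
                 elimination = elim, m_values = m_values),
            class = "stability_ranking")
}

#' @export
print.stability_ranking <- function(x, ...) {
  cat("geNorm stability ranking\n")
  cat("selected:", paste(x$selected, collapse = ", "), "\n")
  if (nrow(x$elimination)) {
    cat("eliminated (first = least stable):\n")
    for (i in seq_len(nrow(x$elimination))) {
      cat(sprintf("  %d. %s (M = %.4f)\n", x$elimination$step[i],
                  x$elimination$gene[i], x$elimination$M[i]))
    }
  }
  invisible(x)
}

#' Normalize counts by the geometric mean of reference genes
#'
#' Per sample s, g_s is the geometric mean of the reference-gene counts and
#' the normalization factor is f_s = G / g_s with G the geometric mean of
#' the g_s across samples, so the factors themselves have geometric mean 1
#' (a scale-stable anchor that makes re-normalization idempotent). All
#' counts in sample s are multiplied by f_s.
#'
#' @param cm background-corrected [count_matrix()].
#' @param hk_genes reference gene ids; must have positive counts in every
#'   sample.
#' @return the normalized `count_matrix` whose `$norm_factors` element holds
#'   per-sample factors, the reference geometric mean and the gene list.
#' @export
normalize_counts <- function(cm, hk_genes) {
  stopifnot(inherits(cm, "count_matrix"))
  missing <- setdiff(hk_genes, rownames(cm$counts))
  if (length(missing)) {
    stop("reference genes absent from matrix: ",
         paste(missing, collapse = ", "))
  }
  hk <- cm$counts[hk_genes, , drop = FALSE]
  if (any(hk <= 0)) {
    bad <- colnames(hk)[colSums(hk <= 0) > 0]
    stop("nonpositive reference-gene counts in samples ",
         paste(bad, collapse = ", "),
         "; reselect references or use a pseudo-count upstream")
  }
  g_s <- apply(hk, 2, geomean)
  G <- geomean(g_s)
  factors <- G / g_s
  out <- cm
  out$counts <- sweep(cm$counts, 2, factors, `*`)
  out$stage <- "normalized"
  out$norm_factors <- list(
    factors = data.frame(sample_id = colnames(cm$counts), factor = factors,
                         hk_geomean = g_s, row.names = NULL,
                         stringsAsFactors = FALSE),
    reference_geomean = G, hk_genes = hk_genes)
  out
}

#' QC linearity check on positive-control probes
#'
#' Fits, per sample, a straight line of log2 counts against log2 nominal
#' concentration (parsed from probe names of the form `POS_A(128)`) and
#' flags samples whose R-squared falls below `r2_floor`. Advisory only:
#' nothing is dropped.
#'
#' @param cm raw-stage [count_matrix()] with >= 3 positive-control probes.
#' @param r2_floor flag threshold on R-squared.
#' @return data.frame: sample_id, slope, r_squared, flagged.
#' @export
qc_positive_controls <- function(cm, r2_floor = 0.95) {
  stopifnot(inherits(cm, "count_matrix"))
  pos <- class_genes(cm, "positive")
  conc <- suppressWarnings(as.numeric(sub("^.*\\(([0-9.]+)\\)$", "\\1", pos)))
  keep <- !is.na(conc) & conc > 0
  if (sum(keep) < 3) {
    warning("fewer than 3 positive controls with nominal concentrations; QC skipped")
    return(data.frame(sample_id = colnames(cm$counts), slope = NA_real_,
                      r_squared = NA_real_, flagged = NA,
                      stringsAsFactors = FALSE))
  }
  pos <- pos[keep]
  lx <- log2(conc[keep])
  fit_one <- function(y) {
    ly <- log2(pmax(y, 0.5))
    slope <- stats::cov(lx, ly) / stats::var(lx)
    r2 <- if (stats::var(ly) == 0) 0 else stats::cor(lx, ly)^2
    c(slope, r2)
  }
  fits <- apply(cm$counts[pos, , drop = FALSE], 2, fit_one)
  data.frame(sample_id = colnames(cm$counts), slope = fits[1, ],
             r_squared = fits[2, ], flagged = fits[2, ] < r2_floor,
             row.names = NULL, stringsAsFactors = FALSE)
}
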