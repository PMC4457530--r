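test_that("PCA embedding matches an eigendecomposition oracle", {
  set.seed(19)
  counts <- matrix(rpois(60, 500), 10, 6,
                   dimnames = list(paste0("G", 1:10), paste0("s", 1:6)))
  counts <- rbind(counts, HK1 = rep(100, 6), `NEG_A(0)` = 1, `NEG_B(0)` = 2)
  cm <- tiny_cm(counts, stage = "normalized")
  emb <- embed_pca(cm, paste0("G", 1:10), n_components = 3)

  # oracle: covariance eigendecomposition of the same transform
  x <- log2(counts[paste0("G", 1:10), ] + 1)
  z <- t((x - rowMeans(x)) / apply(x, 1, sd))
  # prcomp(center = FALSE) decomposes crossprod(z)/(n-1); z is centered per
  # gene, not per sample, so the oracle uses crossprod directly
  eg <- eigen(crossprod(z) / (nrow(z) - 1))
  k <- 3
  expect_equal(emb$explained_variance[1:k], eg$values[1:k], tolerance = 1e-8)
  for (j in 1:k) {
    expect_equal(abs(unname(emb$scores[, j])),
                 abs(unname(z %*% eg$vectors[, j])[, 1]), tolerance = 1e-8)
  }
  # deterministic sign convention: dominant loading positive
  for (j in 1:k) {
    l <- emb$loadings[, j]
    expect_gte(l[which.max(abs(l))], 0)
  }
  # variances nonincreasing and summing to total variance
  expect_true(all(diff(emb$explained_variance) <= 1e-9))
  expect_equal(sum(emb$explained_variance), sum(diag(crossprod(z))) / (nrow(z) - 1),
               tolerance = 1e-9)
})

test_that("two point-clusters load entirely on the first component", {
  counts <- rbind(G1 = c(10, 10, 10, 1000, 1000, 1000),
                  G2 = rep(c(20, 21), 3),
                  HK1 = rep(50, 6), `NEG_A(0)` = 0, `NEG_B(0)` = 0)
  colnames(counts) <- paste0("s", 1:6)
  cm <- tiny_cm(counts, stage = "normalized")
  emb <- embed_pca(cm, "G1", n_components = 1)
  expect_equal(emb$prop_variance[1], 1)
  expect_equal(unname(emb$scores[1:3, 1]), -unname(emb$scores[4:6, 1]),
               tolerance = 1e-9)
  # constant genes are dropped with a warning
  counts2 <- counts; counts2["G2", ] <- 7
  cm2 <- tiny_cm(counts2, stage = "normalized")
  expect_warning(embed_pca(cm2, c("G1", "G2")), "constant")
})

test_that("CLL and normal samples separate on PC1 of the core genes", {
  co <- cached_cohort(101)
  sub <- co$sheet[co$sheet$group %in% c("CLL", "normal_PB", "pure_B"), ]
  emb <- embed_pca(subset_samples(co$normalized, sub$sample_id),
                   co$truth$panels$cll_core)
  labels <- as.integer(sub$group == "CLL") + 1L
  sil <- cluster::silhouette(labels, dist(emb$scores[, 1]))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  # PC1 linearly separates the two groups
  cll_pc1 <- emb$scores[sub$group == "CLL", 1]
  norm_pc1 <- emb$scores[sub$group != "CLL", 1]
  expect_true(min(cll_pc1) > max(norm_pc1) || max(cll_pc1) < min(norm_pc1))
})

test_that("cluster classification is exact on separated groups and invariant to ordering", {
  set.seed(23)
  n <- 20
  counts <- matrix(rpois(5 * n, 100), 5, n,
                   dimnames = list(paste0("G", 1:5), paste0("s", 1:n)))
  counts[, 11:20] <- counts[, 11:20] * 8
  counts <- rbind(counts, HK1 = rep(100, n), `NEG_A(0)` = 1, `NEG_B(0)` = 2)
  cm <- tiny_cm(counts, stage = "normalized")
  sheet <- sample_sheet(colnames(counts), rep(c("normal_PB", "CLL"), each = 10))
  rep1 <- cluster_classify(cm, paste0("G", 1:5), sheet)
  expect_equal(rep1$accuracy, 1)
  expect_equal(rep1$sensitivity, 1)
  expect_equal(rep1$specificity, 1)
  expect_identical(rep1$positive, "CLL")
  expect_equal(sum(rep1$confusion), n)

  # permuting sample order leaves the accuracy unchanged
  perm <- sample(n)
  rep2 <- cluster_classify(subset_samples(cm, colnames(counts)[perm]),
                           paste0("G", 1:5), sheet[perm, ])
  expect_equal(rep2$accuracy, rep1$accuracy)
  # relabeling the truth classes leaves the accuracy unchanged
  sheet3 <- sheet
  sheet3$group <- ifelse(sheet$group == "CLL", "normal_PB", "CLL")
  rep3 <- cluster_classify(cm, paste0("G", 1:5), sheet3)
  expect_equal(rep3$accuracy, rep1$accuracy)

  # three truth classes is an explicit error
  sheet4 <- sheet; sheet4$group[1:3] <- "MCL"
  expect_error(cluster_classify(cm, paste0("G", 1:5), sheet4),
               "one-vs-rest")
})

test_that("random labels cannot score above chance structure", {
  set.seed(29)
  n <- 20
  counts <- matrix(rpois(5 * n, 100), 5, n,
                   dimnames = list(paste0("G", 1:5), paste0("s", 1:n)))
  counts[, 11:20] <- counts[, 11:20] * 8
  counts <- rbind(counts, HK1 = rep(100, n), `NEG_A(0)` = 1, `NEG_B(0)` = 2)
  cm <- tiny_cm(counts, stage = "normalized")
  accs <- replicate(50, {
    labs <- sample(rep(c("normal_PB", "CLL"), each = 10))
    sheet <- sample_sheet(colnames(counts), labs)
    cluster_classify(cm, paste0("G", 1:5), sheet)$accuracy
  })
  expect_true(all(accs <= 1))
  expect_lt(mean(accs), 0.8)  # far below the separated-label accuracy of 1
  expect_gte(min(accs), 0.5)  # best-of-two cluster mapping floor
})

test_that("nearest-centroid prediction labels held-out samples", {
  set.seed(31)
  n <- 16
  counts <- matrix(rpois(4 * n, 80), 4, n,
                   dimnames = list(paste0("G", 1:4), paste0("s", 1:n)))
  counts[, 9:16] <- counts[, 9:16] * 10
  counts <- rbind(counts, HK1 = rep(100, n), `NEG_A(0)` = 1, `NEG_B(0)` = 2)
  cm <- tiny_cm(counts, stage = "normalized")
  sheet <- sample_sheet(colnames(counts), rep(c("normal_PB", "CLL"), each = 8))
  train_ids <- colnames(counts)[c(1:6, 9:14)]
  test_ids <- setdiff(colnames(counts), train_ids)
  pred <- centroid_classify(subset_samples(cm, train_ids),
                            paste0("G", 1:4),
                            sheet[match(train_ids, sheet$sample_id), ],
                            subset_samples(cm, test_ids))
  truth <- sheet$group[match(test_ids, sheet$sample_id)]
  expect_identical(pred$predicted, truth)
})

test_that("clonality calls follow the reference interval", {
  # the published polyclonal interval: 0.89 +/- 2*0.22 = [0.45, 1.33]
  eq <- clonality_call(1000, 1000)
  expect_equal(eq$interval_low, 0.45)
  expect_equal(eq$interval_high, 1.33)
  expect_identical(eq$call, "polyclonal")
  expect_identical(clonality_call(50000, 1000)$call, "monoclonal_kappa")
  expect_identical(clonality_call(1000, 50000)$call, "monoclonal_lambda")
  z <- clonality_call(0, 0)
  expect_identical(z$call, "indeterminate")
  expect_identical(z$flag, "both_chains_zero")
  inf <- clonality_call(500, 0)
  expect_identical(inf$call, "monoclonal_kappa")
  expect_identical(inf$flag, "lambda_zero")
  # estimated reference from polyclonal ratios
  est <- clonality_call(100, 100, polyclonal_ratios = c(0.8, 1.0, 1.2))
  expect_equal(est$interval_low, 1 - 2 * sd(c(0.8, 1, 1.2)))

  # symmetric interval about 1: swapping chains mirrors the call
  swap <- c(monoclonal_kappa = "monoclonal_lambda",
            monoclonal_lambda = "monoclonal_kappa",
            polyclonal = "polyclonal", indeterminate = "indeterminate")
  for (k in c(10, 900, 1100, 3000, 120000)) {
    a <- clonality_call(k, 1000, ref_mean = 1, ref_sd = 0.2)$call
    b <- clonality_call(1000, k, ref_mean = 1, ref_sd = 0.2)$call
    expect_identical(unname(swap[a]), b)
  }
  # with the published asymmetric interval the mirror holds for
  # ratio -> mid^2/ratio across the geometric midpoint of the endpoints
  mid2 <- 0.45 * 1.33
  for (r in c(0.1, 0.4, 0.7, 2, 40)) {
    a <- clonality_call(r * 1000, 1000)$call
    b <- clonality_call(mid2 / r * 1000, 1000)$call
    expect_identical(unname(swap[a]), b)
  }
})

test_that("marker trichotomy and LPL/ADAM29 surrogate behave per thresholds", {
  # printed LDOC1-positive group: LDOC1 483 vs ADAM29 2
  hi <- mut_marker_call(483, 2, 1331)
  expect_identical(hi$trichotomy, "ldoc1_high")
  expect_identical(hi$lpl_call, "unmutated_like")
  # printed mutated-group means: ADAM29 1061, LPL 91
  mu <- mut_marker_call(7, 1061, 91)
  expect_identical(mu$trichotomy, "adam29_high")
  expect_equal(mu$lpl_adam29_ratio, 91 / 1061, tolerance = 1e-12)
  expect_identical(mu$lpl_call, "mutated_like")
  dn <- mut_marker_call(0, 0, 200)
  expect_identical(dn$trichotomy, "double_negative")
  expect_identical(dn$lpl_call, "indeterminate")
  expect_identical(dn$flag, "adam29_zero_pseudocount")
  # monotone: raising LPL never flips unmutated_like -> mutated_like
  lpls <- seq(0, 5000, by = 250)
  calls <- mut_marker_call(7, 1061, lpls)$lpl_call
  first_unmut <- match("unmutated_like", calls)
  if (!is.na(first_unmut)) {
    expect_true(all(calls[first_unmut:length(calls)] == "unmutated_like"))
  }
})

test_that("protein/mRNA correlation matches the closed-form estimator", {
  x <- c(5, 20, 35, 60, 90)
  y <- c(120, 340, 500, 880, 1500)
  counts <- rbind(CD38 = y, HK1 = rep(100, 5), `NEG_A(0)` = 0,
                  `NEG_B(0)` = 0)
  colnames(counts) <- paste0("s", 1:5)
  cm <- tiny_cm(counts, stage = "normalized")
  sheet <- sample_sheet(colnames(counts), "CLL", pct_cd38_pos = x)
  got <- protein_mrna_correlation(cm, sheet, "CD38")
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  expect_equal(got$n, 5)
  # exactly linear counts give r = 1
  cm2 <- cm; cm2$counts["CD38", ] <- 10 * x + 3
  expect_equal(protein_mrna_correlation(cm2, sheet, "CD38")$r, 1)
  # zero variance is an error
  sheet0 <- sheet; sheet0$pct_cd38_pos <- rep(50, 5)
  expect_error(protein_mrna_correlation(cm, sheet0, "CD38"), "variance")
})
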