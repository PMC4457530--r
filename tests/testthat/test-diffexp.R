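toy_comparison <- function(a, b) {
  # single-gene comparison built from explicit vectors
  counts <- rbind(G1 = c(a, b), HK1 = rep(100, length(a) + length(b)),
                  `NEG_A(0)` = 0, `NEG_B(0)` = 0)
  colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  cm <- tiny_cm(counts, stage = "normalized")
  sheet <- sample_sheet(colnames(counts),
                        c(rep("normal_PB", length(a)),
                          rep("CLL", length(b))))
  compare_groups(cm, sheet, "normal_PB", "CLL", genes = "G1")
}

test_that("pooled t-test matches stats::t.test and handles degeneracy", {
  a <- c(10, 12, 14); b <- c(20, 22, 24)
  tab <- toy_comparison(a, b)
  ref <- t.test(b, a, var.equal = TRUE)
  expect_equal(tab$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tab$p, ref$p.value, tolerance = 1e-12)
  expect_equal(tab$mean_a, mean(a))
  expect_equal(tab$sd_b, sd(b))
  expect_equal(tab$ratio, mean(b) / mean(a))

  # identical constant groups: ratio 1, zero-variance flag, p reported as 1
  tab0 <- toy_comparison(c(5, 5, 5), c(5, 5, 5))
  expect_equal(tab0$ratio, 1)
  expect_true(tab0$zero_variance)
  expect_equal(tab0$p, 1)

  # Welch mode agrees with t.test(var.equal = FALSE)
  counts <- rbind(G1 = c(a, b), HK1 = 100, `NEG_A(0)` = 0, `NEG_B(0)` = 0)
  colnames(counts) <- paste0("s", 1:6)
  cm <- tiny_cm(counts, stage = "normalized")
  sheet <- sample_sheet(colnames(counts), rep(c("normal_PB", "CLL"), each = 3))
  tw <- compare_groups(cm, sheet, "normal_PB", "CLL", genes = "G1",
                       var_equal = FALSE)
  refw <- t.test(b, a)
  expect_equal(tw$p, refw$p.value, tolerance = 1e-12)

  expect_error(toy_comparison(c(1, 2), 5), ">= 2 samples")
})

test_that("cascade survivors match an exhaustive flag oracle", {
  # eight genes spanning all 2^3 combinations of floor/fc/p outcomes
  grid <- expand.grid(floor_ok = c(TRUE, FALSE), fc_ok = c(TRUE, FALSE),
                      p_ok = c(TRUE, FALSE))
  tab <- data.frame(
    gene = sprintf("G%d", seq_len(nrow(grid))),
    mean_a = 10,
    mean_b = ifelse(grid$floor_ok, 100, 49),
    sd_a = 1, sd_b = 1,
    ratio = ifelse(grid$fc_ok, 2.5, 1.5),
    t = 1,
    p = ifelse(grid$p_ok, 0.01, 0.2),
    zero_variance = FALSE, stringsAsFactors = FALSE)
  got <- apply_cascade(tab, floor = 50, fc = 2, alpha = 0.05,
                       direction = "up_in_b")
  oracle <- character()
  for (i in seq_len(nrow(tab))) {
    if (tab$mean_b[i] >= 50 && tab$ratio[i] >= 2 && tab$p[i] <= 0.05) {
      oracle <- c(oracle, tab$gene[i])
    }
  }
  expect_identical(as.character(got), sort(oracle))
  flags <- attr(got, "flags")
  expect_identical(flags$pass_floor, grid$floor_ok)
  expect_identical(flags$pass_fc, grid$fc_ok)
  expect_identical(flags$pass_p, grid$p_ok)

  # a gene below the floor is excluded regardless of ratio and p
  low <- tab; low$mean_b <- 49; low$ratio <- 100; low$p <- 1e-9
  expect_length(apply_cascade(low, direction = "up_in_b"), 0)
})

test_that("up and down cascades are mirror images under group swap", {
  set.seed(33)
  counts <- rbind(matrix(rpois(60, 300), 6, 10,
                         dimnames = list(paste0("G", 1:6), NULL)),
                  HK1 = rep(100, 10), `NEG_A(0)` = 1, `NEG_B(0)` = 2)
  colnames(counts) <- paste0("s", 1:10)
  counts[1:3, 6:10] <- counts[1:3, 6:10] * 5  # up in group B
  cm <- tiny_cm(counts, stage = "normalized")
  sheet <- sample_sheet(colnames(counts), rep(c("normal_PB", "CLL"), each = 5))
  ab <- compare_groups(cm, sheet, "normal_PB", "CLL")
  ba <- compare_groups(cm, sheet, "CLL", "normal_PB")
  expect_identical(as.character(apply_cascade(ab, direction = "down_in_b")),
                   as.character(apply_cascade(ba, direction = "up_in_b")))
  expect_identical(as.character(apply_cascade(ab, direction = "up_in_b")),
                   as.character(apply_cascade(ba, direction = "down_in_b")))

  # monotone in thresholds: tightening any knob never adds a gene
  base <- apply_cascade(ab, floor = 50, fc = 2, alpha = 0.05, "up_in_b")
  for (args in list(list(floor = 200), list(fc = 4), list(alpha = 0.01))) {
    tighter <- do.call(apply_cascade,
                       c(list(ab, direction = "up_in_b"), args))
    expect_true(all(tighter %in% base))
  }
})

test_that("gene-list set algebra is exact and lexicographically ordered", {
  expect_identical(gene_set_op(list(c("a", "b", "c"), c("b", "c", "d")),
                               "intersect"), c("b", "c"))
  expect_identical(gene_set_op(list(c("x", "a"), c("q")), "union"),
                   c("a", "q", "x"))
  expect_identical(gene_set_op(list(c("a", "b"), c("c")), "intersect"),
                   character(0))
  expect_identical(gene_set_op(list(c("a", "b", "c"), c("b"), c("c")),
                               "difference"), "a")
})

test_that("CV filter applies the strict cutoff and flags zero means", {
  counts <- rbind(G1 = c(100, 200), G2 = c(100, 100), G3 = c(10, 300),
                  G4 = c(0, 0), HK1 = c(100, 100), `NEG_A(0)` = 0,
                  `NEG_B(0)` = 0)
  colnames(counts) <- c("s1", "s2")
  cm <- tiny_cm(counts, stage = "normalized")
  sheet <- sample_sheet(c("s1", "s2"), c("CLL", "CLL"))
  kept <- cv_filter(cm, sheet, paste0("G", 1:4), "CLL", cv_max = 0.5)
  cvs <- attr(kept, "cv")
  expect_equal(cvs$cv[1], sd(c(100, 200)) / 150)  # ~0.4714, kept
  expect_identical(as.character(kept), c("G1", "G2"))  # G2 constant: CV 0
  expect_true(cvs$zero_mean[4])
  expect_true(is.na(cvs$cv[4]))
})

test_that("derived signatures recover the planted panels on a synthetic cohort", {
  co <- cached_cohort(101)
  sigs <- suppressWarnings(derive_signatures(co$normalized, co$sheet))
  tr <- co$truth$signatures
  # the homogeneous core is exactly the planted low-noise CLL panel
  expect_identical(as.character(sigs$Core$genes), tr$Core)
  expect_identical(tr$Core, co$truth$panels$cll_core)
  # diagnostic signature: no false members, full recovery of the
  # homogeneous half; the high-variance genes are underpowered at the
  # study's small normal groups, so only partial recovery is expected there
  expect_lte(length(setdiff(sigs$Diag$genes, tr$Diag)), 2)
  expect_true(all(tr$Core %in% sigs$Diag$genes))
  expect_gte(length(intersect(sigs$Diag$genes, tr$Diag)),
             0.6 * length(tr$Diag))
  # underexpressed list matches the planted panel almost exactly
  expect_true(length(intersect(sigs$CLL_under$genes, tr$CLL_under)) >=
                length(tr$CLL_under) - 1)
  # provenance records thresholds
  expect_equal(sigs$Diag$provenance$floor, 50)
  expect_equal(sigs$Core$provenance$cv_max, 0.5)
})

test_that("signatures needing absent groups are skipped, others still derived", {
  co <- cached_cohort(101)
  keep <- co$sheet$group != "pure_B"
  sheet <- co$sheet[keep, ]
  cm <- subset_samples(co$normalized, sheet$sample_id)
  warns <- capture_warnings(sigs <- derive_signatures(cm, sheet))
  expect_true(any(grepl("skipped", warns)))
  expect_null(sigs$B_cell)
  expect_null(sigs$Diag)
  expect_null(sigs$CLL_under)
  expect_gt(length(sigs$Mut$genes), 0)
  expect_gt(length(sigs$CLL_vs_PB_up$genes), 0)
})
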