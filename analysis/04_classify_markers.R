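#!/usr/bin/env Rscript
# Classification and ratio markers: PCA embedding on the diagnostic
# signature, unsupervised two-class clustering (CLL vs normals on the core
# genes, mutated vs unmutated on the mutation panel, CLL vs pooled B-CLPD
# on the CLL panel), and the per-sample kappa/lambda clonality and
# LDOC1/ADAM29/LPL marker calls.

library(lymphsig)

fx <- read_fixture("results/cohort")
bc <- background_correct(fx$counts)
norm <- normalize_counts(bc, genorm_rank(bc)$selected)
truth <- jsonlite::read_json("results/cohort/truth.json",
                             simplifyVector = TRUE)
sheet <- fx$sheet

emb <- embed_pca(norm, truth$panels$cll, n_components = 3)
write.csv(data.frame(sample_id = rownames(emb$scores), emb$scores,
                     group = sheet$group[match(rownames(emb$scores),
                                               sheet$sample_id)]),
          "results/run/pca_coordinates.csv", row.names = FALSE)
cat("PCA on the CLL panel: PC1 explains",
    round(100 * emb$prop_variance[1], 1), "% of variance\n")

norms <- sheet[sheet$group %in% c("CLL", "normal_PB", "pure_B"), ]
norms$truth2 <- ifelse(norms$group == "CLL", "CLL", "normal")
r1 <- cluster_classify(subset_samples(norm, norms$sample_id),
                       truth$panels$cll_core, norms, truth_field = "truth2")
cat("CLL vs normal clustering on the 13 core genes: accuracy",
    round(r1$accuracy, 3), "\n")

mut <- sheet[sheet$group == "CLL" &
               sheet$igvh_status %in% c("mutated", "unmutated"), ]
r2 <- cluster_classify(subset_samples(norm, mut$sample_id),
                       truth$panels$mut, mut, truth_field = "igvh_status")
cat("mutated vs unmutated clustering on the mutation panel: accuracy",
    round(r2$accuracy, 3), "\n")

pool <- sheet[sheet$group %in% c("CLL", "MCL", "MZL", "FL", "HCL"), ]
pool$truth2 <- ifelse(pool$group == "CLL", "CLL", "B_CLPD")
r3 <- cluster_classify(subset_samples(norm, pool$sample_id),
                       truth$panels$cll, pool, truth_field = "truth2")
cat("CLL vs pooled B-CLPD on the CLL panel: accuracy",
    round(r3$accuracy, 3), "sensitivity", round(r3$sensitivity, 3),
    "specificity", round(r3$specificity, 3), "\n")
write.csv(rbind(cbind(task = "cll_vs_normal", r1$calls),
                cbind(task = "mut_vs_unmut", r2$calls),
                cbind(task = "cll_vs_bclpd", r3$calls)),
          "results/run/classification_calls.csv", row.names = FALSE)

mk <- marker_calls(norm, sheet)
write.csv(mk, "results/run/marker_calls.csv", row.names = FALSE)
cll_mk <- mk[sheet$group[match(mk$sample_id, sheet$sample_id)] == "CLL", ]
cat("CLL clonality calls:", sum(cll_mk$call != "polyclonal"), "of",
    nrow(cll_mk), "monoclonal\n")
print(table(cll_mk$trichotomy))
igvh <- sheet$igvh_status[match(cll_mk$sample_id, sheet$sample_id)]
conc <- (igvh == "unmutated" & cll_mk$lpl_call == "unmutated_like") |
  (igvh == "mutated" & cll_mk$lpl_call == "mutated_like")
cat("LPL/ADAM29 concordance with IgVH status:",
    sum(conc[igvh %in% c("mutated", "unmutated")]), "of",
    sum(igvh %in% c("mutated", "unmutated")), "\n")

cd38 <- protein_mrna_correlation(norm, sheet, "CD38")
cat("CD38 protein/mRNA Pearson r:", round(cd38$r, 2), "(n =", cd38$n, ")\n")
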