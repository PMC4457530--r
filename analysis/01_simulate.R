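#!/usr/bin/env Rscript
# Generate the synthetic study cohort: 5 normal PB, 4 pure B-cell and 30 CLL
# samples (11 mutated / 17 unmutated / 2 borderline IgVH) plus the 51-sample
# B-CLPD validation series, with panels seeded from the published summary
# tables. Writes the cohort fixture under results/cohort/.

library(lymphsig)

cfg <- sim_config(seed = 1)
cohort <- generate_cohort(cfg)
write_fixture(cohort, "results/cohort")

cat("cohort:", nrow(cohort$counts$counts), "probes x",
    ncol(cohort$counts$counts), "samples\n")
print(table(cohort$sheet$group))
cat("planted CLL panel:", length(cohort$truth$panels$cll), "genes (",
    length(cohort$truth$panels$cll_core), "homogeneous )\n")
cat("planted mutation panel:", length(cohort$truth$panels$mut), "genes\n")
cat("fixture written to results/cohort\n")
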