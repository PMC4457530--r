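#!/usr/bin/env Rscript
# Derive the gene signatures through the filter cascade (floor 50 counts,
# 2-fold change, p <= 0.05, pooled t-test) and the CV < 0.5 homogeneity
# filter, and render the report-style comparison tables. Compares the
# derived lists against the generator's planted truth.

library(lymphsig)

fx <- read_fixture("results/cohort")
bc <- background_correct(fx$counts)
norm <- normalize_counts(bc, genorm_rank(bc)$selected)

sigs <- suppressWarnings(derive_signatures(norm, fx$sheet))
print(sigs)
jsonlite::write_json(
  lapply(unclass(sigs), function(s) list(name = s$name, genes = s$genes,
                                         provenance = s$provenance)),
  "results/run/signatures.json", auto_unbox = TRUE, digits = NA)

truth <- jsonlite::read_json("results/cohort/truth.json",
                             simplifyVector = TRUE)
for (nm in intersect(names(sigs), names(truth$signatures))) {
  t <- truth$signatures[[nm]]; d <- sigs[[nm]]$genes
  cat(sprintf("%-16s planted %3d derived %3d recovered %3d spurious %d\n",
              nm, length(t), length(d), length(intersect(d, t)),
              length(setdiff(d, t))))
}

paths <- render_tables(norm, fx$sheet, "results/run/tables")
cat("report tables:", paste(basename(paths), collapse = ", "), "\n")
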