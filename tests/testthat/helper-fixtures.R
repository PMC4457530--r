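# Shared fixture builders. Cohorts are memoized per (config key, seed) so
# multi-seed tests do not regenerate identical cohorts across test files.

.fixture_cache <- new.env(parent = emptyenv())

# a minimal count matrix: 2 negative controls, 2 housekeeping, rest endogenous
tiny_cm <- function(counts, stage = "raw") {
  genes <- rownames(counts)
  cls <- rep("endogenous", length(genes))
  cls[grepl("^NEG", genes)] <- "negative"
  cls[grepl("^POS", genes)] <- "positive"
  cls[grepl("^HK", genes)] <- "housekeeping"
  count_matrix(counts, probe_def(genes, cls), stage = stage)
}

# write a plausible RCC lane file
write_rcc_file <- function(path, genes, classes, counts, sample_id = NULL) {
  lines <- c("<Header>", "FileVersion,1.7", "SoftwareVersion,4.0.0.3",
             "</Header>")
  if (!is.null(sample_id)) {
    lines <- c(lines, "<Sample_Attributes>", paste0("ID,", sample_id),
               "Owner,", "</Sample_Attributes>")
  }
  lines <- c(lines, "<Lane_Attributes>", "ID,1", "</Lane_Attributes>",
             "<Code_Summary>", "CodeClass,Name,Accession,Count",
             sprintf("%s,%s,ACC,%d", classes, genes, counts),
             "</Code_Summary>")
  writeLines(lines, path)
  path
}

# default study-sized cohort (or a variant), memoized, with preprocessing
cached_cohort <- function(seed, groups = NULL) {
  key <- paste0("s", seed, "_", paste(groups, collapse = "-"))
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cfg <- if (is.null(groups)) sim_config(seed = seed) else
    sim_config(groups = groups, seed = seed)
  co <- generate_cohort(cfg)
  bc <- background_correct(co$counts)
  rk <- genorm_rank(bc)
  co$normalized <- normalize_counts(bc, rk$selected)
  co$ranking <- rk
  .fixture_cache[[key]] <- co
  co
}
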