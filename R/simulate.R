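#' Configuration for the synthetic nCounter cohort generator
#'
#' Defaults emulate the study cohort: 5 normal peripheral-blood samples, 4
#' purified B-cell samples, 30 CLL samples (11 IgVH-mutated, 17 unmutated,
#' 2 borderline) and, by default, the 51-sample B-CLPD validation series
#' (20 MCL, 22 MZL, 4 FL, 5 HCL). Gene panels and their group fold changes
#' are seeded from the published per-gene summary tables (see
#' [printed_table()]): a B-cell panel (printed normal-PB means and pure-B
#' ratios), a CLL panel of 13 homogeneous plus 12 heterogeneous genes
#' (printed CLL means), an underexpressed panel (printed CLL/pure-B fold
#' changes), and the 24-gene mutation-status panel (printed mutated and
#' unmutated means), with LDOC1/ADAM29/LPL modeled per sample through the
#' trichotomy classes including a five-sample double-negative subgroup.
#' Light chains are monoclonally skewed (50-fold minor-chain suppression)
#' in clonal samples. Noise is multiplicative log-normal per panel plus a
#' log-normal per-sample size factor; negative controls are Poisson;
#' positive controls are proportional to nominal concentration.
#'
#' @param groups named integer vector of samples per group.
#' @param cll_split named integer vector (`mutated`, `unmutated`,
#'   `borderline`) summing to `groups["CLL"]`.
#' @param n_both_absent named integer vector (`mutated`, `unmutated`):
#'   double-negative LDOC1/ADAM29 samples per IgVH class.
#' @param kappa_clone_prob probability a clonal sample is a kappa clone.
#' @param minor_chain_suppression fold suppression of the minor light chain.
#' @param size_factor_sd log-scale SD of per-sample size factors.
#' @param sigma named list of per-panel log-noise SDs.
#' @param neg_lambda Poisson mean of negative-control probes.
#' @param fc_cll fold change of CLL-panel genes over normal groups.
#' @param n_filler unregulated filler genes, padding the code set towards
#'   the platform's 290 endogenous probes.
#' @param seed base seed of the hierarchical substreams.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(groups = c(normal_PB = 5, pure_B = 4, CLL = 30,
                                  MCL = 20, MZL = 22, FL = 4, HCL = 5),
                       cll_split = c(mutated = 11, unmutated = 17,
                                     borderline = 2),
                       n_both_absent = c(mutated = 2, unmutated = 3),
                       kappa_clone_prob = 0.6,
                       minor_chain_suppression = 50,
                       size_factor_sd = 0.2,
                       sigma = list(hk_stable = 0.01, hk_other = 0.04,
                                    bcell = 0.3, under = 0.3, core = 0.3,
                                    hetero = 0.8, mut = 0.3, marker = 0.3,
                                    light_chain = 0.17, filler = 0.4,
                                    pos_ctrl = 0.05),
                       neg_lambda = 5, fc_cll = 8, n_filler = 210,
                       seed = 1) {
  stopifnot(all(groups >= 0), sum(groups) > 0, neg_lambda > 0, fc_cll > 0,
            size_factor_sd >= 0, all(unlist(sigma) >= 0))
  if ("CLL" %in% names(groups) && groups[["CLL"]] > 0 &&
      sum(cll_split) != groups[["CLL"]]) {
    stop("cll_split must sum to the CLL group size")
  }
  if (sum(n_both_absent) > 0 &&
      (n_both_absent[["mutated"]] > cll_split[["mutated"]] ||
       n_both_absent[["unmutated"]] > cll_split[["unmutated"]])) {
    stop("n_both_absent exceeds the IgVH class sizes")
  }
  structure(list(groups = groups, cll_split = cll_split,
                 n_both_absent = n_both_absent,
                 kappa_clone_prob = kappa_clone_prob,
                 minor_chain_suppression = minor_chain_suppression,
                 size_factor_sd = size_factor_sd, sigma = sigma,
                 neg_lambda = neg_lambda, fc_cll = fc_cll,
                 n_filler = n_filler, seed = seed),
            class = "sim_config")
}

# panel tables seeded from the bundled printed summary tables; ids strip the
# alias part of compound probe names
sim_panels <- function(config) {
  strip <- function(x) sub("/.*$", "", x)
  t1 <- printed_table("table1")
  bsel <- c("CD19", "CD20", "CD22", "CD69", "CD79A", "CD79B", "CD83",
            "CD268/BAFF-R", "CD267/TACI", "CD180", "CD40/TNFRSF5", "PAX5",
            "EBF1", "SOX11", "IRF4", "JUN", "BCL2", "MYC", "IGHD")
  t1 <- t1[match(bsel, t1$gene), ]
  bcell <- data.frame(gene = strip(t1$gene), mu_pb = t1$mean_normal_pb,
                      fc_pure_b = t1$ratio, stringsAsFactors = FALSE)
  t2b <- printed_table("table2b")
  usel <- c("BANK1", "BIRC3", "CHL1", "CXCR4/SDF-1R", "EBI3", "IL6",
            "MMP12", "NREP", "TIMP4", "ZFP36")
  t2b <- t2b[match(usel, t2b$gene), ]
  under <- data.frame(gene = strip(t2b$gene), mu_pure_b = 2000,
                      fc_cll_vs_pure_b = t2b$fold_change_cll_vs_pure_b,
                      stringsAsFactors = FALSE)
  t2a <- printed_table("table2a")
  t2a$id <- strip(t2a$gene)
  core <- t2a[t2a$cv < 0.5, c("id", "mean_cll")]
  hsel <- c("BIK", "CD24", "CD269/BCMA", "CXCR3", "FGF2", "FGFR1",
            "FILIP1L", "FLT3", "FMOD", "IGFBP4", "IGSF3", "WNT3")
  hetero <- t2a[match(hsel, t2a$gene), c("id", "mean_cll")]
  t4 <- printed_table("table4")
  mut <- data.frame(gene = t4$gene, mean_mut = t4$mean_mutated,
                    mean_unmut = t4$mean_unmutated,
                    stringsAsFactors = FALSE)
  list(bcell = bcell, under = under,
       core = data.frame(gene = core$id, mean_cll = core$mean_cll,
                         stringsAsFactors = FALSE),
       hetero = data.frame(gene = hetero$id, mean_cll = hetero$mean_cll,
                           stringsAsFactors = FALSE),
       mut = mut, markers = c("LDOC1", "ADAM29", "LPL"),
       hk = data.frame(
         gene = c("RPL19", "RPLP0", "TPT1", "ACTB", "TBP", "G6PD",
                  "ABCF1", "B2M", "RPS23"),
         mu = c(25000, 30000, 40000, 60000, 800, 1500, 1200, 45000, 20000),
         stable = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                    FALSE), stringsAsFactors = FALSE))
}

#' Generate a synthetic nCounter cohort
#'
#' Counts follow `round(f_s * e_gs * exp(eps))` with `eps ~ N(0, sigma_g^2)`
#' and `f_s = exp(N(0, size_factor_sd^2))`, where `e_gs` is the planted
#' per-sample expectation (baseline mean times group fold change, with
#' per-sample overrides for light chains, LDOC1/ADAM29/LPL and the IgVH
#' panel). Negative controls are Poisson and unaffected by fold changes and
#' size factors; positive controls are proportional to nominal
#' concentration times the size factor. A single base seed feeds
#' hierarchical per-gene substreams, so the same seed gives bit-identical
#' cohorts and adding a gene does not reshuffle the others.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort`: `counts` (raw [count_matrix()]),
#'   `sheet` (sample sheet), `truth` (size factors, per-sample expectation
#'   matrix, per-gene sigma, panels, clonality and marker classes, truth
#'   signature sets, config).
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  panels <- sim_panels(config)
  sg <- config$sigma
  seed <- config$seed

  ## ---- samples ----
  grp_names <- names(config$groups)[config$groups > 0]
  sample_id <- character(); group <- character()
  for (g in grp_names) {
    n <- config$groups[[g]]
    pref <- c(normal_PB = "PB", pure_B = "B")[g]
    if (is.na(pref)) pref <- g
    sample_id <- c(sample_id, sprintf("%s_%02d", pref, seq_len(n)))
    group <- c(group, rep(g, n))
  }
  n_s <- length(sample_id)
  igvh <- rep("unknown", n_s)
  if ("CLL" %in% group) {
    cll_idx <- which(group == "CLL")
    igvh[cll_idx] <- rep(c("mutated", "unmutated", "borderline"),
                         times = config$cll_split)
  }

  ## ---- marker classes and clonality (seeded substreams) ----
  ldoc1_class <- rep(NA_character_, n_s)
  cll_idx <- which(group == "CLL")
  if (length(cll_idx)) {
    mut_i <- cll_idx[igvh[cll_idx] == "mutated"]
    unmut_i <- cll_idx[igvh[cll_idx] == "unmutated"]
    bl_i <- cll_idx[igvh[cll_idx] == "borderline"]
    absent <- with_substream(seed, "both_absent", function() {
      c(sample(mut_i, config$n_both_absent[["mutated"]]),
        sample(unmut_i, config$n_both_absent[["unmutated"]]))
    })
    ldoc1_class[mut_i] <- "adam29_high"
    ldoc1_class[unmut_i] <- "ldoc1_high"
    if (length(bl_i)) {
      ldoc1_class[bl_i] <- rep(c("ldoc1_high", "adam29_high"),
                               length.out = length(bl_i))
    }
    ldoc1_class[absent] <- "double_negative"
  }
  clonal <- group %in% c("CLL", "MCL", "MZL", "FL", "HCL")
  clone <- rep("polyclonal", n_s)
  clone[clonal] <- with_substream(seed, "clonality", function() {
    ifelse(stats::runif(sum(clonal)) < config$kappa_clone_prob,
           "kappa", "lambda")
  })

  ## ---- per-sample expectations ----
  endo <- character(); mu <- numeric(); sigma_g <- numeric()
  E <- NULL
  add_gene <- function(g, e_by_sample, s) {
    endo <<- c(endo, g); sigma_g <<- c(sigma_g, s)
    E <<- rbind(E, e_by_sample)
  }
  for (i in seq_len(nrow(panels$bcell))) {
    p <- panels$bcell[i, ]
    e <- p$mu_pb * ifelse(group == "normal_PB", 1, p$fc_pure_b)
    add_gene(p$gene, e, sg$bcell)  # all B-cell-rich groups share the level
  }
  for (i in seq_len(nrow(panels$under))) {
    p <- panels$under[i, ]
    e <- rep(p$mu_pure_b, n_s)
    e[group == "normal_PB"] <- p$mu_pure_b / 5
    e[group == "CLL"] <- p$mu_pure_b * p$fc_cll_vs_pure_b
    add_gene(p$gene, e, sg$under)
  }
  for (nm in c("core", "hetero")) {
    tab <- panels[[nm]]
    for (i in seq_len(nrow(tab))) {
      p <- tab[i, ]
      e <- rep(p$mean_cll / config$fc_cll, n_s)
      e[group == "CLL"] <- p$mean_cll
      add_gene(p$gene, e, sg[[nm]])
    }
  }
  # IgVH mutation-status panel: printed class means inside CLL; every other
  # group sits at the CLL-average level so the mutation contrast is isolated
  # from the diagnostic one. LDOC1/ADAM29 follow the trichotomy classes.
  marker_e <- list(
    LDOC1 = c(ldoc1_high = 450, adam29_high = 5, double_negative = 5),
    ADAM29 = c(ldoc1_high = 5, adam29_high = 1300, double_negative = 5))
  for (i in seq_len(nrow(panels$mut))) {
    p <- panels$mut[i, ]
    e <- rep(NA_real_, n_s)
    if (p$gene %in% names(marker_e)) {
      e[cll_idx] <- marker_e[[p$gene]][ldoc1_class[cll_idx]]
    } else {
      e[cll_idx] <- ifelse(igvh[cll_idx] == "mutated", p$mean_mut,
                           ifelse(igvh[cll_idx] == "unmutated", p$mean_unmut,
                                  sqrt(pmax(p$mean_mut, 1) *
                                         pmax(p$mean_unmut, 1))))
    }
    non_cll <- setdiff(seq_len(n_s), cll_idx)
    e[non_cll] <- if (length(cll_idx)) mean(e[cll_idx]) else
      mean(c(p$mean_mut, p$mean_unmut))
    s <- if (p$gene %in% panels$markers) sg$marker else sg$mut
    add_gene(p$gene, e, s)
  }
  # light chains: printed polyclonal means; clonal samples draw a dominant
  # chain with the minor chain suppressed
  kap <- lam <- rep(NA_real_, n_s)
  kap[group == "normal_PB"] <- 11354.34; lam[group == "normal_PB"] <- 17487.73
  kap[group == "pure_B"] <- 70720.31;    lam[group == "pure_B"] <- 64435.64
  dom <- ifelse(group == "CLL", 130000, 60000)
  kap[clonal] <- ifelse(clone[clonal] == "kappa", dom[clonal],
                        dom[clonal] / config$minor_chain_suppression)
  lam[clonal] <- ifelse(clone[clonal] == "lambda", dom[clonal] * 1.2,
                        dom[clonal] * 1.2 / config$minor_chain_suppression)
  add_gene("kappa", kap, sg$light_chain)
  add_gene("lambda", lam, sg$light_chain)
  # filler genes: unregulated, baseline drawn once per gene
  filler_mu <- with_substream(seed, "filler_mu", function() {
    round(exp(stats::runif(config$n_filler, log(50), log(5000))))
  })
  for (i in seq_len(config$n_filler)) {
    add_gene(sprintf("FILL%03d", i), rep(filler_mu[i], n_s), sg$filler)
  }
  # housekeeping candidates
  for (i in seq_len(nrow(panels$hk))) {
    p <- panels$hk[i, ]
    add_gene(p$gene, rep(p$mu, n_s),
             if (p$stable) sg$hk_stable else sg$hk_other)
  }
  rownames(E) <- endo
  colnames(E) <- sample_id

  ## ---- counts ----
  f_s <- with_substream(seed, "size_factors", function() {
    exp(stats::rnorm(n_s, 0, config$size_factor_sd))
  })
  counts <- matrix(0, nrow = length(endo), ncol = n_s,
                   dimnames = list(endo, sample_id))
  for (i in seq_along(endo)) {
    eps <- with_substream(seed, paste0("gene:", endo[i]), function() {
      stats::rnorm(n_s, 0, sigma_g[i])
    })
    counts[i, ] <- round(f_s * E[i, ] * exp(eps))
  }
  pos_names <- c("POS_A(128)", "POS_B(32)", "POS_C(8)", "POS_D(2)",
                 "POS_E(0.5)", "POS_F(0.125)")
  pos_conc <- c(128, 32, 8, 2, 0.5, 0.125)
  pos <- t(vapply(seq_along(pos_names), function(i) {
    eps <- with_substream(seed, paste0("gene:", pos_names[i]), function() {
      stats::rnorm(n_s, 0, sg$pos_ctrl)
    })
    round(f_s * 30 * pos_conc[i] * exp(eps))
  }, numeric(n_s)))
  rownames(pos) <- pos_names
  neg_names <- sprintf("NEG_%s(0)", LETTERS[1:8])
  neg <- t(vapply(neg_names, function(g) {
    with_substream(seed, paste0("gene:", g), function() {
      as.numeric(stats::rpois(n_s, config$neg_lambda))
    })
  }, numeric(n_s)))
  colnames(pos) <- colnames(neg) <- sample_id
  all_counts <- rbind(counts, pos, neg)
  hk_ids <- panels$hk$gene
  probes <- probe_def(rownames(all_counts),
                      c(ifelse(endo %in% hk_ids, "housekeeping",
                               "endogenous"),
                        rep("positive", length(pos_names)),
                        rep("negative", length(neg_names))))
  cm <- count_matrix(all_counts, probes, stage = "raw")

  ## ---- sample sheet with flow-cytometry surrogates ----
  cd38_e <- E["CD38", ]
  pct_cd38 <- rep(NA_real_, n_s)
  pct_cd38[cll_idx] <- with_substream(seed, "pct_cd38", function() {
    pmin(100, pmax(0, 100 * cd38_e[cll_idx] / (cd38_e[cll_idx] + 800) *
                     exp(stats::rnorm(length(cll_idx), 0, 0.3))))
  })
  pct_mal <- rep(NA_real_, n_s)
  pct_mal[cll_idx] <- with_substream(seed, "pct_malignant", function() {
    round(stats::runif(length(cll_idx), 58, 100))
  })
  zap <- rep("unknown", n_s)
  zap[cll_idx] <- ifelse(E["ZAP70", cll_idx] >= 2000, "pos", "neg")
  sheet <- sample_sheet(sample_id, group, igvh_status = igvh,
                        pct_cd38_pos = pct_cd38, pct_malignant = pct_mal,
                        zap70_status = zap)

  panel_sets <- list(
    bcell = sort_genes(panels$bcell$gene),
    under = sort_genes(panels$under$gene),
    cll_core = sort_genes(panels$core$gene),
    cll_hetero = sort_genes(panels$hetero$gene),
    cll = sort_genes(c(panels$core$gene, panels$hetero$gene)),
    mut = sort_genes(panels$mut$gene), markers = panels$markers,
    light_chains = c("kappa", "lambda"),
    hk_stable = sort_genes(panels$hk$gene[panels$hk$stable]),
    hk = sort_genes(panels$hk$gene),
    fillers = sprintf("FILL%03d", seq_len(config$n_filler)))
  truth <- list(size_factors = stats::setNames(f_s, sample_id),
                expected = E, sigma = stats::setNames(sigma_g, endo),
                panels = panel_sets,
                clonality = data.frame(sample_id = sample_id, clone = clone,
                                       stringsAsFactors = FALSE),
                ldoc1_class = data.frame(sample_id = sample_id,
                                         class = ldoc1_class,
                                         stringsAsFactors = FALSE),
                config = config)
  truth$signatures <- truth_signature_sets(truth, sheet)
  structure(list(counts = cm, sheet = sheet, truth = truth),
            class = "sim_cohort")
}

#' Expectation-level truth signatures of a synthetic cohort
#'
#' Applies the filter cascade to the planted expectations rather than to
#' sampled counts: expected measured means are the planted expectations
#' times the log-normal mean factor `exp(sigma^2/2)`, minus the expected
#' background threshold, clamped at zero. The CV criterion for the core set
#' uses the planted coefficient of variation (expectation spread across CLL
#' samples combined with the log-normal noise CV). These are the gene sets
#' an ideal, infinitely powered analysis would report, and the reference
#' for parameter-recovery checks.
#'
#' @param truth the `truth` element of a [generate_cohort()] result.
#' @param sheet matching sample sheet.
#' @param floor,fc,cv_max cascade and homogeneity thresholds.
#' @return named list of sorted gene-id vectors: `B_cell`, `CLL_vs_PB_up`,
#'   `CLL_vs_pureB_up`, `Diag`, `Core`, `CLL_under`, `Mut`.
#' @export
truth_signature_sets <- function(truth, sheet, floor = 50, fc = 2,
                                 cv_max = 0.5) {
  cfg <- truth$config
  bg <- cfg$neg_lambda + 2 * sqrt(cfg$neg_lambda)
  meas <- function(ids) {
    # expected measured normalized mean of each gene over samples `ids`
    e <- truth$expected[, ids, drop = FALSE] *
      exp(truth$sigma^2 / 2)
    pmax(rowMeans(e) - bg, 0)
  }
  ids_of <- function(g, field = "group", val = g) {
    sheet$sample_id[sheet[[field]] == val]
  }
  out <- list()
  up <- function(a, b) {
    ratio <- ifelse(a > 0, b / a, ifelse(b > 0, Inf, NA))
    names(ratio)[!is.na(ratio) & b >= floor & ratio >= fc]
  }
  down <- function(a, b) {
    ratio <- ifelse(a > 0, b / a, NA)
    names(ratio)[!is.na(ratio) & a >= floor & ratio <= 1 / fc]
  }
  grp <- function(g) sum(sheet$group == g) >= 2
  if (grp("pure_B") && grp("normal_PB")) {
    out$B_cell <- sort_genes(up(meas(ids_of("normal_PB")),
                                meas(ids_of("pure_B"))))
  }
  if (grp("CLL") && grp("normal_PB")) {
    out$CLL_vs_PB_up <- sort_genes(up(meas(ids_of("normal_PB")),
                                      meas(ids_of("CLL"))))
  }
  if (grp("CLL") && grp("pure_B")) {
    out$CLL_vs_pureB_up <- sort_genes(up(meas(ids_of("pure_B")),
                                         meas(ids_of("CLL"))))
    out$CLL_under <- sort_genes(down(meas(ids_of("pure_B")),
                                     meas(ids_of("CLL"))))
  }
  if (!is.null(out$CLL_vs_PB_up) && !is.null(out$CLL_vs_pureB_up)) {
    out$Diag <- gene_set_op(list(out$CLL_vs_PB_up, out$CLL_vs_pureB_up),
                            "intersect")
    cll_ids <- ids_of("CLL")
    e <- truth$expected[out$Diag, cll_ids, drop = FALSE]
    cv_e2 <- apply(e, 1, function(x) stats::var(x) / mean(x)^2)
    cv_planted <- sqrt((1 + cv_e2) * exp(truth$sigma[out$Diag]^2) - 1)
    out$Core <- sort_genes(out$Diag[cv_planted < cv_max])
  }
  mut_ids <- sheet$sample_id[sheet$group == "CLL" &
                               sheet$igvh_status == "mutated"]
  unmut_ids <- sheet$sample_id[sheet$group == "CLL" &
                                 sheet$igvh_status == "unmutated"]
  if (length(mut_ids) >= 2 && length(unmut_ids) >= 2) {
    a <- meas(mut_ids); b <- meas(unmut_ids)
    out$Mut <- sort_genes(c(up(a, b), down(a, b)))
  }
  out
}

#' Write a synthetic cohort to plain-text fixture files
#'
#' Emits `counts.csv` (raw matrix), `codeset.csv`, `samples.csv` and
#' `truth.json`; the CSV triplet round-trips losslessly through the
#' package's readers.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts_csv(cohort$counts, file.path(dir, "counts.csv"))
  write_codeset_csv(cohort$counts$probes, file.path(dir, "codeset.csv"))
  write_sample_sheet(cohort$sheet, file.path(dir, "samples.csv"))
  truth <- cohort$truth
  jsonlite::write_json(
    list(size_factors = as.list(truth$size_factors),
         sigma = as.list(truth$sigma), panels = truth$panels,
         clonality = truth$clonality, ldoc1_class = truth$ldoc1_class,
         signatures = truth$signatures,
         config = unclass(truth$config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort fixture back
#'
#' @param dir directory written by [write_fixture()].
#' @return list with `counts` (raw [count_matrix()]) and `sheet`.
#' @export
read_fixture <- function(dir) {
  codeset <- read_codeset_csv(file.path(dir, "codeset.csv"))
  list(counts = read_counts_csv(file.path(dir, "counts.csv"), codeset,
                                stage = "raw"),
       sheet = read_sample_sheet(file.path(dir, "samples.csv")))
}
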