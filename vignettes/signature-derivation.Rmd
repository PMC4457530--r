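---
title: "Deriving CLL gene-expression signatures from digital multiplexed counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving CLL gene-expression signatures from digital multiplexed counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the data

Chronic lymphocytic leukemia (CLL) is diagnosed and prognosticated today by
a combination of flow cytometry, cytogenetics and molecular assays such as
IgVH mutation sequencing. Digital multiplexed gene expression (DMGE, the
NanoString nCounter platform) counts individual mRNA molecules for a few
hundred probes per sample without amplification, which makes it attractive
as a single-assay substitute: a code set of ~290 disease-relevant genes plus
nine candidate normalization genes, positive spike-in controls at known
concentrations and "alien" negative-control probes.

`lymphsig` implements the full analysis path from raw lane counts to
diagnostic and prognostic signatures:

1. **Background correction** — per sample, the negative-control mean plus
   two standard deviations is subtracted from every non-control count,
   clamping at zero (`background_correct()`).
2. **Reference-gene selection** — the geNorm stability measure over the
   nine candidates, eliminating the least stable gene iteratively
   (`genorm_rank()`).
3. **Normalization** — each sample is scaled by the geometric mean of the
   selected reference genes (`normalize_counts()`).
4. **Signature derivation** — a three-threshold filter cascade on group
   comparisons, set algebra over the resulting lists, and a CV homogeneity
   filter (`compare_groups()`, `apply_cascade()`, `derive_signatures()`).
5. **Classification and markers** — PCA and average-linkage hierarchical
   clustering on signature genes, the kappa/lambda clonality ratio, and the
   LDOC1/ADAM29 and LPL/ADAM29 mutation-status surrogates
   (`cluster_classify()`, `clonality_call()`, `mut_marker_call()`).

The deposited patient-level data are not redistributed with the package;
a seeded synthetic-cohort generator (`generate_cohort()`) reproduces the
statistical structure each stage assumes, and the published per-gene
summary tables are bundled as plain CSV (`printed_table()`) for worked
examples and for seeding the generator.

## Models and conventions

### Background model

For sample $s$ with negative-control counts $n_{1..k}$, the threshold is
$t_s = \bar n_s + 2\,\hat\sigma_s$ with the sample standard deviation
($n-1$ denominator; conventional for small control sets). Every
non-control count becomes $\max(0, c - t_s)$. The subtraction is per lane,
not pooled across the run — background is a lane property on this
platform. Results stay fractional; re-rounding would discard information
used by downstream ratio statistics. Negative-control rows are carried
along unchanged for audit.

### geNorm stability

For candidates $j$ and $k$, stability is measured on pairwise log ratios:
$M_j = \operatorname{mean}_{k \ne j} \operatorname{sd}_s\,
\log_2(x_{js}/x_{ks})$. Because log-ratios cancel any per-sample scalar,
$M$ is invariant to size factors, which is the reason this measure is
suitable before normalization. The gene with the highest $M$ is removed
and $M$ recomputed until the requested number of references (default 3)
remains; the final pair is never split. Ties break lexicographically so
the ranking is deterministic. Candidate counts at or below zero are
replaced by a pseudo-count (default 0.5) with a warning.

### Normalization anchor

With $g_s$ the geometric mean of the reference genes in sample $s$ and
$G$ the geometric mean of the $g_s$, the factor is $f_s = G/g_s$, so the
factors themselves have geometric mean 1. The anchor (a single cohort-wide
scalar) is the one genuinely open choice here: anchoring to the cohort
geometric mean is scale-stable, makes re-normalization idempotent, and
leaves every within- and between-sample ratio identical to any
fixed-reference variant, so no downstream statistic depends on it.

### The filter cascade

A gene passes a two-group comparison when all three hold:

* expression floor: the mean of the **higher-expressing group** of the
  requested direction is at least 50 normalized counts;
* fold change: the ratio of group means is $\ge 2$ (or $\le 0.5$ for the
  under-expressed direction);
* significance: two-sided two-sample Student t-test $p \le 0.05$.

The t-test uses pooled variance on linear normalized counts by default —
the printed group means of the study tables are linear, and this is the
closest match to its reported statistics; Welch and log2-scale modes are
available as arguments. No multiple-testing correction is applied by
default, again for fidelity; `stats::p.adjust` can be applied to the
returned table by the caller. Genes with zero variance in both groups get
$p = 1$ with a flag rather than an undefined statistic.

Signatures are then set algebra over cascade survivors: the diagnostic
signature is the intersection of the CLL-vs-normal-PB and
CLL-vs-pure-B-cell up-lists (44 genes in the study cohort), and the core
classifier keeps the subset expressed homogeneously across CLL samples,
CV $= \hat\sigma/\bar x < 0.5$ strictly (13 genes). The published core
gene list has CVs between 0.32 and 0.48, which confirms 0.5 as the
operative cutoff (a figure legend mentioning "5%" is inconsistent with
those values and is treated as a typo). The mutation-status signature
compares IgVH-mutated with unmutated CLL samples, excluding borderline
cases, and pools both directions (24 genes in the study cohort, 19 up in
unmutated and 5 up in mutated). The two spellings SFMBT1/SFMBP1 occurring
in the source material are treated as the same gene under the table
spelling SFMBT1.

### Classification

Counts are transformed $\log_2(x+1)$ and standardized per gene before any
embedding or clustering — the platform norm for heatmap/PCA work; the
transform is centralized and documented so it can be revisited in one
place. PCA components follow a deterministic sign convention (the
largest-magnitude loading is positive). Unsupervised classification cuts
an average-linkage hierarchical tree (Euclidean distance) into two
clusters and maps them to the two truth labels by maximum agreement;
a nearest-centroid rule (`centroid_classify()`) is provided for labeling
new samples deterministically.

### Ratio markers

* **Clonality**: the ratio kappa/lambda is compared to the polyclonal
  reference interval mean $\pm 2$ SD. The study's printed reference is
  mean 0.89, SD 0.22 (interval $[0.45, 1.33]$); when enough polyclonal
  samples are present the interval is re-estimated from them. Orientation
  is always kappa over lambda.
* **LDOC1/ADAM29 trichotomy**: LDOC1-expressing, ADAM29-expressing, or
  double-negative when both fall below the absence threshold. The
  threshold reuses the pipeline's 50-count expression floor — the source
  material gives no separate value, and one consistent floor avoids a
  second free parameter.
* **LPL/ADAM29**: the published surrogate for IgVH status. The decision
  cut is 1.0 — the natural separatrix given group means on opposite sides
  of unity (mutated $\approx 91/1061$, unmutated $\approx 1072/66$) — and
  is configurable. A pseudo-count of 1 enters the denominator when ADAM29
  is zero (flagged), and double-negative samples get an indeterminate
  call rather than a forced one.

## The synthetic cohort: what it emulates

`generate_cohort()` draws
$\text{count}(g,s) = \text{round}\!\big(f_s\, e_{gs}\, e^{\varepsilon}\big)$,
$\varepsilon \sim N(0, \sigma_g^2)$, $f_s = e^{N(0, 0.2^2)}$, with
negative controls Poisson(5) (unaffected by fold changes and size
factors) and positive controls proportional to nominal concentration.
Log-normal multiplicative noise, rather than a negative-binomial count
model, is the deliberate choice: the pipeline's statistics are
mean/SD/CV-based on linear counts, and the log-normal gives directly
controllable CV $=\sqrt{e^{\sigma^2}-1}$ for planting the published CV
structure.

Defaults are the study conditions: 5 normal PB, 4 pure B-cell, 30 CLL
samples (11 mutated, 17 unmutated, 2 borderline IgVH) and the 51-sample
B-CLPD series (20 MCL, 22 MZL, 4 FL, 5 HCL). Panel expectations are
seeded from the published tables: the B-cell panel uses printed normal-PB
means and pure-B ratios; the CLL panel uses printed CLL means with an
8-fold elevation over the normal groups (the published tables do not
print the normal-group means for these genes; 8 sits in the middle of the
ratios they do print); the mutation panel uses the printed
mutated/unmutated class means, with borderline cases at the geometric
midpoint. LDOC1 and ADAM29 are modeled per sample through the trichotomy
classes, including a five-sample double-negative subgroup (two mutated,
three unmutated); all other groups hold mutation-panel genes at the CLL
average so that the mutation contrast stays isolated from the diagnostic
one. Clonal samples draw a kappa clone with probability 0.6 and the minor
chain suppressed 50-fold; polyclonal light-chain levels are the printed
normal-group means.

Noise is per panel: $\sigma = 0.3$ for the homogeneous core-like genes
(planted CV $\approx 0.31$, matching the printed 0.32–0.49 range) and
$\sigma = 0.8$ for the heterogeneous half of the CLL panel (CV
$\approx 0.95$, matching the printed 0.51–2.25 range). Housekeeping
candidates get $\sigma = 0.01$ for the three genes the study selected and
$\sigma = 0.04$ for the other six: this calibration makes geNorm's
selection of the stable trio a testable prediction and keeps the
post-normalization housekeeping CV under 5%, which is the package's
operational definition of "normalization removed the size factors".

A single base seed feeds hierarchical per-gene substreams, so cohorts are
bit-identical under the same seed and adding a gene does not reshuffle
the counts of the others.

**What the generator does not emulate:** probe cross-hybridization, lane
position effects, RNA-quality gradients, the correlation structure
between biologically related genes, and the long-tailed heterogeneity of
real patient cohorts. Passing recovery tests therefore demonstrates that
the pipeline's inference is correct under its own assumptions, not that
the published signatures would re-derive identically from new patients.

## Problem sizes and statistical expectations

The test suite and the acceptance script use cohorts at the study's group
sizes (90 samples, 313 probes) and, for parameter-recovery rates, cohorts
with 10 samples per normal group; recovery and clustering metrics are
averaged over 20 generator seeds. These sizes were chosen so that every
planted contrast is well-powered for the cascade's pooled t-test — with
the exception the power analysis predicts: genes carrying $\sigma = 0.8$
heterogeneity cannot be detected reliably by a *pooled-variance* linear
t-test against 4–5 normal samples (the pooled variance is dominated by the
CLL group while the small normal group dominates the standard-error
weight, capping $t$ near 2 regardless of fold change). At the study's
group sizes the pipeline therefore recovers the homogeneous half of the
diagnostic panel completely and the heterogeneous half partially — worth
remembering when interpreting how such cascades behave on small cohorts.
Welch or log-scale testing (both available) restores power for such
genes.

## Known limitations

* The pipeline reproduces the study's statistical conventions, including
  the absence of multiple-testing correction and moderated-variance
  testing; it is a faithful re-implementation, not a recommendation of
  those conventions for new designs.
* Printed ratio cells are reproducible from printed group means only to
  the precision of those means; a few published cells differ in the last
  decimal because they were computed from unrounded values.
* The classifier operations implement two-class problems (with pooling
  for one-vs-rest); multi-class assignment of specific disorder subtypes
  is out of scope.
* Reproduction of the deposited cohort's headline numbers
  (`reproduce_study_cohort()`) requires the user to supply the deposited
  data; the package ships only the published summary tables.
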