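---
title: "Methods: spot-level TME analysis of lymphoma spatial transcriptomics"
author: "spotTME"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spot-level TME analysis of lymphoma spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotTME)
```

## The problem

Angioimmunoblastic T-cell lymphoma (AITL) derives from follicular helper T
(TFH) cells and grows inside a dense microenvironment of B cells,
macrophages and stromal cells. On a Visium-style array each ~55 µm capture
spot mixes several cells, so "tumor" and "microenvironment" must be
disentangled at the level of spots, clusters and deconvolved cell-type
abundances. spotTME implements the full analysis chain for this setting:
spot QC and normalization, expression clustering, provenance-based calling
of neoplastic clusters, post-processing and enrichment testing of
deconvolution output, a ligand–receptor colocalization statistic for the
CD40–CD40LG axis, rule-based differential expression, per-spot signature
scoring, a tumor-only somatic variant filter, and survival analysis of an
immunohistochemistry (IHC)-stratified cohort. Because the matched patient
data are controlled-access, a seeded synthetic-data generator reproduces
the statistical structure of every input with exact ground truth, and the
whole test suite runs against it.

## Spot QC, normalization, clustering

QC keeps a spot when its library size is at least 500 UMIs, at least 500
genes are detected, and the mitochondrial count fraction (genes named
`MT-*`, computed on raw counts) is at most 5%. The inequalities are strict
on the removal side, so a spot sitting exactly on a threshold is retained;
`qc_filter()` reports each removed spot with the first failing rule (UMI,
then genes, then mito). Applying the filter twice changes nothing.

The normalization method is deliberately simple and zero-preserving: each
spot's counts are scaled so its total equals the median pre-scaling
library size, then `log1p` is applied. Consequences used elsewhere:
"detected" (count ≥ 1) can be read off either layer, and de-logging the
layer (`expm1`) recovers linear-scale, depth-corrected expression on which
fold changes are computed. The method is a package choice (the upstream
convention of spot toolkits); it is configurable by replacing the
`"normalized"` assay.

Highly variable genes are ranked by variance-to-mean dispersion of the
normalized layer, with lexicographic gene-id tie-breaks for determinism.
PCA (24 components by default) is computed by an exact eigendecomposition
with a fixed sign convention, so embeddings are reproducible to the bit.
Clustering sits behind a minimal contract — any function
`f(embedding, seed) -> integer labels` — with a shared-nearest-neighbor
graph + Leiden (modularity) engine as the default and a k-means engine for
controlled tests. Batch correction is out of scope: the generator produces
batch-free data, and an externally corrected embedding can be passed via
`embedding=`. The pipeline default resolution (1.3) was chosen so that
nodal sections resolve into several neoplastic and non-neoplastic
communities rather than one blob; it makes no claim of matching any
particular published cluster count.

## Neoplastic cluster calling

A cluster is called neoplastic when strictly more than 95% of its spots
originate from tumor sections; strictly more than 95% from normal sections
gives `normal_dominant`; anything else is `mixed`. Spots inherit a binary
compartment (neoplastic / nonneoplastic). Provenance is the deciding rule
— it is the only quantified criterion available — while TFH marker
expression (mean normalized expression of CXCL13, MME, BCL6, PDCD1, ICOS,
averaged per cluster) is reported as supporting evidence, with a warning
when a neoplastic-called cluster scores below the across-cluster median.
The rule is applied to raw spot counts per cluster; per-sample
normalization of the provenance fractions is a configuration decision left
to the user since either reading is defensible.

Between-sample similarity of the neoplastic architecture is the Pearson
correlation of each tumor sample's composition vector across neoplastic
clusters (fractions of that sample's neoplastic spots per cluster).

## Deconvolution post-processing and enrichment

Deconvolution abundances (e.g. from a Bayesian mapping with an expected 10
cells per spot) are converted to integer cell counts by rounding, with any
all-zero spot assigned one cell of its highest-abundance type. Rounding is
half-to-even by default (half-up optional) and argmax ties break by
cell-type name; both choices exist only to make the operation
deterministic and are documented rather than claimed to match any upstream
convention. Enrichment between compartments uses a two-sided Mann–Whitney
U test per cell type at spot level, Benjamini–Hochberg adjustment across
cell types, and the dual gate p < 0.05 and q < 0.25. Rounded abundances
are tested by default, consistent with the stated post-processing;
passing the raw matrix tests raw values.

## Mann–Whitney U implementation

The test statistic is U = R1 − n1(n1+1)/2 (pairs where the first group
wins, ties counting one half). When the number of group assignments
`choose(n1+n2, n1)` is at most 1e5 the null distribution is enumerated
exactly — this stays exact under ties, which the standard R implementation
refuses — and the two-sided p is `min(1, 2·min(P(U' ≤ U), P(U' ≥ U)))`.
Larger groups use the normal approximation with the standard tie
correction and no continuity correction. Property tests compare both
branches against independent enumeration and textbook-formula oracles.

## Differential expression

A gene is differentially expressed in a cluster when all three gates hold:
fold > √2 on the linear normalized scale (ratio of de-logged means with a
1e-9 pseudocount guarding empty denominators), detection in at least 25%
of the cluster's spots (raw count ≥ 1), and BH-adjusted q < 1e-4, with
p-values from one-vs-rest Mann–Whitney tests and BH applied within each
cluster across genes. Fold thresholds are conventionally linear-scale,
which fixed the "average expression" reading; log-scale means can be
obtained by operating on the log layer directly. `contrast_degs()` applies
the identical rule to an explicit two-group contrast (detection computed
on the first group); swapping the groups inverts the fold and preserves p.

## Ligand–receptor colocalization activity

The activity of a receptor–ligand axis in a spot is the minimum of the two
genes' normalized expression — coexpression quantified by the lower
partner — and a spot is "active" when both transcripts are detected
(equivalently, activity strictly positive under the zero-preserving
normalization; the threshold is exposed as `lr_active_min`). Active
fractions are reported per (sample, compartment) stratum over all
QC-passing spots, not only cluster-assigned ones, because whole sections
are the natural reporting unit. Formal comparison of two strata uses a
two-sided Fisher exact test on active/inactive counts. CD40–CD40LG ships
as the default pair; any pair list works.

## Signature scoring

The per-spot score of a gene set is the mean over its present genes of the
gene's z-scored (across spots) normalized expression — a mean-z module
score, not a rank-based GSVA/ssGSEA statistic. The package's comparisons
are ordinal contrasts of spot groups (M1 vs M2 polarization, angiogenesis
vs phagocytosis), which this score supports; an externally computed score
matrix can be supplied anywhere a score table is accepted for users who
want GSVA proper. Zero-variance genes contribute 0 rather than NaN. The
shipped signature file is an editable placeholder (flagged in its name):
the published M1/M2 and angiogenesis/phagocytosis memberships live in
prior literature and are not hard-coded as ground truth.

## Tumor-only variant filtering

Without a matched normal, germline calls are removed by five rules applied
in order: (1) intronic or synonymous consequence; (2) ClinVar benign or
likely-benign (case-insensitive; compound classes containing "pathogenic"
are never removed; absent annotation passes); (3) VAF strictly greater
than 0.90, read as homozygous germline; (4) population allele frequency
strictly greater than 1% (absence from the population database passes as
rare); (5) gene outside the recurrently mutated panel (TET2, DNMT3A, IDH2,
RHOA by default; a larger panel is user-suppliable). Order affects only
the audit trail — membership equals the intersection of the five
predicates, a property the tests verify by brute force. Multi-transcript
consequence conflicts are outside the record model: one consequence per
record, produced by the upstream annotator ("worst consequence" selection
belongs there).

## Cohort stratification and survival

The uncommon-TME phenotype is CD68 > cut, CD163 > cut, CD40LG ≤ cut, with
per-marker cohort medians as default cuts (explicit cuts can be supplied;
the published work does not state its cut points, and none of median,
ordinal-grade or absence-of-staining readings is asserted as faithful).
Kaplan–Meier curves and the two-group Mantel–Haenszel log-rank test are
implemented natively — they are the module's testable core, checked
against hand-computed product-limit values and an independent fitter —
while Cox regression delegates to the standard partial-likelihood fitter
behind a thin contract (Efron ties by default; Breslow makes the fit
exactly invariant to duplicating subjects). The relapse comparison uses a
two-sided Fisher exact test; the published analysis printed a p-value
without naming the method, so Fisher is a documented package choice.

## The synthetic-data generator

The generator defines the study conditions the tests run under:

* Six sections by default — four tumor (AITL1–4) and two control lymph
  nodes — with 1,439–4,799 spots each, matching the reported per-sample
  spot range (average 2,677).
* Counts are negative binomial (shared dispersion 0.5, baseline mean 2 per
  gene) with spot-level gene means mixing cell-type profiles weighted by
  Dirichlet-drawn proportions. Seven cell types cover the nodal TME (TFH,
  GC and naïve B cells, M1/M2 macrophages, CD8 T cells, stroma); the
  neoplastic compartment is TFH-heavy with M1-skewed macrophages, the
  non-neoplastic compartment follicle-like, so M1 enrichment and TFH-gene
  DE are true effects with known direction.
* Each cell type elevates its canonical markers (fold 6 for TFH markers,
  5 otherwise) plus 25 unnamed "program" genes at fold 4. Real cell types
  differ across hundreds of genes, not five; without programs the
  compartments are statistically separable but not cleanly clusterable,
  which is a property of toy data, not of tissue.
* Tumor purity (fraction of tumor-section spots that are neoplastic)
  defaults to 0.7 — nodal AITL largely effaces the node — and is a free
  parameter, since the source material states only a >20% lower bound.
* A configured fraction of spots (5% default) is corrupted to fail exactly
  one QC rule; clean spots are re-drawn if they would fail by chance, so
  planted failures are exactly the QC-removed set.
* Ligand–receptor coexpression is imposed per (sample, compartment) at the
  configured rate: designated spots get both genes forced to ≥ 1 by
  zero-truncated resampling, all other spots have one partner zeroed, so
  the active-spot ground truth is exact. Default rates give AITL2 the
  "uncommon" low-activity phenotype (0.11 neoplastic / 0.04
  non-neoplastic vs 0.35 / 0.30 elsewhere).
* True cell counts are Poisson(10) per spot, multinomially split by the
  spot's proportions; the abundance matrix adds Gaussian noise floored at
  zero.
* Variant tables assign each record a fate (kept, or first-failing rule
  1–5) and construct fields so earlier rules pass; cohorts draw
  exponential survival times with a configurable hazard ratio (0.125 is
  the eight-fold-longer-EFS regime), independent censoring, group-dependent
  relapse probabilities, and marker scores separated by 6 SDs between
  groups. Six, not three: with a strict triple-AND rule and median cuts,
  3-SD separation caps recovery near 0.94 (per-marker error Φ(−1.5) ≈ 6.7%
  compounds across three markers), so "clearly separated" IHC phenotypes
  need the larger gap for the ≥ 99% recovery the tests assert.

What the generator does not emulate: spatial autocorrelation of histology
(spots are exchangeable within compartments), batch effects, segmented
tissue images, and EBV status. Passing tests therefore demonstrate
correctness of the statistical machinery under the stated model, not
robustness to spatial artefacts or batch structure in real sections.

## Numerical choices and problem sizes

All randomness flows from one root seed through named substreams, so every
pipeline run is reproducible byte for byte. Deterministic tie-breaks:
lexicographic gene ids in HVG selection, cell-type name order in the
abundance argmax, fixed PCA sign convention. Degenerate inputs are
explicit errors (empty post-QC dataset, zero-total spots, absent pair
genes, zero-margin 2×2 tables warn and report p = 1). The shipped test
and acceptance configurations use hundreds of spots per section and a
1,000-gene universe — the package's chosen validation scale, at which
every planted effect is comfortably detectable — while the generator's
defaults reproduce the full study scale.
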