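# spotTME

Spot-level tumor microenvironment (TME) analysis for Visium-style spatial
transcriptomics of angioimmunoblastic T-cell lymphoma (AITL) and control
lymph nodes, for analysts working with nodal lymphoma sections alongside
tumor-only whole-exome variant tables and IHC-stratified survival cohorts.

AITL derives from follicular helper T (TFH) cells; each ~55 µm array spot
captures a mixture of tumor and microenvironment cells. The package
implements the analysis chain that disentangles them:

- **Spot QC** — keep spots with total UMI ≥ 500, detected genes ≥ 500 and
  mitochondrial fraction ≤ 5% (strict inequalities on removal, first
  failing rule reported), then median-library normalization with `log1p`.
- **Clustering** — HVG selection by variance/mean dispersion, exact PCA,
  and a pluggable clustering engine (SNN + Leiden default).
- **Neoplastic cluster calling** — a cluster is neoplastic iff strictly
  more than 95% of its spots come from tumor sections; TFH markers
  (CXCL13, MME, BCL6, PDCD1, ICOS) are reported as supporting evidence.
  Pearson correlation of neoplastic-cluster composition compares samples.
- **Deconvolution post-processing** — abundances rounded to integer cell
  counts, empty spots assigned one cell of the argmax type; spot-level
  Mann–Whitney enrichment between compartments at p < 0.05 and BH
  q < 0.25.
- **Differential expression** — a gene is a DEG in a cluster iff
  fold > √2 (linear normalized scale), detection ≥ 25% of the cluster's
  spots, and BH q < 1e-4 (one-vs-rest Mann–Whitney).
- **Ligand–receptor activity** — activity of a pair in a spot is
  min(ligand, receptor) normalized expression; a spot is active when both
  transcripts are detected; active fractions stratified by sample and
  compartment (CD40–CD40LG shipped as default).
- **Tumor-only variant filter** — five ordered rules with an audit trail:
  intronic/synonymous, ClinVar (likely) benign, VAF > 90% (homozygous),
  population AF > 1%, outside the recurrent-gene panel (TET2, DNMT3A,
  IDH2, RHOA).
- **Survival** — CD68^high / CD163^high / CD40LG^low cohort
  stratification, native Kaplan–Meier + log-rank, Fisher exact relapse
  test, Cox regression via the `survival` package.
- **Synthetic data** — a seeded generator emulating all inputs (negative
  binomial counts mixing Dirichlet-weighted cell-type profiles, planted QC
  failures, exact ligand–receptor coexpression rates, variant tables with
  per-rule fates, survival cohorts with configurable hazard ratio) with
  full ground truth.

The exact Mann–Whitney implementation (`mann_whitney_u`) enumerates the
null distribution for small groups — remaining exact under ties — and
uses the tie-corrected normal approximation otherwise.

## Worked example

```r
library(spotTME)

cfg <- st_sim_config(n_samples_tumor = 4, n_samples_normal = 2,
                     spots_per_sample = c(300L, 400L), seed = 42)
sim <- simulate_st_dataset(cfg)
qc  <- qc_filter(sim$dataset)
ds  <- normalize_spots(qc$dataset)
ds  <- embed_and_cluster(ds, engine = snn_leiden_engine(k = 25,
                                                        resolution = 1.3),
                         seed = 5)
ann <- call_neoplastic(ds)
ann$profiles
#>   cluster_id n_spots fraction_tumor_origin tfh_score       call
#> 1          1    1024                 0.360     0.983      mixed
#> 2          2     889                 0.997     1.864 neoplastic
#> 3          3      20                 0.700     1.401      mixed
#> 4          4      13                 0.615     1.389      mixed
#> 5          5      12                 0.583     1.535      mixed
#> 6          6      18                 0.833     1.375      mixed
```

2,080 spots were simulated and 104 failed QC (exactly the planted 5%).
Cluster 2 draws 99.7% of its spots from tumor sections and shows the
highest TFH score, so it is called neoplastic and its spots form the
neoplastic compartment; 98.4% of spots receive their true compartment.
CD40–CD40LG activity then separates the "uncommon" sample (AITL2 in the
generator's defaults) from the rest:

```r
act <- spot_activity(ann$dataset, lr_pair("CD40", "CD40LG"))
subset(activity_fractions(act, ann$dataset),
       compartment == "neoplastic" & n > 0)
#>  sample_id compartment   n n_active active_fraction
#>      AITL1  neoplastic 226       79            0.35
#>      AITL2  neoplastic 258       29            0.11
#>      AITL3  neoplastic 190       68            0.36
#>      AITL4  neoplastic 212       76            0.36
```

AITL2's 11% active fraction against 35–36% elsewhere recovers the planted
low-coexpression phenotype. `run_pipeline(config, out_dir, seed)` chains
every stage (QC → clustering → annotation → enrichment → DEGs →
ligand–receptor → signatures, plus the variant and cohort branches) into
one reproducible run with a manifest; `inst/cli/pipeline.R` wraps it for
the shell.

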