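#' Analysis thresholds and parameters
#'
#' Central container for every tunable threshold of the analysis, with the
#' published values as defaults: spot QC (UMI >= 500, genes >= 500, mito
#' fraction <= 5%, strict inequalities on removal), 5,000 highly variable
#' genes, 24 principal components, the > 95% sample-provenance rule for
#' neoplastic cluster calling, TFH marker set (CXCL13, MME, BCL6, PDCD1,
#' ICOS), the DEG triple gate (fold > 2^0.5, detection >= 25%, q < 1e-4),
#' enrichment dual gate (p < 0.05 and BH q < 0.25), the tumor-only variant
#' cutoffs (VAF > 0.90 homozygous, population AF > 1%), and 10 cells per
#' spot for deconvolution post-processing.
#'
#' @param min_umi,min_genes,max_mito spot QC thresholds.
#' @param n_hvg number of highly variable genes.
#' @param n_pcs number of principal components.
#' @param provenance_threshold tumor-provenance fraction above which a
#'   cluster is called neoplastic (strict).
#' @param tfh_markers follicular helper T-cell marker genes.
#' @param deg_fold,deg_detection,deg_q DEG gates (linear fold, detection
#'   fraction, BH q).
#' @param enrich_p,enrich_q enrichment gates (raw p, BH q).
#' @param vaf_hom,pop_af variant-filter cutoffs (strict "greater than").
#' @param cells_per_spot expected cells per spot.
#' @param rounding abundance rounding mode, `"half_even"` or `"half_up"`.
#' @param lr_active_min minimum of the pair's normalized expression above
#'   which a spot counts as ligand-receptor "active" (0 = both detected).
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(min_umi = 500, min_genes = 500, max_mito = 0.05,
                            n_hvg = 5000, n_pcs = 24,
                            provenance_threshold = 0.95,
                            tfh_markers = c("CXCL13", "MME", "BCL6",
                                            "PDCD1", "ICOS"),
                            deg_fold = 2^0.5, deg_detection = 0.25,
                            deg_q = 1e-4,
                            enrich_p = 0.05, enrich_q = 0.25,
                            vaf_hom = 0.90, pop_af = 0.01,
                            cells_per_spot = 10,
                            rounding = c("half_even", "half_up"),
                            lr_active_min = 0) {
  rounding <- match.arg(rounding)
  vals <- c(min_umi, min_genes, max_mito, n_hvg, n_pcs,
            provenance_threshold, deg_fold, deg_detection, deg_q,
            enrich_p, enrich_q, vaf_hom, pop_af, cells_per_spot)
  stop_if_not(all(vals > 0), "all thresholds must be positive")
  stop_if_not(deg_fold > 1, "deg_fold must exceed 1")
  structure(list(
    min_umi = min_umi, min_genes = min_genes, max_mito = max_mito,
    n_hvg = n_hvg, n_pcs = n_pcs,
    provenance_threshold = provenance_threshold, tfh_markers = tfh_markers,
    deg_fold = deg_fold, deg_detection = deg_detection, deg_q = deg_q,
    enrich_p = enrich_p, enrich_q = enrich_q,
    vaf_hom = vaf_hom, pop_af = pop_af, cells_per_spot = cells_per_spot,
    rounding = rounding, lr_active_min = lr_active_min
  ), class = "pipeline_config")
}
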