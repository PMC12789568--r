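default_cell_types <- function() {
  c("B_GC", "B_naive", "Macro_M1", "Macro_M2", "Stroma", "T_CD8", "Tfh")
}

default_marker_map <- function() {
  list(
    Tfh      = list(genes = c("CXCL13", "MME", "BCL6", "PDCD1", "ICOS",
                              "CD40LG"), fold = 6),
    B_naive  = list(genes = c("IGHD", "TCL1A", "FCER2"), fold = 5),
    B_GC     = list(genes = c("CD40", "AICDA", "RGS13"), fold = 5),
    Macro_M1 = list(genes = c("CD68", "IL1B", "CXCL9"), fold = 5),
    Macro_M2 = list(genes = c("CD163", "MRC1", "CCL22"), fold = 5),
    T_CD8    = list(genes = c("CD8A", "GZMK", "NKG7"), fold = 5),
    Stroma   = list(genes = c("COL1A1", "PDGFRB", "CCL21"), fold = 5)
  )
}

# Dirichlet concentration per cell type and compartment. Neoplastic spots are
# TFH-rich with germinal-centre B cells and M1-skewed macrophages; the
# non-neoplastic compartment mirrors reactive lymph node follicles.
default_dirichlet_alpha <- function(cell_types = default_cell_types()) {
  a <- matrix(0.5, nrow = length(cell_types), ncol = 2,
              dimnames = list(cell_types, c("neoplastic", "nonneoplastic")))
  a[, "neoplastic"] <- c(B_GC = 2, B_naive = 0.5, Macro_M1 = 2,
                         Macro_M2 = 1, Stroma = 0.5, T_CD8 = 1,
                         Tfh = 8)[cell_types]
  a[, "nonneoplastic"] <- c(B_GC = 3, B_naive = 6, Macro_M1 = 0.5,
                            Macro_M2 = 1, Stroma = 1, T_CD8 = 2,
                            Tfh = 0.5)[cell_types]
  a
}

# Default ligand-receptor coexpression rates per (sample, compartment).
# Sample AITL2 carries the "uncommon" CD40-CD40LG-low microenvironment.
default_coexpr_rates <- function(n_tumor, n_normal) {
  tumor <- paste0("AITL", seq_len(n_tumor))
  normal <- paste0("LN", seq_len(n_normal))
  rate_neo <- rep(0.35, n_tumor)
  rate_non <- rep(0.30, n_tumor)
  if (n_tumor >= 2) {
    rate_neo[2] <- 0.11
    rate_non[2] <- 0.04
  }
  rbind(
    data.frame(sample_id = rep(tumor, 2),
               compartment = rep(c("neoplastic", "nonneoplastic"),
                                 each = n_tumor),
               rate = c(rate_neo, rate_non)),
    data.frame(sample_id = normal, compartment = "nonneoplastic",
               rate = 0.30)
  )
}

#' Configuration for the spatial-transcriptome simulator
#'
#' Defaults emulate the study conditions the package targets: four tumor
#' (AITL) and two control lymph node (LN) sections, 1,439-4,799 spots per
#' section, overdispersed negative-binomial UMI counts whose spot-level means
#' mix cell-type expression profiles weighted by Dirichlet-drawn proportions,
#' "MT-"-prefixed mitochondrial genes, planted QC failures, and per-stratum
#' ligand-receptor coexpression rates with exact ground truth.
#'
#' @param n_samples_tumor,n_samples_normal number of tumor / normal sections.
#' @param spots_per_sample integer range (length 2) of spots per section.
#' @param n_genes size of the gene universe (marker, ligand-receptor and
#'   mitochondrial genes included).
#' @param nb_mean baseline negative-binomial mean per gene and spot.
#' @param nb_dispersion shared NB dispersion (variance = mu + dispersion*mu^2).
#' @param mito_gene_fraction fraction of genes given an `"MT-"` name.
#' @param mito_expr_mult expression multiplier for mitochondrial genes
#'   (controls the typical mitochondrial fraction of clean spots).
#' @param qc_fail_rate fraction of spots corrupted to fail QC (library size
#'   < 500, genes detected < 500, or mitochondrial fraction > 5%).
#' @param tumor_purity fraction of tumor-section spots that are neoplastic.
#' @param cell_types character vector of cell-type names.
#' @param dirichlet_alpha cell_types x {neoplastic, nonneoplastic} matrix of
#'   Dirichlet concentrations.
#' @param marker_map named list per cell type: `list(genes=, fold=)`.
#' @param program_genes_per_type number of additional unnamed "program"
#'   genes elevated in each cell type (cell types differ across many genes,
#'   not only canonical markers; this is what makes expression clustering of
#'   spot mixtures realistic).
#' @param program_fold fold elevation of program genes in their cell type.
#' @param lr_pairs list of c(ligand, receptor) character pairs.
#' @param coexpr_rates data.frame (sample_id, compartment, rate) of target
#'   coexpression rates; `NULL` uses the shipped defaults.
#' @param cells_per_spot mean true cells per spot (Poisson).
#' @param gene_ids optional explicit gene universe; `NULL` builds one.
#' @param seed integer seed; fully determines the simulated dataset.
#' @return validated config list of class `"st_sim_config"`.
#' @export
st_sim_config <- function(n_samples_tumor = 4,
                          n_samples_normal = 2,
                          spots_per_sample = c(1439L, 4799L),
                          n_genes = 1000,
                          nb_mean = 2,
                          nb_dispersion = 0.5,
                          mito_gene_fraction = 0.01,
                          mito_expr_mult = 2,
                          qc_fail_rate = 0.05,
                          tumor_purity = 0.7,
                          cell_types = default_cell_types(),
                          dirichlet_alpha = default_dirichlet_alpha(cell_types),
                          marker_map = default_marker_map(),
                          program_genes_per_type = 25,
                          program_fold = 4,
                          lr_pairs = list(c("CD40", "CD40LG")),
                          coexpr_rates = NULL,
                          cells_per_spot = 10,
                          gene_ids = NULL,
                          seed = 1L) {
  stop_if_not(n_samples_tumor >= 1 && n_samples_normal >= 0,
              "need at least one tumor sample")
  stop_if_not(length(spots_per_sample) == 2 &&
                spots_per_sample[1] >= 1 &&
                spots_per_sample[1] <= spots_per_sample[2],
              "spots_per_sample must be an increasing positive range")
  stop_if_not(nb_mean > 0 && nb_dispersion > 0,
              "nb_mean and nb_dispersion must be positive")
  stop_if_not(is_proportion(c(mito_gene_fraction, qc_fail_rate, tumor_purity)),
              "mito_gene_fraction, qc_fail_rate and tumor_purity must lie in [0,1]")
  stop_if_not(is.matrix(dirichlet_alpha) &&
                nrow(dirichlet_alpha) == length(cell_types) &&
                all(c("neoplastic", "nonneoplastic") %in%
                      colnames(dirichlet_alpha)) &&
                all(dirichlet_alpha > 0),
              "dirichlet_alpha must be a positive cell_types x compartment matrix")
  stop_if_not(all(names(marker_map) %in% cell_types),
              "marker_map names must be cell types")
  lr_genes <- unlist(lr_pairs)
  program_map <- list()
  if (program_genes_per_type > 0) {
    program_map <- stats::setNames(lapply(cell_types, function(ct) {
      list(genes = sprintf("PROG-%s-%02d", ct,
                           seq_len(program_genes_per_type)),
           fold = program_fold)
    }), cell_types)
  }
  named <- unique(c(unlist(lapply(marker_map, `[[`, "genes")), lr_genes))
  prog_genes <- unlist(lapply(program_map, `[[`, "genes"))
  if (is.null(gene_ids)) {
    n_mito <- max(1L, round(mito_gene_fraction * n_genes))
    n_bg <- n_genes - length(named) - length(prog_genes) - n_mito
    stop_if_not(n_bg >= 0,
                "n_genes too small for the marker, program and LR genes")
    gene_ids <- c(named, prog_genes, paste0("MT-G", seq_len(n_mito)),
                  sprintf("GENE%04d", seq_len(n_bg)))
  } else {
    program_map <- list()
    missing <- setdiff(named, gene_ids)
    stop_if_not(length(missing) == 0,
                "marker/LR genes absent from gene universe: ",
                paste(missing, collapse = ", "))
    n_genes <- length(gene_ids)
  }
  if (is.null(coexpr_rates)) {
    coexpr_rates <- default_coexpr_rates(n_samples_tumor, n_samples_normal)
  }
  stop_if_not(is_proportion(coexpr_rates$rate), "coexpr rates must lie in [0,1]")

  structure(list(
    n_samples_tumor = n_samples_tumor, n_samples_normal = n_samples_normal,
    spots_per_sample = as.integer(spots_per_sample), n_genes = n_genes,
    nb_mean = nb_mean, nb_dispersion = nb_dispersion,
    mito_gene_fraction = mito_gene_fraction, mito_expr_mult = mito_expr_mult,
    qc_fail_rate = qc_fail_rate, tumor_purity = tumor_purity,
    cell_types = cell_types, dirichlet_alpha = dirichlet_alpha,
    marker_map = marker_map, program_map = program_map,
    program_genes_per_type = program_genes_per_type,
    program_fold = program_fold, lr_pairs = lr_pairs,
    coexpr_rates = coexpr_rates, cells_per_spot = cells_per_spot,
    gene_ids = gene_ids, seed = as.integer(seed)
  ), class = "st_sim_config")
}
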