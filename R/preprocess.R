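#' Filter spots on QC thresholds
#'
#' Removes spots with library size below `min_umi`, fewer detected genes than
#' `min_genes`, or a mitochondrial count fraction above `max_mito`. The
#' inequalities are strict on the removal side ("less than 500", "greater
#' than 5%"), so a spot at exactly 500 UMIs, 500 genes and 5% mitochondrial
#' counts is retained. The report lists each removed spot with the first
#' failing criterion, checked in the order UMI, genes, mito.
#'
#' @param ds spot dataset.
#' @param cfg a [pipeline_config()].
#' @return list with `dataset` (filtered) and `report` (data.frame: spot_id,
#'   total_umi, n_genes_detected, mito_fraction, first_fail).
#' @export
qc_filter <- function(ds, cfg = pipeline_config()) {
  md <- spot_meta(ds)
  fail_umi <- md$total_umi < cfg$min_umi
  fail_genes <- md$n_genes_detected < cfg$min_genes
  fail_mito <- md$mito_fraction > cfg$max_mito
  fails <- fail_umi | fail_genes | fail_mito
  first_fail <- rep(NA_character_, nrow(md))
  first_fail[fail_mito] <- "mito"
  first_fail[fail_genes] <- "genes"
  first_fail[fail_umi] <- "umi"
  if (all(fails)) {
    stop("no spot passes QC (", sum(fail_umi), " low-UMI, ",
         sum(fail_genes), " low-gene, ", sum(fail_mito),
         " high-mito); check thresholds against the data", call. = FALSE)
  }
  report <- data.frame(
    spot_id = md$spot_id[fails],
    total_umi = md$total_umi[fails],
    n_genes_detected = md$n_genes_detected[fails],
    mito_fraction = md$mito_fraction[fails],
    first_fail = first_fail[fails],
    stringsAsFactors = FALSE
  )
  list(dataset = ds[, !fails], report = report)
}

#' Median-library normalization with log1p
#'
#' Scales each spot's counts so its total equals the median pre-scaling
#' library size, then applies `log1p`. Raw counts are preserved; the result
#' is stored in the `"normalized"` assay. The transform preserves the zero
#' pattern, so "detected" can be read off either layer.
#'
#' @param ds spot dataset (QC already applied).
#' @return the dataset with a `"normalized"` assay added.
#' @export
normalize_spots <- function(ds) {
  counts <- SummarizedExperiment::assay(ds, "counts")
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    stop(sum(totals == 0), " spot(s) have zero total counts; run qc_filter() first",
         call. = FALSE)
  }
  target <- stats::median(totals)
  scaled <- counts %*% Matrix::Diagonal(x = target / totals)
  scaled <- as(scaled, "CsparseMatrix")
  scaled@x <- log1p(scaled@x)
  dimnames(scaled) <- dimnames(counts)
  SummarizedExperiment::assay(ds, "normalized") <- scaled
  ds
}

#' Select highly variable genes
#'
#' Ranks genes by variance-to-mean dispersion of the normalized layer and
#' returns the top `n`. Ties are broken by gene id (lexicographic) so the
#' selection is deterministic; zero-variance genes have dispersion 0 and are
#' never selected before any non-constant gene.
#'
#' @param ds spot dataset with a normalized layer.
#' @param n number of genes to return (at most the number of genes).
#' @return character vector of gene ids, in decreasing dispersion order.
#' @export
select_hvg <- function(ds, n) {
  x <- norm_layer(ds)
  stop_if_not(n >= 1 && n <= nrow(x),
              "n must lie between 1 and the number of genes (", nrow(x), ")")
  m <- Matrix::rowMeans(x)
  v <- row_vars_sparse(x)
  disp <- ifelse(m > 0, v / m, 0)
  ord <- order(-disp, rownames(x))
  rownames(x)[ord][seq_len(n)]
}

#' Default clustering engine: shared-nearest-neighbor graph + Leiden
#'
#' Builds an SNN graph on the embedding and partitions it with the Leiden
#' algorithm (modularity objective). Returns a function satisfying the
#' clustering contract: `f(embedding, seed) -> integer labels`.
#'
#' @param k neighbors for the SNN graph.
#' @param resolution Leiden resolution parameter.
#' @param n_iterations Leiden iterations.
#' @return an engine function.
#' @export
snn_leiden_engine <- function(k = 15, resolution = 1, n_iterations = 5) {
  function(embedding, seed) {
    set.seed(seed)
    g <- scran::buildSNNGraph(embedding, k = min(k, nrow(embedding) - 1),
                              transposed = TRUE)
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution,
                                 n_iterations = n_iterations)
    as.integer(igraph::membership(cl))
  }
}

#' k-means clustering engine
#'
#' Simple alternative engine for data with a known number of well-separated
#' groups.
#'
#' @param centers number of clusters.
#' @param nstart random restarts.
#' @return an engine function `f(embedding, seed) -> integer labels`.
#' @export
kmeans_engine <- function(centers, nstart = 10) {
  function(embedding, seed) {
    set.seed(seed)
    as.integer(stats::kmeans(embedding, centers = centers,
                             nstart = nstart)$cluster)
  }
}

# Deterministic PCA scores; rotation/center stored for reconstruction.
# Uses the eigendecomposition of the gene-gene cross-product when genes do
# not outnumber spots, falling back to SVD otherwise.
pca_embed <- function(X, k) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  k <- min(k, ncol(Xc), nrow(Xc))
  if (ncol(Xc) <= nrow(Xc)) {
    e <- eigen(crossprod(Xc), symmetric = TRUE)
    V <- e$vectors[, seq_len(k), drop = FALSE]
  } else {
    V <- svd(Xc, nu = 0, nv = k)$v
  }
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- Xc %*% V
  colnames(scores) <- colnames(V) <- paste0("PC", seq_len(k))
  list(scores = scores, rotation = V, center = ctr)
}

#' Embed spots by PCA and assign cluster labels
#'
#' Computes PCA (to `cfg$n_pcs` components, clipped to the data rank) on the
#' highly-variable-gene submatrix of the normalized layer and hands the
#' embedding to a clustering engine, any function
#' `f(embedding, seed) -> integer labels`, one label per spot. Labels are
#' stored in `colData(ds)$cluster`; the embedding in `reducedDim(ds, "PCA")`
#' and the rotation/center in `metadata(ds)$pca`, so an externally corrected
#' embedding can also be supplied via `embedding=`.
#'
#' @param ds spot dataset with a normalized layer.
#' @param cfg a [pipeline_config()].
#' @param engine clustering engine (default [snn_leiden_engine()]).
#' @param hvg optional gene vector; defaults to
#'   `select_hvg(ds, min(cfg$n_hvg, nrow(ds)))`.
#' @param embedding optional precomputed spots x dims matrix (skips PCA).
#' @param seed seed forwarded to the engine.
#' @return the dataset with cluster labels.
#' @export
embed_and_cluster <- function(ds, cfg = pipeline_config(),
                              engine = snn_leiden_engine(),
                              hvg = NULL, embedding = NULL, seed = 1L) {
  if (is.null(embedding)) {
    if (is.null(hvg)) hvg <- select_hvg(ds, min(cfg$n_hvg, nrow(ds)))
    X <- Matrix::t(norm_layer(ds)[hvg, , drop = FALSE])
    pca <- pca_embed(as.matrix(X), cfg$n_pcs)
    embedding <- pca$scores
    S4Vectors::metadata(ds)$pca <- list(rotation = pca$rotation,
                                        center = pca$center, hvg = hvg)
  }
  SingleCellExperiment::reducedDim(ds, "PCA") <- embedding
  labels <- engine(embedding, seed)
  if (!is.numeric(labels) || length(labels) != ncol(ds) || anyNA(labels)) {
    stop("clustering engine contract violation: expected ", ncol(ds),
         " non-missing integer labels, got ", length(labels), call. = FALSE)
  }
  SummarizedExperiment::colData(ds)$cluster <- as.integer(labels)
  ds
}
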