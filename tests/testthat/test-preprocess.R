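# QC boundary behaviour is tested on hand-built spots whose totals, detected
# genes and mito fractions sit exactly at the printed thresholds.
make_boundary_ds <- function() {
  n_genes <- 1200
  genes <- c("MT-1", sprintf("G%04d", seq_len(n_genes - 1)))
  col <- function(n_detected, per_gene = 1, mito = 0) {
    v <- numeric(n_genes)
    v[1] <- mito
    v[1 + seq_len(n_detected)] <- per_gene
    v
  }
  counts <- cbind(
    pass_all = col(600, 1),                 # 600 umi / 600 genes / 0 mito
    umi_499 = col(499, 1),                  # 499 umi -> below 500
    genes_499 = col(499, 2),                # 998 umi but 499 genes
    genes_500 = col(500, 2),                # boundary: exactly 500 genes
    mito_high = col(600, 1, mito = 32),     # 32/632 = 5.06% > 5%
    mito_edge = col(570, 1, mito = 30)      # 30/600 = 5.00% -> retained
  )
  rownames(counts) <- genes
  spot_dataset(counts, data.frame(sample_id = "S1", tissue_type = "tumor"))
}

test_that("qc_filter applies strict thresholds exactly as printed", {
  ds <- make_boundary_ds()
  res <- qc_filter(ds)
  expect_setequal(res$report$spot_id, c("umi_499", "genes_499", "mito_high"))
  expect_setequal(colnames(res$dataset),
                  c("pass_all", "genes_500", "mito_edge"))
  ff <- setNames(res$report$first_fail, res$report$spot_id)
  expect_identical(ff[["umi_499"]], "umi")
  expect_identical(ff[["genes_499"]], "genes")
  expect_identical(ff[["mito_high"]], "mito")
})

test_that("qc_filter is idempotent and the identity on clean data", {
  ds <- make_boundary_ds()
  once <- qc_filter(ds)
  twice <- qc_filter(once$dataset)
  expect_identical(colnames(twice$dataset), colnames(once$dataset))
  expect_equal(nrow(twice$report), 0)
  # a dataset with no violations is returned unchanged
  clean <- once$dataset
  expect_identical(as.matrix(SummarizedExperiment::assay(clean)),
                   as.matrix(SummarizedExperiment::assay(
                     qc_filter(clean)$dataset)))
})

test_that("qc_filter refuses to return an empty dataset", {
  counts <- matrix(1, nrow = 5, ncol = 3,
                   dimnames = list(paste0("G", 1:5), paste0("s", 1:3)))
  ds <- spot_dataset(counts, data.frame(sample_id = "S1",
                                        tissue_type = "tumor"))
  expect_error(qc_filter(ds), "no spot passes QC")
})

test_that("normalization matches a brute-force recomputation", {
  counts <- rand_counts(20, 30, seed = 7)
  ds <- manual_ds(counts)
  layer <- as.matrix(SummarizedExperiment::assay(ds, "normalized"))
  totals <- colSums(counts)
  expected <- log1p(sweep(counts, 2, median(totals) / totals, "*"))
  expect_equal(layer, expected, tolerance = 1e-12, ignore_attr = TRUE)
  # zero pattern preserved; pre-log column sums equal the median total
  expect_identical(layer == 0, counts == 0, ignore_attr = TRUE)
  expect_equal(colSums(expm1(layer)), rep(median(totals), 30),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("normalization is invariant to rescaling a spot's depth", {
  counts <- matrix(5, nrow = 20, ncol = 5,
                   dimnames = list(paste0("G", 1:20), paste0("s", 1:5)))
  counts2 <- counts
  counts2[, 1] <- counts2[, 1] * 2  # median total unchanged (5 spots)
  d1 <- manual_ds(counts)
  d2 <- manual_ds(counts2)
  expect_equal(
    as.numeric(SummarizedExperiment::assay(d1, "normalized")[, 1]),
    as.numeric(SummarizedExperiment::assay(d2, "normalized")[, 1]),
    tolerance = 1e-12
  )
  expect_error(normalize_spots(spot_dataset(
    matrix(0, 3, 2, dimnames = list(paste0("G", 1:3), c("a", "b"))),
    data.frame(sample_id = "S1", tissue_type = "tumor"))), "zero total")
})

test_that("highly variable gene selection matches an oracle sort", {
  set.seed(3)
  n_spots <- 50
  sds <- c(G_high = 8, G_mid = 4, G_low = 1, G_const = 0)
  counts <- do.call(rbind, lapply(names(sds), function(g) {
    pmax(0, round(rnorm(n_spots, mean = 20, sd = sds[[g]])))
  }))
  counts <- rbind(counts, rand_counts(96, n_spots, seed = 9, lambda = 20))
  rownames(counts) <- c(names(sds), sprintf("R%03d", 1:96))
  colnames(counts) <- sprintf("s%03d", seq_len(n_spots))
  ds <- manual_ds(counts)
  x <- as.matrix(SummarizedExperiment::assay(ds, "normalized"))
  m <- rowMeans(x); v <- apply(x, 1, var)
  disp <- ifelse(m > 0, v / m, 0)
  oracle <- rownames(x)[order(-disp, rownames(x))]
  expect_identical(select_hvg(ds, 10), oracle[1:10])
  expect_identical(select_hvg(ds, nrow(ds)), oracle)
  # a constant gene is never selected before any non-constant one
  sel <- select_hvg(ds, nrow(ds) - 1)
  expect_false("G_const" %in% sel[1:(nrow(ds) - sum(disp == 0))])
  expect_error(select_hvg(ds, nrow(ds) + 1), "between 1 and")
})

test_that("PCA + engine recovers two separated blobs and is reproducible", {
  set.seed(21)
  n_per <- 40; n_genes <- 30
  mu <- matrix(5, n_genes, 2); mu[1:15, 1] <- 50; mu[16:30, 2] <- 50
  counts <- cbind(
    matrix(rpois(n_genes * n_per, mu[, 1]), n_genes),
    matrix(rpois(n_genes * n_per, mu[, 2]), n_genes)
  )
  dimnames(counts) <- list(sprintf("G%03d", 1:n_genes),
                           sprintf("s%03d", 1:(2 * n_per)))
  truth <- rep(1:2, each = n_per)
  ds <- manual_ds(counts)
  ds <- embed_and_cluster(ds, pipeline_config(n_pcs = 5),
                          engine = kmeans_engine(2), seed = 1)
  skip_if_not_installed("mclust")
  expect_equal(
    mclust::adjustedRandIndex(spot_meta(ds)$cluster, truth), 1.0)
  # the default graph engine is deterministic under a fixed seed
  d1 <- embed_and_cluster(ds, pipeline_config(n_pcs = 5),
                          engine = snn_leiden_engine(k = 10), seed = 7)
  d2 <- embed_and_cluster(ds, pipeline_config(n_pcs = 5),
                          engine = snn_leiden_engine(k = 10), seed = 7)
  expect_identical(spot_meta(d1)$cluster, spot_meta(d2)$cluster)
})

test_that("full-rank PCA is lossless and bad engines violate the contract", {
  counts <- rand_counts(12, 25, seed = 13)
  ds <- manual_ds(counts)
  ds <- embed_and_cluster(ds, pipeline_config(n_pcs = 12, n_hvg = 12),
                          engine = kmeans_engine(2), seed = 1)
  pca <- S4Vectors::metadata(ds)$pca
  emb <- SingleCellExperiment::reducedDim(ds, "PCA")
  X <- t(as.matrix(SummarizedExperiment::assay(ds, "normalized")[pca$hvg, ]))
  recon <- emb %*% t(pca$rotation) + rep(pca$center, each = nrow(X))
  expect_equal(max(abs(recon - X)), 0, tolerance = 1e-8)
  expect_error(
    embed_and_cluster(ds, pipeline_config(n_pcs = 5),
                      engine = function(emb, seed) 1:3, seed = 1),
    "contract violation"
  )
})
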