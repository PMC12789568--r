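# Datasets with hand-assigned clusters and provenance for the calling rule.
labelled_ds <- function(n_per_cluster, tumor_fraction, seed = 1) {
  # one cluster per element of tumor_fraction; exact tumor/normal counts
  n <- sum(n_per_cluster)
  counts <- rand_counts(40, n, seed = seed)
  rownames(counts)[1:5] <- c("CXCL13", "MME", "BCL6", "PDCD1", "ICOS")
  cluster <- rep(seq_along(n_per_cluster), n_per_cluster)
  tumor <- unlist(lapply(seq_along(n_per_cluster), function(i) {
    k <- round(tumor_fraction[i] * n_per_cluster[i])
    rep(c(TRUE, FALSE), c(k, n_per_cluster[i] - k))
  }))
  meta <- data.frame(
    sample_id = ifelse(tumor, "AITL1", "LN1"),
    tissue_type = ifelse(tumor, "tumor", "normal"),
    cluster = cluster
  )
  ds <- spot_dataset(counts, meta)
  normalize_spots(ds)
}

test_that("cluster profiles equal an independent group-by tally", {
  ds <- labelled_ds(c(10, 20, 15), c(0.6, 1.0, 0.2), seed = 5)
  prof <- profile_clusters(ds)
  md <- spot_meta(ds)
  x <- as.matrix(SummarizedExperiment::assay(ds, "normalized"))
  markers <- c("CXCL13", "MME", "BCL6", "PDCD1", "ICOS")
  for (i in seq_len(nrow(prof))) {
    sel <- md$cluster == prof$cluster_id[i]
    expect_equal(prof$n_spots[i], sum(sel))
    expect_equal(prof$fraction_tumor_origin[i],
                 mean(md$tissue_type[sel] == "tumor"))
    expect_equal(prof$tfh_score[i],
                 mean(colMeans(x[markers, sel, drop = FALSE])))
  }
  fbs <- attr(prof, "fraction_by_sample")
  expect_equal(unname(rowSums(fbs)), rep(1, nrow(fbs)))
  # cluster of 10 spots, 6 tumor / 4 normal -> fractions 0.6 / 0.4
  expect_equal(unname(fbs["1", c("AITL1", "LN1")]), c(0.6, 0.4))
})

test_that("neoplastic calls use the strict 95% provenance rule", {
  ds <- labelled_ds(rep(100, 4), c(0.96, 0.95, 0.5, 1.0), seed = 2)
  res <- suppressWarnings(call_neoplastic(ds))
  calls <- setNames(res$profiles$call, res$profiles$cluster_id)
  expect_identical(unname(calls[c("1", "2", "3", "4")]),
                   c("neoplastic", "mixed", "mixed", "neoplastic"))
  md <- spot_meta(res$dataset)
  expect_true(all(md$compartment %in% c("neoplastic", "nonneoplastic")))
  expect_identical(unique(md$compartment[md$cluster %in% c(1, 4)]),
                   "neoplastic")
  expect_identical(unique(md$compartment[md$cluster %in% c(2, 3)]),
                   "nonneoplastic")
  # a >95% normal cluster is normal_dominant
  ds2 <- labelled_ds(c(100, 100), c(0.99, 0.02), seed = 3)
  res2 <- suppressWarnings(call_neoplastic(ds2))
  expect_identical(res2$profiles$call, c("neoplastic", "normal_dominant"))
})

test_that("calls are invariant to cluster relabelling", {
  ds <- labelled_ds(rep(60, 3), c(0.99, 0.5, 0.98), seed = 4)
  res1 <- suppressWarnings(call_neoplastic(ds))
  md <- SummarizedExperiment::colData(ds)
  md$cluster <- c(7L, 2L, 9L)[md$cluster]
  SummarizedExperiment::colData(ds) <- md
  res2 <- suppressWarnings(call_neoplastic(ds))
  expect_identical(spot_meta(res1$dataset)$compartment,
                   spot_meta(res2$dataset)$compartment)
})

test_that("missing TFH markers warn, absent markers error", {
  counts <- rand_counts(30, 20, seed = 6)
  rownames(counts)[1] <- "CXCL13"
  meta <- data.frame(sample_id = "S1", tissue_type = "tumor",
                     cluster = rep(1:2, 10))
  ds <- normalize_spots(spot_dataset(counts, meta))
  expect_warning(profile_clusters(ds), "absent")
  counts2 <- rand_counts(30, 20, seed = 6)
  ds2 <- normalize_spots(spot_dataset(counts2, meta))
  expect_error(profile_clusters(ds2), "TFH marker")
})

test_that("composition similarity reproduces textbook Pearson values", {
  # two tumor samples spread over three neoplastic clusters
  build <- function(fracs_by_sample) {
    blocks <- list(); metas <- list()
    for (s in names(fracs_by_sample)) {
      n_per <- fracs_by_sample[[s]]
      n <- sum(n_per)
      cl <- rep(seq_along(n_per), n_per)
      blocks[[s]] <- cl
      metas[[s]] <- data.frame(sample_id = s, tissue_type = "tumor",
                               cluster = cl)
    }
    # add a normal-dominant cluster so clustering axes exist
    meta <- do.call(rbind, metas)
    meta <- rbind(meta, data.frame(sample_id = "LN1", tissue_type = "normal",
                                   cluster = 99))
    counts <- rand_counts(25, nrow(meta), seed = 8)
    rownames(counts)[1:5] <- c("CXCL13", "MME", "BCL6", "PDCD1", "ICOS")
    ds <- normalize_spots(spot_dataset(counts, meta))
    suppressWarnings(call_neoplastic(ds))$dataset
  }
  ds <- build(list(A1 = c(10, 30, 60), A2 = c(20, 30, 50)))
  sim <- composition_similarity(ds)
  expect_equal(diag(sim), c(A1 = 1, A2 = 1))
  oracle <- cor(c(0.1, 0.3, 0.6), c(0.2, 0.3, 0.5))
  expect_equal(sim["A1", "A2"], oracle, tolerance = 1e-12)
  expect_equal(sim["A2", "A1"], oracle, tolerance = 1e-12)

  dsi <- build(list(A1 = c(50, 50, 1), A2 = c(50, 50, 1)))
  expect_equal(composition_similarity(dsi)["A1", "A2"], 1.0)

  # (1,0) vs (0,1) over two clusters -> correlation -1
  ds2 <- build(list(A1 = c(40, 0, 0), A2 = c(0, 40, 0)))
  expect_equal(composition_similarity(ds2)["A1", "A2"], -1.0)
})
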