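test_that("the simulator is fully determined by its seed", {
  cfg <- quick_cfg(qc_fail_rate = 0.1, n_genes = 1000,
                   program_genes_per_type = 25, seed = 11)
  a <- simulate_st_dataset(cfg)
  b <- simulate_st_dataset(cfg)
  expect_identical(as.matrix(SummarizedExperiment::assay(a$dataset)),
                   as.matrix(SummarizedExperiment::assay(b$dataset)))
  expect_identical(a$truth$spots, b$truth$spots)
  expect_identical(a$truth$coexpr, b$truth$coexpr)
  c <- simulate_st_dataset(quick_cfg(qc_fail_rate = 0.1, n_genes = 1000,
                                     program_genes_per_type = 25, seed = 12))
  expect_false(identical(as.matrix(SummarizedExperiment::assay(a$dataset)),
                         as.matrix(SummarizedExperiment::assay(c$dataset))))
})

test_that("clean spots pass QC when no failures are planted", {
  sim <- simulate_st_dataset(qc_cfg(qc_fail_rate = 0, seed = 2))
  md <- spot_meta(sim$dataset)
  expect_true(all(md$total_umi >= 500))
  expect_true(all(md$n_genes_detected >= 500))
  expect_true(all(md$mito_fraction <= 0.05))
  expect_true(all(is.na(sim$truth$spots$qc_fail)))
})

test_that("planted QC failures fail exactly their assigned rule first", {
  sim <- simulate_st_dataset(qc_cfg(qc_fail_rate = 0.1, seed = 5))
  md <- spot_meta(sim$dataset)
  tr <- sim$truth$spots
  for (i in which(!is.na(tr$qc_fail))) {
    row <- md[md$spot_id == tr$spot_id[i], ]
    first <- if (row$total_umi < 500) "umi"
             else if (row$n_genes_detected < 500) "genes"
             else if (row$mito_fraction > 0.05) "mito"
             else NA_character_
    expect_identical(first, tr$qc_fail[i])
  }
})

test_that("imposed LR coexpression hits the configured stratum rate", {
  rates <- data.frame(sample_id = "AITL1",
                      compartment = c("neoplastic", "nonneoplastic"),
                      rate = c(0.30, 0.10))
  cfg <- quick_cfg(n_samples_normal = 0, spots_per_sample = c(500L, 500L),
                   coexpr_rates = rates, seed = 9)
  sim <- simulate_st_dataset(cfg)
  cx <- sim$truth$coexpr
  counts <- SummarizedExperiment::assay(sim$dataset, "counts")
  both <- as.numeric(counts["CD40", ]) >= 1 &
    as.numeric(counts["CD40LG", ]) >= 1
  expect_identical(unname(both), cx$designated)
  for (cc in c("neoplastic", "nonneoplastic")) {
    sub <- cx[cx$compartment == cc & cx$qc_clean, ]
    rate <- rates$rate[rates$compartment == cc]
    se <- sqrt(rate * (1 - rate) / nrow(sub))
    expect_lt(abs(mean(sub$designated) - rate), 3 * se)
  }
})

test_that("marker genes outside the gene universe are rejected", {
  expect_error(
    quick_cfg(gene_ids = sprintf("GENE%04d", 1:300)),
    "absent from gene universe"
  )
})

test_that("abundance simulation is the truth plus floored Gaussian noise", {
  sim <- simulate_st_dataset(quick_cfg(spots_per_sample = c(400L, 400L)))
  expect_error(simulate_abundance_matrix(sim$truth, noise_sd = -1),
               "non-negative")
  exact <- simulate_abundance_matrix(sim$truth, noise_sd = 0)
  expect_equal(exact, sim$truth$cell_counts + 0)
  ab <- simulate_abundance_matrix(sim$truth, noise_sd = 0.2, seed = 42)
  expect_true(all(ab >= 0))
  # grand mean cells per spot tracks the 10-cell deconvolution prior
  expect_lt(abs(mean(rowSums(sim$truth$cell_counts)) - 10) / 10, 0.05)
  # per-type mean absolute deviation bounded by the folded-normal mean
  mad_types <- colMeans(abs(ab - sim$truth$cell_counts))
  bound <- 0.2 * sqrt(2 / pi) + 4 * 0.2 / sqrt(nrow(ab))
  expect_true(all(mad_types <= bound))
})

test_that("variant fates follow the seeded assignment and rule anatomy", {
  vt <- simulate_variant_table(600, seed = 31)
  set.seed(31)
  fates <- c("kept", "fail_consequence", "fail_clinvar", "fail_vaf",
             "fail_popfreq", "fail_panel")
  redraw <- sample(fates, 600, replace = TRUE, prob = rep(1 / 6, 6))
  expect_identical(vt$truth$fate, redraw)

  v <- vt$variants
  i <- vt$truth$fate == "fail_vaf"
  expect_true(all(v$vaf[i] > 0.90))
  expect_true(all(!v$consequence[i] %in% c("intronic", "synonymous")))
  expect_true(all(!spotTME:::clinvar_benign(v$clinvar_class[i])))
  i <- vt$truth$fate == "fail_popfreq"
  expect_true(all(v$pop_af[i] > 0.01))
  expect_true(all(v$vaf[i] <= 0.90))

  all_kept <- simulate_variant_table(
    50, rule_mix = setNames(c(1, 0, 0, 0, 0, 0),
                            spotTME:::variant_fates()), seed = 3)
  fc <- filter_cascade(all_kept$variants)
  expect_equal(nrow(fc$kept), 50)
})

test_that("cohort generator honours censoring and errors on bad inputs", {
  expect_error(simulate_cohort(50, hazard_ratio = -1), "positive")
  expect_error(simulate_cohort(50, group_fraction = 1), "strictly between")
  coh <- simulate_cohort(80, censor_rate = 0, seed = 4)
  expect_true(all(coh$efs_event == 1))
  expect_true(all(coh$os_event == 1))
  coh2 <- simulate_cohort(400, censor_rate = 0.3, seed = 5)
  expect_lt(abs(mean(1 - coh2$efs_event) - 0.3), 3 * sqrt(0.3 * 0.7 / 400))
})
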