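#' Default end-to-end run configuration
#'
#' Nested configuration for [run_pipeline()]: `sim` overrides for
#' [st_sim_config()] (the default run simulates six sections at a few
#' hundred spots each so a full run completes in minutes; pass
#' `sim = list()` sparingly overridden for study-scale runs), `analysis`
#' overrides for [pipeline_config()], `cluster` engine settings, `variants`
#' and `cohort` branch settings, and `stages` toggles.
#'
#' @return nested configuration list.
#' @export
default_run_config <- function() {
  list(
    sim = list(spots_per_sample = c(250L, 350L), qc_fail_rate = 0.05),
    analysis = list(),
    cluster = list(k = 15, resolution = 1.3),
    abundance = list(noise_sd = 0.2),
    variants = list(n_variants = 600),
    cohort = list(n_patients = 200, group_fraction = 0.3,
                  hazard_ratio = 0.125, censor_rate = 0.2),
    signatures = list(sig_a = "Macro_M1", sig_b = "Macro_M2"),
    stages = list(composition = TRUE, enrichment = TRUE, deg = TRUE,
                  lr = TRUE, signatures = TRUE, variants = TRUE,
                  cohort = TRUE)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order - simulate (or load), QC,
#' normalization, HVG selection, clustering, neoplastic annotation,
#' composition similarity, abundance post-processing and enrichment,
#' one-vs-rest DEGs, ligand-receptor activity, signature dichotomies - plus
#' the independent variant-filter and cohort-survival branches, writing one
#' CSV/JSON per stage and a run manifest. All randomness flows from the
#' single `seed` through named per-stage substreams, so a rerun with the
#' same configuration and seed reproduces every output byte for byte
#' (manifest timestamp aside). A stage whose preconditions are not met
#' (e.g. fewer than two neoplastic clusters for composition similarity) is
#' marked "skipped" in the manifest; a genuine stage failure aborts with the
#' stage name, leaving earlier outputs intact.
#'
#' @param config `NULL` (defaults), a nested list (see
#'   [default_run_config()]), or a path to a YAML file of overrides.
#' @param out_dir output directory.
#' @param seed integer root seed.
#' @param simulate generate inputs with the synthetic module (`TRUE`) or
#'   load a dataset from `input_dir` (`FALSE`).
#' @param input_dir directory for [read_spot_dataset()] when
#'   `simulate = FALSE`.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = NULL, out_dir, seed = 1L,
                         simulate = TRUE, input_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_run_config(), config %||% list())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(seed, 6)
  acfg <- do.call(pipeline_config, cfg$analysis)
  manifest <- list(package = "spotTME",
                   version = as.character(utils::packageVersion("spotTME")),
                   seed = as.integer(seed),
                   config_hash = rlang::hash(cfg),
                   stages = list())
  note <- function(name, status, rows = NA, outputs = character()) {
    manifest$stages[[name]] <<- list(status = status, rows = rows,
                                     outputs = outputs)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  out <- function(f) file.path(out_dir, f)

  # -- inputs -----------------------------------------------------------
  truth <- NULL
  if (simulate) {
    sim <- run_stage("simulate", {
      scfg <- do.call(st_sim_config, c(cfg$sim, list(seed = seeds[1])))
      simulate_st_dataset(scfg)
    })
    ds <- sim$dataset
    truth <- sim$truth
    note("simulate", "ok", ncol(ds))
  } else {
    stop_if_not(!is.null(input_dir), "input_dir required when simulate = FALSE")
    ds <- run_stage("load", read_spot_dataset(input_dir))
    note("load", "ok", ncol(ds))
  }

  # -- preprocess -------------------------------------------------------
  qc <- run_stage("qc", qc_filter(ds, acfg))
  write.csv(qc$report, out("qc_report.csv"), row.names = FALSE)
  note("qc", "ok", ncol(qc$dataset), "qc_report.csv")
  ds <- run_stage("normalize", normalize_spots(qc$dataset))
  note("normalize", "ok", ncol(ds))
  ds <- run_stage("cluster", {
    engine <- snn_leiden_engine(k = cfg$cluster$k,
                                resolution = cfg$cluster$resolution)
    embed_and_cluster(ds, acfg, engine = engine, seed = seeds[2])
  })
  note("cluster", "ok", length(unique(spot_meta(ds)$cluster)))

  # -- annotation -------------------------------------------------------
  ann <- run_stage("annotate", call_neoplastic(ds, acfg))
  ds <- ann$dataset
  prof <- ann$profiles
  write.csv(cbind(prof, attr(prof, "fraction_by_sample")[
    as.character(prof$cluster_id), , drop = FALSE]),
    out("cluster_profiles.csv"), row.names = FALSE)
  write.csv(spot_meta(ds), out("spot_metadata.csv"), row.names = FALSE)
  note("annotate", "ok", nrow(prof),
       c("cluster_profiles.csv", "spot_metadata.csv"))

  md <- spot_meta(ds)
  n_neo_clusters <- length(unique(md$cluster[md$compartment == "neoplastic"]))

  if (isTRUE(cfg$stages$composition)) {
    if (n_neo_clusters >= 2 && sum(md$tissue_type == "tumor") > 0) {
      sim_mat <- run_stage("composition", composition_similarity(ds))
      write.csv(sim_mat, out("composition_similarity.csv"))
      note("composition", "ok", nrow(sim_mat), "composition_similarity.csv")
    } else {
      note("composition", "skipped (needs >= 2 neoplastic clusters)")
    }
  } else note("composition", "skipped")

  # -- abundance / enrichment ------------------------------------------
  if (isTRUE(cfg$stages$enrichment) && simulate) {
    enr <- run_stage("enrichment", {
      raw <- simulate_abundance_matrix(truth, cfg$abundance$noise_sd,
                                       seed = seeds[3])
      post <- postprocess_abundance(raw, acfg$rounding)
      enrichment_test(post, ds, acfg)
    })
    write.csv(enr, out("enrichment.csv"), row.names = FALSE)
    note("enrichment", "ok", nrow(enr), "enrichment.csv")
  } else note("enrichment", "skipped")

  # -- differential expression -----------------------------------------
  if (isTRUE(cfg$stages$deg)) {
    degs <- run_stage("deg", find_degs(ds, "cluster", acfg))
    write.csv(degs, out("degs.csv"), row.names = FALSE)
    note("deg", "ok", sum(degs$is_deg), "degs.csv")
  } else note("deg", "skipped")

  # -- ligand-receptor activity ----------------------------------------
  if (isTRUE(cfg$stages$lr)) {
    lr <- run_stage("lr", {
      pairs <- if (simulate) truth$config$lr_pairs else
        list(c("CD40", "CD40LG"))
      do.call(rbind, lapply(pairs, function(p) {
        act <- spot_activity(ds, lr_pair(p[1], p[2]), acfg)
        fr <- activity_fractions(act, ds)
        fr$ligand <- p[1]; fr$receptor <- p[2]
        fr
      }))
    })
    write.csv(lr, out("lr_fractions.csv"), row.names = FALSE)
    note("lr", "ok", nrow(lr), "lr_fractions.csv")
  } else note("lr", "skipped")

  # -- signatures -------------------------------------------------------
  if (isTRUE(cfg$stages$signatures) && simulate) {
    mm <- truth$config$marker_map
    sa <- cfg$signatures$sig_a; sb <- cfg$signatures$sig_b
    strata <- ifelse(md$compartment == "neoplastic", md$sample_id, NA)
    usable <- length(unique(stats::na.omit(strata))) >= 2 &&
      all(c(sa, sb) %in% names(mm))
    if (usable) {
      sig <- run_stage("signatures", {
        sigs <- list(gene_signature(sa, mm[[sa]]$genes, partner = sb),
                     gene_signature(sb, mm[[sb]]$genes, partner = sa))
        sc <- score_signatures(ds, sigs)
        dichotomy_compare(sc, ds, sa, sb, strata)
      })
      write.csv(sig$medians, out("signature_medians.csv"), row.names = FALSE)
      write.csv(sig$tests, out("signature_tests.csv"), row.names = FALSE)
      note("signatures", "ok", nrow(sig$tests),
           c("signature_medians.csv", "signature_tests.csv"))
    } else {
      note("signatures", "skipped (needs >= 2 neoplastic strata)")
    }
  } else note("signatures", "skipped")

  # -- variant branch ---------------------------------------------------
  if (isTRUE(cfg$stages$variants)) {
    vres <- run_stage("variants", {
      vt <- simulate_variant_table(cfg$variants$n_variants, seed = seeds[4])
      fc <- filter_cascade(vt$variants, cfg = acfg)
      list(vt = vt, fc = fc,
           summary = recurrent_gene_summary(
             fc$kept, sort(unique(vt$variants$sample_id))))
    })
    write.table(vres$fc$kept, out("variants_kept.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.csv(vres$fc$trace, out("variant_trace.csv"), row.names = FALSE)
    write.csv(vres$summary, out("variant_gene_summary.csv"),
              row.names = FALSE)
    note("variants", "ok", nrow(vres$fc$kept),
         c("variants_kept.tsv", "variant_trace.csv",
           "variant_gene_summary.csv"))
  } else note("variants", "skipped")

  # -- cohort branch ----------------------------------------------------
  if (isTRUE(cfg$stages$cohort)) {
    coh <- run_stage("cohort", {
      cohort <- do.call(simulate_cohort,
                        c(cfg$cohort, list(seed = seeds[5])))
      st <- stratify(cohort)
      km_efs <- km_logrank(cohort, st$groups, "efs")
      km_os <- km_logrank(cohort, st$groups, "os")
      rel <- relapse_test(cohort, st$groups)
      cox <- cox_multivariate(cohort, st$groups, c("age", "sex"))
      list(cohort = cohort, st = st, km_efs = km_efs, km_os = km_os,
           rel = rel, cox = cox)
    })
    write.csv(merge(coh$cohort, coh$st$groups, by = "patient_id"),
              out("cohort_groups.csv"), row.names = FALSE)
    jsonlite::write_json(list(
      cutpoints = as.list(coh$st$cutpoints),
      efs_logrank = list(chisq = coh$km_efs$chisq, p = coh$km_efs$p),
      os_logrank = list(chisq = coh$km_os$chisq, p = coh$km_os$p),
      relapse_fisher = list(odds_ratio = coh$rel$odds_ratio, p = coh$rel$p),
      cox = coh$cox
    ), out("survival_summary.json"), auto_unbox = TRUE, digits = NA)
    note("cohort", "ok", nrow(coh$cohort),
         c("cohort_groups.csv", "survival_summary.json"))
  } else note("cohort", "skipped")

  manifest$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
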