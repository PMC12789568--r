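#' Simulate a multi-sample spatial-transcriptome dataset with ground truth
#'
#' Generates Visium-style spot counts for tumor (AITL) and control lymph-node
#' sections under a negative-binomial model. Each spot draws true cell-type
#' proportions from a compartment-specific Dirichlet; its gene means mix
#' cell-type expression profiles (baseline mean, marker genes fold-elevated)
#' weighted by those proportions. A configured fraction of spots is corrupted
#' to fail exactly one QC rule (library size < 500, detected genes < 500, or
#' mitochondrial fraction > 5%), and ligand-receptor coexpression is imposed
#' per (sample, compartment) stratum at the configured rate by zero-truncated
#' resampling of designated spots and zeroing one partner elsewhere, so the
#' coexpression ground truth is exact among QC-clean spots.
#'
#' @param config an [st_sim_config()] object.
#' @return list with elements `dataset` (a spot dataset, see
#'   [spot_dataset()]) and `truth` (class `"st_ground_truth"`: per-spot
#'   compartments, QC fates, cell-type proportions and integer counts,
#'   per-pair coexpression designations, and expected per-gene compartment
#'   fold changes).
#' @examples
#' cfg <- st_sim_config(n_samples_tumor = 1, n_samples_normal = 1,
#'                      spots_per_sample = c(80, 80), n_genes = 60,
#'                      qc_fail_rate = 0, seed = 7)
#' sim <- simulate_st_dataset(cfg)
#' dim(sim$dataset)
#' @export
simulate_st_dataset <- function(config) {
  stop_if_not(inherits(config, "st_sim_config"),
              "config must come from st_sim_config()")
  set.seed(config$seed)

  genes <- config$gene_ids
  n_genes <- length(genes)
  mito <- grepl("^MT-", genes)
  types <- config$cell_types

  # cell-type expression profiles: genes x types
  base <- rep(config$nb_mean, n_genes)
  base[mito] <- base[mito] * config$mito_expr_mult
  P <- matrix(base, nrow = n_genes, ncol = length(types),
              dimnames = list(genes, types))
  for (mp in list(config$marker_map, config$program_map)) {
    for (ct in names(mp)) {
      mm <- mp[[ct]]
      P[match(mm$genes, genes), ct] <- config$nb_mean * mm$fold
    }
  }

  samples <- c(paste0("AITL", seq_len(config$n_samples_tumor)),
               if (config$n_samples_normal > 0)
                 paste0("LN", seq_len(config$n_samples_normal)))
  tissue <- rep(c("tumor", "normal"),
                c(config$n_samples_tumor, config$n_samples_normal))
  size_nb <- 1 / config$nb_dispersion

  count_blocks <- vector("list", length(samples))
  meta_blocks <- vector("list", length(samples))
  truth_spots <- vector("list", length(samples))
  props_blocks <- vector("list", length(samples))
  cells_blocks <- vector("list", length(samples))
  coexpr_blocks <- list()

  for (si in seq_along(samples)) {
    s <- samples[si]
    rng <- config$spots_per_sample
    n <- if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1)
    comp <- if (tissue[si] == "tumor") {
      ifelse(runif(n) < config$tumor_purity, "neoplastic", "nonneoplastic")
    } else rep("nonneoplastic", n)

    W <- matrix(0, nrow = length(types), ncol = n,
                dimnames = list(types, NULL))
    for (cc in c("neoplastic", "nonneoplastic")) {
      idx <- which(comp == cc)
      if (length(idx)) {
        W[, idx] <- t(rdirichlet(length(idx), config$dirichlet_alpha[, cc]))
      }
    }
    n_cells <- rpois(n, config$cells_per_spot)
    cellc <- matrix(0L, nrow = n, ncol = length(types),
                    dimnames = list(NULL, types))
    for (j in seq_len(n)) {
      if (n_cells[j] > 0) cellc[j, ] <- rmultinom(1, n_cells[j], W[, j])
    }

    mu <- P %*% W
    cnt <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = size_nb),
                  nrow = n_genes)

    # plant QC failures
    n_fail <- round(config$qc_fail_rate * n)
    fail_idx <- if (n_fail > 0) sample.int(n, n_fail) else integer(0)
    fail_mode <- rep(NA_character_, n)
    if (n_fail > 0) {
      fail_mode[fail_idx] <- sample(c("umi", "genes", "mito"), n_fail,
                                    replace = TRUE)
      for (j in fail_idx) {
        cnt[, j] <- corrupt_spot(cnt[, j], fail_mode[j], mito,
                                 mu[, j])
      }
    }

    # repair any clean spot that fails QC by chance (feasible universes only)
    clean <- setdiff(seq_len(n), fail_idx)
    if (n_genes >= 600) {
      for (j in clean) {
        tries <- 0
        while (!passes_qc_vec(cnt[, j], mito) && tries < 50) {
          cnt[, j] <- rnbinom(n_genes, mu = mu[, j], size = size_nb)
          tries <- tries + 1
        }
        if (!passes_qc_vec(cnt[, j], mito)) {
          stop("could not generate a QC-passing spot; increase nb_mean or n_genes",
               call. = FALSE)
        }
      }
    }

    # ligand-receptor coexpression forcing, exact among clean spots
    for (pi in seq_along(config$lr_pairs)) {
      pair <- config$lr_pairs[[pi]]
      gl <- match(pair[1], genes)
      gr <- match(pair[2], genes)
      designated <- rep(FALSE, n)
      for (cc in unique(comp)) {
        strat_clean <- intersect(which(comp == cc), clean)
        rr <- config$coexpr_rates
        hit <- rr$sample_id == s & rr$compartment == cc
        rate <- if (any(hit)) rr$rate[which(hit)[1]] else 0.25
        k <- round(rate * length(strat_clean))
        if (k > 0) {
          designated[sample(strat_clean, k)] <- TRUE
        }
      }
      for (j in which(designated)) {
        if (cnt[gl, j] == 0) cnt[gl, j] <- rztnbinom(1, mu[gl, j], size_nb)
        if (cnt[gr, j] == 0) cnt[gr, j] <- rztnbinom(1, mu[gr, j], size_nb)
      }
      both <- which(!designated & cnt[gl, ] >= 1 & cnt[gr, ] >= 1)
      if (length(both)) {
        drop_l <- runif(length(both)) < 0.5
        cnt[gl, both[drop_l]] <- 0L
        cnt[gr, both[!drop_l]] <- 0L
      }
      coexpr_blocks[[length(coexpr_blocks) + 1L]] <- data.frame(
        spot_id = sprintf("%s_%05d", s, seq_len(n)),
        sample_id = s, compartment = comp,
        ligand = pair[1], receptor = pair[2],
        designated = designated,
        qc_clean = seq_len(n) %in% clean,
        stringsAsFactors = FALSE
      )
    }

    ids <- sprintf("%s_%05d", s, seq_len(n))
    ncol_grid <- ceiling(sqrt(n))
    count_blocks[[si]] <- as(cnt, "CsparseMatrix")
    colnames(count_blocks[[si]]) <- ids
    meta_blocks[[si]] <- data.frame(
      sample_id = s, tissue_type = tissue[si],
      array_row = (seq_len(n) - 1L) %/% ncol_grid,
      array_col = (seq_len(n) - 1L) %% ncol_grid,
      stringsAsFactors = FALSE
    )
    truth_spots[[si]] <- data.frame(
      spot_id = ids, sample_id = s, tissue_type = tissue[si],
      compartment = comp, qc_fail = fail_mode, stringsAsFactors = FALSE
    )
    rownames(cellc) <- ids
    Wt <- t(W); rownames(Wt) <- ids
    props_blocks[[si]] <- Wt
    cells_blocks[[si]] <- cellc
  }

  counts <- do.call(cbind, count_blocks)
  rownames(counts) <- genes
  meta <- do.call(rbind, meta_blocks)
  ds <- spot_dataset(counts, meta)

  # expected per-gene compartment means and fold under the mixture model
  ealpha <- sweep(config$dirichlet_alpha, 2,
                  colSums(config$dirichlet_alpha), "/")
  mu_comp <- P %*% ealpha
  eps <- 1e-9
  gene_fold <- data.frame(
    gene = genes,
    mu_neoplastic = mu_comp[, "neoplastic"],
    mu_nonneoplastic = mu_comp[, "nonneoplastic"],
    fold = (mu_comp[, "neoplastic"] + eps) / (mu_comp[, "nonneoplastic"] + eps),
    stringsAsFactors = FALSE
  )

  truth <- structure(list(
    spots = do.call(rbind, truth_spots),
    cell_props = do.call(rbind, props_blocks),
    cell_counts = do.call(rbind, cells_blocks),
    coexpr = do.call(rbind, coexpr_blocks),
    gene_fold = gene_fold,
    config = config
  ), class = "st_ground_truth")

  list(dataset = ds, truth = truth)
}

passes_qc_vec <- function(v, mito, min_umi = 500, min_genes = 500,
                          max_mito = 0.05) {
  tot <- sum(v)
  tot >= min_umi && sum(v > 0) >= min_genes &&
    (if (tot > 0) sum(v[mito]) / tot else 0) <= max_mito
}

# Corrupt one spot's count vector so that it fails exactly the given QC rule
# first (rules checked in order: library size, genes detected, mito fraction).
corrupt_spot <- function(v, mode, mito, mu) {
  tot <- sum(v)
  if (mode == "umi") {
    v <- rbinom(length(v), v, min(1, 300 / max(tot, 301)))
    while (sum(v) >= 500) v <- floor(v / 2)
  } else if (mode == "genes") {
    nonmito <- which(!mito)
    keep <- sample(nonmito, min(300L, length(nonmito)))
    target <- max(tot, 600)
    w <- mu[keep] + 1e-9
    v[] <- 0L
    v[keep] <- rmultinom(1, target, w)
  } else if (mode == "mito") {
    mito_tot <- sum(v[mito])
    extra <- ceiling(max(0, (0.10 * tot - mito_tot) / 0.90)) + 1
    add <- rmultinom(1, extra, rep(1, sum(mito)))
    v[mito] <- v[mito] + add
  }
  v
}
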