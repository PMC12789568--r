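# Fixtures built in code: small datasets and independent oracles.

# A small simulated dataset configuration (fast; gene universe too small for
# absolute 500-gene QC, so QC-oriented tests use qc_cfg() instead).
quick_cfg <- function(...) {
  args <- utils::modifyList(list(
    n_samples_tumor = 1, n_samples_normal = 1,
    spots_per_sample = c(100L, 100L), n_genes = 300,
    program_genes_per_type = 5, qc_fail_rate = 0, seed = 1L
  ), list(...))
  do.call(st_sim_config, args)
}

# Full-size gene universe so clean spots clear the 500/500/5% thresholds.
qc_cfg <- function(...) {
  args <- utils::modifyList(list(
    n_samples_tumor = 2, n_samples_normal = 1,
    spots_per_sample = c(120L, 120L), n_genes = 1000, seed = 1L
  ), list(...))
  do.call(st_sim_config, args)
}

# Hand-built dataset: counts drawn around per-group means so that clustering
# structure (or its absence) is controlled by the test.
manual_ds <- function(counts, samples = "S1", tissue = "tumor",
                      normalize = TRUE) {
  n <- ncol(counts)
  meta <- data.frame(
    sample_id = rep_len(samples, n),
    tissue_type = rep_len(tissue, n)
  )
  ds <- spot_dataset(counts, meta)
  if (normalize) ds <- normalize_spots(ds)
  ds
}

rand_counts <- function(n_genes, n_spots, seed = 1, lambda = 5) {
  set.seed(seed)
  matrix(rpois(n_genes * n_spots, lambda), nrow = n_genes,
         dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n_spots))))
}

# Independent Mann-Whitney oracle: U by explicit pair counting and the exact
# two-sided p by full enumeration over all group assignments of the values.
mw_enum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  ucount <- function(a, b) {
    s <- 0
    for (ai in a) for (bi in b) s <- s + (ai > bi) + 0.5 * (ai == bi)
    s
  }
  U <- ucount(x, y)
  pooled <- c(x, y)
  idx <- utils::combn(n1 + n2, n1)
  Us <- apply(idx, 2, function(ii) ucount(pooled[ii], pooled[-ii]))
  tol <- 1e-9
  list(U = U,
       p = min(1, 2 * min(mean(Us <= U + tol), mean(Us >= U - tol))))
}

# Independent normal-approximation Mann-Whitney (tie-corrected, no
# continuity correction), written from the textbook formula.
mw_normal_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- as.numeric(table(r))
  s2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  p <- if (s2 <= 0) 1 else min(1, 2 * pnorm(-abs(U - n1 * n2 / 2) / sqrt(s2)))
  list(U = U, p = p)
}

# Brute-force DEG reference: direct loops over genes, no shared code with
# find_degs beyond mann_whitney_u's documented definition.
deg_brute_force <- function(norm_mat, counts_mat, labels, cfg) {
  eps <- 1e-9
  out <- list()
  for (g in sort(unique(labels))) {
    inm <- labels == g
    if (sum(inm) < 2) next
    qs <- ps <- folds <- dets <- numeric(nrow(norm_mat))
    for (i in seq_len(nrow(norm_mat))) {
      lin <- expm1(norm_mat[i, ])
      folds[i] <- (mean(lin[inm]) + eps) / (mean(lin[!inm]) + eps)
      dets[i] <- mean(counts_mat[i, inm] >= 1)
      ps[i] <- mw_normal_oracle(norm_mat[i, inm], norm_mat[i, !inm])$p
    }
    qs <- p.adjust(ps, "BH")
    out[[as.character(g)]] <- data.frame(
      gene = rownames(norm_mat), cluster = g, fold = folds,
      detection_fraction = dets, p = ps, q = qs,
      is_deg = folds > cfg$deg_fold & dets >= cfg$deg_detection &
        qs < cfg$deg_q
    )
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Two-sided Fisher exact p by hypergeometric enumeration on a 2x2 table.
fisher_enum_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
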