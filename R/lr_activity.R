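#' Define a ligand-receptor pair
#'
#' @param ligand,receptor distinct gene ids.
#' @return list of class `"lr_pair"`.
#' @export
lr_pair <- function(ligand, receptor) {
  stop_if_not(is.character(ligand) && is.character(receptor) &&
                length(ligand) == 1 && length(receptor) == 1,
              "ligand and receptor must be single gene ids")
  stop_if_not(ligand != receptor, "ligand and receptor must differ")
  structure(list(ligand = ligand, receptor = receptor), class = "lr_pair")
}

#' Spot-level ligand-receptor colocalization activity
#'
#' The activity of a receptor-ligand axis in a spot is the lower of the two
#' genes' normalized expression values (coexpression quantified by the
#' minimum); a spot is "active" when both transcripts are detected (raw
#' count >= 1 for both, equivalently activity above `cfg$lr_active_min`
#' under the zero-preserving normalization). Symmetric in the pair.
#'
#' @param ds spot dataset with a normalized layer.
#' @param pair an [lr_pair()] (or length-2 character vector).
#' @param cfg a [pipeline_config()].
#' @return data.frame of class `"lr_activity"`: spot_id, activity, active;
#'   the pair is attached as `attr(, "pair")`.
#' @export
spot_activity <- function(ds, pair, cfg = pipeline_config()) {
  if (is.character(pair) && length(pair) == 2) pair <- lr_pair(pair[1], pair[2])
  stop_if_not(inherits(pair, "lr_pair"), "pair must be an lr_pair()")
  x <- norm_layer(ds)
  for (g in c(pair$ligand, pair$receptor)) {
    if (!g %in% rownames(x)) {
      stop("gene '", g, "' is not present in the dataset", call. = FALSE)
    }
  }
  counts <- SummarizedExperiment::assay(ds, "counts")
  act <- pmin(as.numeric(x[pair$ligand, ]), as.numeric(x[pair$receptor, ]))
  active <- as.numeric(counts[pair$ligand, ]) >= 1 &
    as.numeric(counts[pair$receptor, ]) >= 1 &
    act > cfg$lr_active_min
  out <- data.frame(spot_id = colnames(ds), activity = act, active = active,
                    stringsAsFactors = FALSE)
  attr(out, "pair") <- pair
  class(out) <- c("lr_activity", "data.frame")
  out
}

#' Active-spot fractions per sample and compartment
#'
#' Fraction of active spots in every (sample, compartment) stratum over all
#' spots of the dataset, plus a per-sample overall row. Empty strata are
#' reported with `n = 0` and a missing fraction.
#'
#' @param result a [spot_activity()] result.
#' @param ds the matching spot dataset with compartments called.
#' @return data.frame: sample_id, compartment, n, n_active, active_fraction.
#' @export
activity_fractions <- function(result, ds) {
  md <- spot_meta(ds)
  stop_if_not(identical(result$spot_id, md$spot_id),
              "activity result does not match the dataset's spots")
  stop_if_not(!anyNA(md$compartment),
              "compartments missing; run call_neoplastic()")
  samples <- sort(unique(md$sample_id))
  rows <- list()
  for (s in samples) {
    for (cc in c("neoplastic", "nonneoplastic", "overall")) {
      sel <- md$sample_id == s &
        (cc == "overall" | md$compartment == cc)
      n <- sum(sel)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, compartment = cc, n = n,
        n_active = sum(result$active[sel]),
        active_fraction = if (n > 0) mean(result$active[sel]) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Compare ligand-receptor activity between two strata
#'
#' Two-sided Fisher exact test on the active/inactive counts of two strata.
#' A stratum is selected by sample and/or compartment (`NULL` = no
#' restriction). Zero-margin tables report p = 1 with a warning.
#'
#' @param result a [spot_activity()] result.
#' @param ds the matching spot dataset.
#' @param stratum_a,stratum_b lists with optional elements `sample_id` and
#'   `compartment`.
#' @return data.frame: n and active counts per stratum, odds ratio, p.
#' @export
compare_activity <- function(result, ds, stratum_a, stratum_b) {
  md <- spot_meta(ds)
  sel <- function(st) {
    keep <- rep(TRUE, nrow(md))
    if (!is.null(st$sample_id)) keep <- keep & md$sample_id %in% st$sample_id
    if (!is.null(st$compartment)) keep <- keep & md$compartment %in% st$compartment
    keep
  }
  a <- sel(stratum_a); b <- sel(stratum_b)
  stop_if_not(sum(a) >= 1 && sum(b) >= 1, "both strata must be non-empty")
  tab <- rbind(a = c(active = sum(result$active[a]),
                     inactive = sum(!result$active[a])),
               b = c(active = sum(result$active[b]),
                     inactive = sum(!result$active[b])))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 table (zero margin); p set to 1", call. = FALSE)
    p <- 1; or <- NA_real_
  } else {
    ft <- stats::fisher.test(tab)
    p <- ft$p.value; or <- unname(ft$estimate)
  }
  data.frame(n_a = sum(a), active_a = tab["a", "active"],
             n_b = sum(b), active_b = tab["b", "active"],
             odds_ratio = or, p = p)
}
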