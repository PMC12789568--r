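# Differential expression under the triple-gate rule:
# fold > 2^0.5 on the linear normalized scale, detection >= 25% of the
# cluster's spots, BH q < 1e-4 (Mann-Whitney one-vs-rest p-values).

deg_table_for_groups <- function(ds, in_mask, rest_mask, label, cfg,
                                 eps = 1e-9) {
  norm <- norm_layer(ds)
  counts <- SummarizedExperiment::assay(ds, "counts")
  linear <- sparse_expm1(norm)
  mean_in <- Matrix::rowMeans(linear[, in_mask, drop = FALSE])
  mean_rest <- Matrix::rowMeans(linear[, rest_mask, drop = FALSE])
  fold <- (mean_in + eps) / (mean_rest + eps)
  detection <- Matrix::rowMeans(counts[, in_mask, drop = FALSE] > 0)

  sub <- as.matrix(norm[, in_mask | rest_mask, drop = FALSE])
  in_sub <- in_mask[in_mask | rest_mask]
  tests <- apply(sub, 1, function(v) {
    mw <- mann_whitney_u(v[in_sub], v[!in_sub])
    c(mw$U, mw$p)
  })
  out <- data.frame(
    gene = rownames(norm), cluster = label,
    fold = as.numeric(fold), detection_fraction = as.numeric(detection),
    U = tests[1, ], p = tests[2, ], stringsAsFactors = FALSE
  )
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$is_deg <- out$fold > cfg$deg_fold &
    out$detection_fraction >= cfg$deg_detection &
    out$q < cfg$deg_q
  rownames(out) <- NULL
  out
}

#' One-vs-rest differential expression per cluster
#'
#' For each (gene, cluster) pair: a two-sided Mann-Whitney U test of the
#' normalized expression in the cluster against all other spots; fold change
#' as the ratio of de-logged (linear-scale) normalized means with a 1e-9
#' pseudocount; detection fraction as the share of the cluster's spots with
#' raw count >= 1; BH adjustment across genes within each cluster. A gene is
#' a DEG when fold > `cfg$deg_fold` (2^0.5), detection >=
#' `cfg$deg_detection` (0.25) and q < `cfg$deg_q` (1e-4). Single-spot
#' clusters are skipped with a warning.
#'
#' @param ds spot dataset with a normalized layer and group labels.
#' @param group_by colData column holding the labels (default `"cluster"`).
#' @param cfg a [pipeline_config()].
#' @return data.frame: gene, cluster, fold, detection_fraction, U, p, q,
#'   is_deg.
#' @export
find_degs <- function(ds, group_by = "cluster", cfg = pipeline_config()) {
  labels <- SummarizedExperiment::colData(ds)[[group_by]]
  stop_if_not(!is.null(labels) && !anyNA(labels),
              "group labels '", group_by, "' missing")
  groups <- sort(unique(labels))
  stop_if_not(length(groups) >= 2, "need at least two groups")
  res <- list()
  for (g in groups) {
    in_mask <- labels == g
    if (sum(in_mask) < 2) {
      warning("cluster ", g, " has fewer than 2 spots; skipped",
              call. = FALSE)
      next
    }
    res[[as.character(g)]] <-
      deg_table_for_groups(ds, in_mask, !in_mask, g, cfg)
  }
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Differential expression between two explicit cluster groups
#'
#' Applies the same fold / detection / q rule to a two-group contrast, e.g.
#' one neoplastic cluster against the remaining neoplastic clusters.
#' Detection is computed on the first group's spots; swapping the groups
#' inverts the fold and preserves the p-value.
#'
#' @param ds spot dataset with a normalized layer and cluster labels.
#' @param group_a,group_b disjoint vectors of cluster labels.
#' @param group_by colData column holding the labels.
#' @param cfg a [pipeline_config()].
#' @return data.frame as in [find_degs()], with `cluster` naming the
#'   contrast.
#' @export
contrast_degs <- function(ds, group_a, group_b, group_by = "cluster",
                          cfg = pipeline_config()) {
  stop_if_not(length(intersect(group_a, group_b)) == 0,
              "group_a and group_b overlap")
  labels <- SummarizedExperiment::colData(ds)[[group_by]]
  in_mask <- labels %in% group_a
  rest_mask <- labels %in% group_b
  stop_if_not(sum(in_mask) >= 2 && sum(rest_mask) >= 2,
              "both groups need at least 2 spots")
  label <- paste0(paste(group_a, collapse = "+"), "_vs_",
                  paste(group_b, collapse = "+"))
  deg_table_for_groups(ds, in_mask, rest_mask, label, cfg)
}
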