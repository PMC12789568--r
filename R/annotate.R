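#' Profile clusters by sample provenance and TFH marker expression
#'
#' For every cluster, tallies the fraction of spots contributed by each
#' sample, the total fraction originating from tumor sections, and a TFH
#' score: the mean over the cluster's spots of each spot's mean normalized
#' expression of the TFH marker set (CXCL13, MME, BCL6, PDCD1, ICOS by
#' default). Markers absent from the dataset are dropped with a warning; if
#' none are present the profiling errors.
#'
#' @param ds spot dataset with cluster labels and a normalized layer.
#' @param cfg a [pipeline_config()].
#' @return data.frame of class `"cluster_profiles"`: `cluster_id`, `n_spots`,
#'   `fraction_tumor_origin`, `tfh_score`; the full cluster x sample fraction
#'   matrix is in `attr(, "fraction_by_sample")`.
#' @export
profile_clusters <- function(ds, cfg = pipeline_config()) {
  md <- spot_meta(ds)
  stop_if_not(!anyNA(md$cluster), "cluster labels missing; run embed_and_cluster()")
  x <- norm_layer(ds)
  present <- intersect(cfg$tfh_markers, rownames(x))
  if (length(present) == 0) {
    stop("none of the TFH marker genes (",
         paste(cfg$tfh_markers, collapse = ", "),
         ") are present in the dataset", call. = FALSE)
  }
  if (length(present) < length(cfg$tfh_markers)) {
    warning("TFH markers absent from dataset: ",
            paste(setdiff(cfg$tfh_markers, present), collapse = ", "),
            "; scoring over the present subset", call. = FALSE)
  }
  spot_tfh <- Matrix::colMeans(x[present, , drop = FALSE])

  tab <- table(md$cluster, md$sample_id)
  frac <- sweep(tab, 1, rowSums(tab), "/")
  tumor_samples <- unique(md$sample_id[md$tissue_type == "tumor"])
  clusters <- as.integer(rownames(tab))
  prof <- data.frame(
    cluster_id = clusters,
    n_spots = as.integer(rowSums(tab)),
    fraction_tumor_origin = rowSums(frac[, colnames(frac) %in% tumor_samples,
                                         drop = FALSE]),
    tfh_score = vapply(clusters, function(cl) {
      mean(spot_tfh[md$cluster == cl])
    }, 0),
    stringsAsFactors = FALSE
  )
  rownames(prof) <- NULL
  attr(prof, "fraction_by_sample") <- as.matrix(frac)
  class(prof) <- c("cluster_profiles", "data.frame")
  prof
}

#' Call neoplastic clusters from sample provenance
#'
#' A cluster is called `neoplastic` when strictly more than
#' `cfg$provenance_threshold` (default 95%) of its spots originate from tumor
#' sections, `normal_dominant` when strictly more than that fraction comes
#' from normal sections, and `mixed` otherwise; a cluster at exactly 95%
#' tumor provenance is therefore `mixed`. Spots inherit a binary compartment:
#' `neoplastic` for neoplastic clusters, `nonneoplastic` for every other
#' cluster. Provenance decides the call; the TFH score is reported evidence,
#' and a warning flags any neoplastic-called cluster whose TFH score falls
#' below the across-cluster median.
#'
#' @param ds spot dataset with cluster labels.
#' @param cfg a [pipeline_config()].
#' @param profiles optional precomputed [profile_clusters()] output.
#' @return list with `dataset` (compartment labels filled in) and `profiles`
#'   (with a `call` column).
#' @export
call_neoplastic <- function(ds, cfg = pipeline_config(),
                            profiles = profile_clusters(ds, cfg)) {
  thr <- cfg$provenance_threshold
  call <- ifelse(profiles$fraction_tumor_origin > thr, "neoplastic",
                 ifelse(1 - profiles$fraction_tumor_origin > thr,
                        "normal_dominant", "mixed"))
  profiles$call <- call
  neo <- profiles$cluster_id[call == "neoplastic"]
  if (length(neo)) {
    med <- stats::median(profiles$tfh_score)
    low <- profiles$cluster_id[call == "neoplastic" &
                                 profiles$tfh_score < med]
    if (length(low)) {
      warning("neoplastic-called cluster(s) with TFH score below the ",
              "across-cluster median: ", paste(low, collapse = ", "),
              call. = FALSE)
    }
  }
  md_cluster <- SummarizedExperiment::colData(ds)$cluster
  SummarizedExperiment::colData(ds)$compartment <-
    ifelse(md_cluster %in% neo, "neoplastic", "nonneoplastic")
  list(dataset = ds, profiles = profiles)
}

#' Pearson similarity of neoplastic-cluster composition between samples
#'
#' For each tumor sample, forms the vector of its neoplastic spots' fractions
#' across the neoplastic clusters (summing to 1) and correlates sample pairs
#' (Pearson). Requires at least two neoplastic clusters. A tumor sample with
#' no neoplastic spots gets a missing row/column with a warning.
#'
#' @param ds spot dataset with compartments called.
#' @return sample x sample correlation matrix (diagonal 1).
#' @export
composition_similarity <- function(ds) {
  md <- spot_meta(ds)
  stop_if_not(!anyNA(md$compartment), "compartments missing; run call_neoplastic()")
  neo_clusters <- sort(unique(md$cluster[md$compartment == "neoplastic"]))
  stop_if_not(length(neo_clusters) >= 2,
              "need at least two neoplastic clusters, found ",
              length(neo_clusters))
  tumor_samples <- sort(unique(md$sample_id[md$tissue_type == "tumor"]))
  comp <- matrix(NA_real_, nrow = length(tumor_samples),
                 ncol = length(neo_clusters),
                 dimnames = list(tumor_samples, as.character(neo_clusters)))
  for (s in tumor_samples) {
    sel <- md$sample_id == s & md$compartment == "neoplastic"
    if (!any(sel)) {
      warning("tumor sample ", s, " has no neoplastic spots; ",
              "similarity set to missing", call. = FALSE)
      next
    }
    tt <- table(factor(md$cluster[sel], levels = neo_clusters))
    comp[s, ] <- as.numeric(tt) / sum(tt)
  }
  out <- matrix(NA_real_, length(tumor_samples), length(tumor_samples),
                dimnames = list(tumor_samples, tumor_samples))
  for (a in tumor_samples) for (b in tumor_samples) {
    if (!anyNA(comp[a, ]) && !anyNA(comp[b, ])) {
      out[a, b] <- if (a == b) 1 else stats::cor(comp[a, ], comp[b, ])
    }
  }
  out
}
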