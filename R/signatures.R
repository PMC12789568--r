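#' Define a gene signature
#'
#' @param name signature name.
#' @param genes non-empty character vector of unique gene ids.
#' @param partner optional name of the dichotomy partner signature
#'   (e.g. M1 <-> M2, angiogenesis <-> phagocytosis).
#' @return list of class `"gene_signature"`.
#' @export
gene_signature <- function(name, genes, partner = NULL) {
  stop_if_not(length(genes) >= 1, "signature '", name, "' has no genes")
  stop_if_not(!anyDuplicated(genes), "signature '", name,
              "' has duplicated genes")
  structure(list(name = name, genes = genes, partner = partner),
            class = "gene_signature")
}

#' Read signatures from a GMT file
#' @param path GMT file (name, description, genes... per tab-separated line).
#' @return named list of [gene_signature()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sigs <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    gene_signature(f[1], unique(f[-(1:2)]))
  })
  stats::setNames(sigs, vapply(sigs, `[[`, "", "name"))
}

#' Read signatures from a two-column TSV (signature, gene)
#' @param path TSV file with columns `signature` and `gene`.
#' @return named list of [gene_signature()] objects.
#' @export
read_signature_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stop_if_not(all(c("signature", "gene") %in% names(df)),
              "TSV must have columns 'signature' and 'gene'")
  sp <- split(df$gene, df$signature)
  stats::setNames(lapply(names(sp), function(nm)
    gene_signature(nm, unique(sp[[nm]]))), names(sp))
}

#' Score gene signatures per spot
#'
#' The score of a signature in a spot is the mean, over the signature's
#' genes present in the dataset, of the gene's z-scored (across spots)
#' normalized expression. Zero-variance genes contribute 0 rather than NaN,
#' so a dataset of constant genes scores 0 everywhere. Missing genes are
#' messaged; a signature with no present genes errors.
#'
#' This is a mean-z-score module score, not a rank-based GSVA/ssGSEA
#' statistic; it supports the ordinal spot-group comparisons made here, and
#' an externally computed score matrix can be used anywhere a score table is
#' accepted.
#'
#' @param ds spot dataset with a normalized layer.
#' @param sigs list of [gene_signature()] objects (or a single one).
#' @return spots x signatures numeric matrix.
#' @export
score_signatures <- function(ds, sigs) {
  if (inherits(sigs, "gene_signature")) sigs <- list(sigs)
  x <- as.matrix(norm_layer(ds))
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  z <- (x - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  scores <- vapply(sigs, function(sg) {
    present <- intersect(sg$genes, rownames(z))
    if (length(present) == 0) {
      stop("signature '", sg$name, "' has no genes present in the dataset",
           call. = FALSE)
    }
    if (length(present) < length(sg$genes)) {
      message("signature '", sg$name, "': ",
              length(sg$genes) - length(present), " gene(s) absent")
    }
    colMeans(z[present, , drop = FALSE])
  }, numeric(ncol(x)))
  colnames(scores) <- vapply(sigs, `[[`, "", "name")
  rownames(scores) <- colnames(ds)
  scores
}

#' Compare a signature dichotomy between spot strata
#'
#' For a pair of signatures (e.g. M1 vs M2 polarization, angiogenesis vs
#' phagocytosis) and a stratification of spots, reports per-stratum medians
#' of both scores and, for every pair of strata, a two-sided Mann-Whitney U
#' test per signature with BH adjustment across all tests. Strata with fewer
#' than 2 spots are skipped with a warning.
#'
#' @param scores matrix from [score_signatures()].
#' @param ds the matching spot dataset.
#' @param sig_a,sig_b column names of the two signatures in `scores`.
#' @param strata either a colData column name or a vector of stratum labels
#'   (NA = spot excluded).
#' @return list with `medians` (stratum x signature medians and n) and
#'   `tests` (stratum_a, stratum_b, signature, U, p, q).
#' @export
dichotomy_compare <- function(scores, ds, sig_a, sig_b, strata) {
  stop_if_not(all(c(sig_a, sig_b) %in% colnames(scores)),
              "sig_a/sig_b must be columns of the score matrix")
  if (is.character(strata) && length(strata) == 1) {
    strata <- SummarizedExperiment::colData(ds)[[strata]]
  }
  stop_if_not(length(strata) == nrow(scores),
              "strata must label every spot")
  keep <- !is.na(strata)
  strata <- as.character(strata[keep])
  sc <- scores[keep, , drop = FALSE]
  lv <- sort(unique(strata))
  sizes <- table(strata)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("strata with fewer than 2 spots skipped: ",
            paste(small, collapse = ", "), call. = FALSE)
    lv <- setdiff(lv, small)
  }
  stop_if_not(length(lv) >= 2, "need at least two usable strata")
  medians <- do.call(rbind, lapply(lv, function(l) {
    sel <- strata == l
    data.frame(stratum = l, n = sum(sel),
               median_a = stats::median(sc[sel, sig_a]),
               median_b = stats::median(sc[sel, sig_b]),
               stringsAsFactors = FALSE)
  }))
  names(medians)[3:4] <- paste0("median_", c(sig_a, sig_b))
  tests <- list()
  for (i in seq_along(lv)) for (j in seq_along(lv)) {
    if (i >= j) next
    for (sg in c(sig_a, sig_b)) {
      mw <- mann_whitney_u(sc[strata == lv[i], sg],
                           sc[strata == lv[j], sg])
      tests[[length(tests) + 1L]] <- data.frame(
        stratum_a = lv[i], stratum_b = lv[j], signature = sg,
        U = mw$U, p = mw$p, stringsAsFactors = FALSE
      )
    }
  }
  tests <- do.call(rbind, tests)
  tests$q <- stats::p.adjust(tests$p, method = "BH")
  list(medians = medians, tests = tests)
}
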