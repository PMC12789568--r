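#' Build a spot-level dataset
#'
#' Wraps a genes x spots count matrix and per-spot metadata into a
#' [SingleCellExperiment::SingleCellExperiment] used throughout the package.
#' Per-spot QC fields (`total_umi`, `n_genes_detected`, `mito_fraction`) are
#' computed from the raw counts; mitochondrial genes are identified by the
#' human `"MT-"` gene-name prefix. The normalized expression layer, when
#' produced by [normalize_spots()], lives in the `"normalized"` assay.
#'
#' @param counts genes x spots matrix of non-negative integer counts (dense
#'   or sparse); rownames are gene identifiers, colnames spot barcodes.
#' @param meta data.frame with one row per spot. Required columns:
#'   `sample_id`, `tissue_type` (`"tumor"` or `"normal"`). Optional:
#'   `array_row`, `array_col`, and any further annotation.
#' @return A `SingleCellExperiment` with assay `"counts"` and colData columns
#'   `sample_id`, `tissue_type`, `array_row`, `array_col`, `total_umi`,
#'   `n_genes_detected`, `mito_fraction`, `cluster` (NA until clustering) and
#'   `compartment` (NA until neoplastic calling).
#' @examples
#' counts <- matrix(rpois(60, 5), nrow = 6,
#'                  dimnames = list(paste0("G", 1:6), paste0("s", 1:10)))
#' meta <- data.frame(sample_id = "S1", tissue_type = "tumor")
#' ds <- spot_dataset(counts, meta)
#' @export
spot_dataset <- function(counts, meta) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene rownames and spot colnames", call. = FALSE)
  }
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (any(counts@x < 0)) stop("counts must be non-negative", call. = FALSE)
  meta <- as.data.frame(meta)
  if (nrow(meta) == 1 && ncol(counts) > 1) {
    meta <- meta[rep(1L, ncol(counts)), , drop = FALSE]
  }
  stop_if_not(nrow(meta) == ncol(counts),
              "meta must have one row per spot (", ncol(counts), ")")
  for (col in c("sample_id", "tissue_type")) {
    stop_if_not(col %in% names(meta), "meta lacks required column '", col, "'")
  }
  stop_if_not(all(meta$tissue_type %in% c("tumor", "normal")),
              "tissue_type must be 'tumor' or 'normal'")
  meta <- as.data.frame(meta)
  rownames(meta) <- colnames(counts)
  if (is.null(meta$array_row)) meta$array_row <- NA_integer_
  if (is.null(meta$array_col)) meta$array_col <- NA_integer_

  mito <- grepl("^MT-", rownames(counts))
  totals <- Matrix::colSums(counts)
  meta$total_umi <- as.numeric(totals)
  meta$n_genes_detected <- as.numeric(Matrix::colSums(counts > 0))
  meta$mito_fraction <- ifelse(totals > 0,
                               as.numeric(Matrix::colSums(counts[mito, , drop = FALSE])) /
                                 pmax(totals, 1), 0)
  if (is.null(meta$cluster)) meta$cluster <- NA_integer_
  if (is.null(meta$compartment)) meta$compartment <- NA_character_

  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(meta)
  )
}

#' Per-spot metadata as a data.frame
#' @param ds a spot dataset (`SingleCellExperiment`)
#' @return data.frame of colData with a `spot_id` column.
#' @export
spot_meta <- function(ds) {
  df <- as.data.frame(SummarizedExperiment::colData(ds))
  df$spot_id <- colnames(ds)
  df
}

norm_layer <- function(ds, required = TRUE) {
  if (!"normalized" %in% SummarizedExperiment::assayNames(ds)) {
    if (required) stop("dataset has no normalized layer; run normalize_spots() first",
                       call. = FALSE)
    return(NULL)
  }
  SummarizedExperiment::assay(ds, "normalized")
}

#' Write a spot dataset to a Matrix Market directory
#'
#' Emits `matrix.mtx`, `genes.tsv`, `barcodes.tsv`, `spot_positions.csv`
#' (barcode, array_row, array_col) and `spot_metadata.csv`.
#'
#' @param ds spot dataset
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly.
#' @export
write_spot_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(SummarizedExperiment::assay(ds, "counts"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(ds), file.path(dir, "genes.tsv"))
  writeLines(colnames(ds), file.path(dir, "barcodes.tsv"))
  md <- spot_meta(ds)
  write.csv(md[, c("spot_id", "array_row", "array_col")],
            file.path(dir, "spot_positions.csv"), row.names = FALSE)
  write.csv(md, file.path(dir, "spot_metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a spot dataset written by [write_spot_dataset()]
#' @param dir directory containing `matrix.mtx`, `genes.tsv`, `barcodes.tsv`
#'   and `spot_metadata.csv`
#' @return a spot dataset
#' @export
read_spot_dataset <- function(dir) {
  counts <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  rownames(counts) <- readLines(file.path(dir, "genes.tsv"))
  colnames(counts) <- readLines(file.path(dir, "barcodes.tsv"))
  meta <- read.csv(file.path(dir, "spot_metadata.csv"),
                   stringsAsFactors = FALSE)
  keep <- setdiff(names(meta),
                  c("spot_id", "total_umi", "n_genes_detected", "mito_fraction"))
  spot_dataset(counts, meta[, keep, drop = FALSE])
}
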