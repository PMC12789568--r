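#' Default AITL gene panel
#'
#' The recurrently mutated AITL genes used by the final filtering rule:
#' TET2, DNMT3A, IDH2, RHOA. A larger panel can be supplied as a character
#' vector or a one-gene-per-line file.
#'
#' @return character vector of gene symbols.
#' @export
default_aitl_panel <- function() c("TET2", "DNMT3A", "IDH2", "RHOA")

#' Validate an annotated variant table
#'
#' @param df data.frame with columns chrom, pos, ref, alt, gene,
#'   consequence, clinvar_class, pop_af, vaf (required), plus optional
#'   depth and sample_id.
#' @return the validated data.frame.
#' @export
variant_table <- function(df) {
  req <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
           "clinvar_class", "pop_af", "vaf")
  missing <- setdiff(req, names(df))
  stop_if_not(length(missing) == 0, "variant table lacks column(s): ",
              paste(missing, collapse = ", "))
  bad <- which(!is.na(df$vaf) & (df$vaf < 0 | df$vaf > 1))
  stop_if_not(length(bad) == 0, "vaf outside [0,1] at row(s): ",
              paste(head(bad, 5), collapse = ", "))
  bad <- which(!is.na(df$pop_af) & (df$pop_af < 0 | df$pop_af > 1))
  stop_if_not(length(bad) == 0, "pop_af outside [0,1] at row(s): ",
              paste(head(bad, 5), collapse = ", "))
  bad <- which(is.na(df$pos) | df$pos < 1)
  stop_if_not(length(bad) == 0, "pos must be >= 1 at row(s): ",
              paste(head(bad, 5), collapse = ", "))
  df
}

clinvar_benign <- function(cv) {
  norm <- tolower(gsub("_", " ", trimws(as.character(cv))))
  !is.na(norm) &
    norm %in% c("benign", "likely benign", "benign/likely benign") &
    !grepl("pathogenic", norm)
}

#' Tumor-only variant filter cascade
#'
#' Applies, in order, the five tumor-only filtering rules: (1) remove
#' intronic or synonymous variants; (2) remove variants annotated benign or
#' likely benign in ClinVar (case-insensitive; compound classes containing
#' "pathogenic" are never removed; a missing ClinVar class passes); (3)
#' remove variants with VAF strictly greater than `cfg$vaf_hom` (0.90) as
#' homozygous; (4) remove variants with population allele frequency strictly
#' greater than `cfg$pop_af` (0.01; a missing frequency passes as rare); (5)
#' remove variants outside the recurrently mutated gene panel. Order affects
#' only the audit trail, never the kept set.
#'
#' @param variants annotated variant data.frame (see [variant_table()]).
#' @param panel character vector of panel genes.
#' @param cfg a [pipeline_config()].
#' @return list with `kept` (surviving rows), `fates` (per input row:
#'   `"kept"` or `"removed@step1"` ... `"removed@step5"`) and `trace`
#'   (per-step data.frame: step, rule, n_in, n_removed, n_out).
#' @export
filter_cascade <- function(variants, panel = default_aitl_panel(),
                           cfg = pipeline_config()) {
  variants <- variant_table(variants)
  stop_if_not(length(panel) >= 1, "panel must be non-empty")
  csq <- tolower(as.character(variants$consequence))
  rules <- list(
    consequence = csq %in% c("intronic", "synonymous"),
    clinvar = clinvar_benign(variants$clinvar_class),
    vaf = !is.na(variants$vaf) & variants$vaf > cfg$vaf_hom,
    popfreq = !is.na(variants$pop_af) & variants$pop_af > cfg$pop_af,
    panel = !(variants$gene %in% panel)
  )
  n <- nrow(variants)
  fates <- rep("kept", n)
  alive <- rep(TRUE, n)
  trace <- data.frame(step = seq_along(rules), rule = names(rules),
                      n_in = NA_integer_, n_removed = NA_integer_,
                      n_out = NA_integer_)
  for (k in seq_along(rules)) {
    hit <- alive & rules[[k]]
    trace$n_in[k] <- sum(alive)
    trace$n_removed[k] <- sum(hit)
    fates[hit] <- paste0("removed@step", k)
    alive <- alive & !hit
    trace$n_out[k] <- sum(alive)
  }
  list(kept = variants[alive, , drop = FALSE], fates = fates, trace = trace)
}

#' Per-gene recurrence summary of kept variants
#'
#' Gene x sample incidence of the kept variants, reported as "k/N" over the
#' full sample set, with minimum and median VAF per gene and a flag for
#' genes whose minimum VAF falls at or below 0.20.
#'
#' @param kept kept variants (must carry `sample_id`).
#' @param samples character vector of all sample ids (defines N).
#' @return data.frame: gene, n_samples_mutated, incidence, min_vaf,
#'   median_vaf, low_vaf_flag; the incidence matrix is attached as
#'   `attr(, "incidence")`.
#' @export
recurrent_gene_summary <- function(kept, samples) {
  if (nrow(kept) == 0) {
    out <- data.frame(gene = character(0), n_samples_mutated = integer(0),
                      incidence = character(0), min_vaf = numeric(0),
                      median_vaf = numeric(0), low_vaf_flag = logical(0))
    attr(out, "incidence") <- matrix(0L, 0, length(samples),
                                     dimnames = list(NULL, samples))
    return(out)
  }
  stop_if_not("sample_id" %in% names(kept),
              "kept variants must carry sample_id")
  genes <- sort(unique(kept$gene))
  inc <- matrix(0L, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  for (i in seq_len(nrow(kept))) {
    inc[kept$gene[i], kept$sample_id[i]] <- 1L
  }
  out <- data.frame(
    gene = genes,
    n_samples_mutated = as.integer(rowSums(inc)),
    incidence = paste0(rowSums(inc), "/", length(samples)),
    min_vaf = vapply(genes, function(g) min(kept$vaf[kept$gene == g]), 0),
    median_vaf = vapply(genes, function(g)
      stats::median(kept$vaf[kept$gene == g]), 0),
    stringsAsFactors = FALSE
  )
  out$low_vaf_flag <- out$min_vaf <= 0.20
  rownames(out) <- NULL
  attr(out, "incidence") <- inc
  out
}

#' Write variants as a minimal VCF 4.2
#'
#' INFO keys: GENE, CSQ (consequence), CLNSIG (ClinVar class, spaces as
#' underscores), POP_AF, VAF, DP.
#'
#' @param variants variant data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, path) {
  variants <- variant_table(variants)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence\">",
    "##INFO=<ID=CLNSIG,Number=1,Type=String,Description=\"ClinVar class\">",
    "##INFO=<ID=POP_AF,Number=1,Type=Float,Description=\"Population AF\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  info <- vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    f <- c(paste0("GENE=", v$gene), paste0("CSQ=", v$consequence))
    if (!is.na(v$clinvar_class)) {
      f <- c(f, paste0("CLNSIG=", gsub(" ", "_", v$clinvar_class)))
    }
    if (!is.na(v$pop_af)) f <- c(f, paste0("POP_AF=", v$pop_af))
    f <- c(f, paste0("VAF=", v$vaf))
    if (!is.null(v$depth) && !is.na(v$depth)) f <- c(f, paste0("DP=", v$depth))
    paste(f, collapse = ";")
  }, "")
  body <- paste(variants$chrom, variants$pos, ".", variants$ref,
                variants$alt, ".", "PASS", info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read variants from VCF
#'
#' Parses a VCF (4.2) whose INFO field carries the annotation keys used by
#' [write_variant_vcf()] (configurable). Multi-allelic records are split
#' into one row per alternate allele before filtering.
#'
#' @param path VCF file.
#' @param info_keys named mapping from record fields to INFO keys.
#' @return variant data.frame.
#' @export
read_variant_vcf <- function(path,
                             info_keys = c(gene = "GENE", consequence = "CSQ",
                                           clinvar_class = "CLNSIG",
                                           pop_af = "POP_AF", vaf = "VAF",
                                           depth = "DP")) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  grab <- function(key, numeric = FALSE) {
    vcfR::extract.info(v, element = key, as.numeric = numeric)
  }
  df <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
    alt = fix$ALT,
    gene = grab(info_keys[["gene"]]),
    consequence = grab(info_keys[["consequence"]]),
    clinvar_class = gsub("_", " ", grab(info_keys[["clinvar_class"]])),
    pop_af = suppressWarnings(grab(info_keys[["pop_af"]], numeric = TRUE)),
    vaf = suppressWarnings(grab(info_keys[["vaf"]], numeric = TRUE)),
    depth = suppressWarnings(grab(info_keys[["depth"]], numeric = TRUE)),
    stringsAsFactors = FALSE
  )
  multi <- grepl(",", df$alt)
  if (any(multi)) {
    expanded <- lapply(which(multi), function(i) {
      alts <- strsplit(df$alt[i], ",")[[1]]
      out <- df[rep(i, length(alts)), , drop = FALSE]
      out$alt <- alts
      out
    })
    df <- rbind(df[!multi, , drop = FALSE], do.call(rbind, expanded))
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
  }
  rownames(df) <- NULL
  variant_table(df)
}
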