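#' Post-process deconvolution abundances to integer cell counts
#'
#' Rounds the estimated mean abundances to integers (half-to-even by
#' default, half-up optionally) and assigns one cell to the cell type with
#' the greatest raw abundance in any spot whose rounded row is all zero.
#' Argmax ties are broken by cell-type name order for determinism.
#'
#' @param raw spots x cell-type matrix of non-negative real abundances with
#'   spot ids as rownames and cell-type names as colnames.
#' @param rounding `"half_even"` (default) or `"half_up"`.
#' @return integer matrix on the same axes.
#' @examples
#' raw <- rbind(s1 = c(A = 0.4, B = 0.3), s2 = c(A = 2.6, B = 0.2))
#' postprocess_abundance(raw)  # s1 -> (1, 0); s2 -> (3, 0)
#' @export
postprocess_abundance <- function(raw, rounding = c("half_even", "half_up")) {
  rounding <- match.arg(rounding)
  stop_if_not(is.matrix(raw) && is.numeric(raw), "raw must be a numeric matrix")
  if (any(raw < 0)) stop("raw abundances must be non-negative", call. = FALSE)
  stop_if_not(!is.null(colnames(raw)), "raw must carry cell-type colnames")
  post <- round_mode(raw, rounding)
  zero_rows <- which(rowSums(post) == 0)
  for (i in zero_rows) {
    cand <- which(raw[i, ] == max(raw[i, ]))
    pick <- cand[which.min(rank(colnames(raw))[cand])]
    post[i, ] <- 0
    post[i, pick] <- 1
  }
  storage.mode(post) <- "integer"
  post
}

#' Cell-type enrichment between neoplastic and non-neoplastic spots
#'
#' Per cell type, a two-sided Mann-Whitney U test of per-spot abundance
#' between the two compartments, Benjamini-Hochberg adjustment across cell
#' types, and the dual significance gate p < `enrich_p` and q < `enrich_q`
#' (defaults 0.05 and 0.25).
#'
#' @param post spots x cell-type abundance matrix (rownames = spot ids,
#'   aligned with the dataset; usually the [postprocess_abundance()] output).
#' @param ds spot dataset with compartments called.
#' @param cfg a [pipeline_config()].
#' @return data.frame: cell_type, median_neoplastic, median_nonneoplastic,
#'   U, p, q, direction, significant.
#' @export
enrichment_test <- function(post, ds, cfg = pipeline_config()) {
  md <- spot_meta(ds)
  stop_if_not(!anyNA(md$compartment), "compartments missing; run call_neoplastic()")
  stop_if_not(all(md$spot_id %in% rownames(post)),
              "abundance matrix does not cover all spots")
  post <- post[md$spot_id, , drop = FALSE]
  neo <- md$compartment == "neoplastic"
  if (sum(neo) < 2 || sum(!neo) < 2) {
    stop("each compartment needs at least 2 spots (neoplastic: ", sum(neo),
         ", nonneoplastic: ", sum(!neo), ")", call. = FALSE)
  }
  res <- lapply(colnames(post), function(ct) {
    a <- post[neo, ct]; b <- post[!neo, ct]
    mw <- mann_whitney_u(a, b)
    m_a <- stats::median(a); m_b <- stats::median(b)
    dir <- if (m_a > m_b) "up_in_neoplastic"
           else if (m_a < m_b) "down_in_neoplastic"
           else if (mean(a) > mean(b)) "up_in_neoplastic"
           else if (mean(a) < mean(b)) "down_in_neoplastic"
           else "none"
    data.frame(cell_type = ct, median_neoplastic = m_a,
               median_nonneoplastic = m_b, U = mw$U, p = mw$p,
               direction = dir, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < cfg$enrich_p & out$q < cfg$enrich_q
  out[, c("cell_type", "median_neoplastic", "median_nonneoplastic",
          "U", "p", "q", "direction", "significant")]
}
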