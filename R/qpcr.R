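#' Delta-Ct between conditions
#'
#' The Ct value is the PCR cycle at which the product becomes detectable;
#' lower Ct means more template. Delta-Ct is defined here as
#' \code{ct_mature - ct_premature}, so a positive value means higher
#' expression in the premature ovary. Measurements at or above the cycle
#' cap (44 cycles by default, the run length of the emulated program) are
#' non-detects and yield \code{NA}; nonpositive Ct values are invalid.
#'
#' @param ctPremature,ctMature Ct values in cycles (vectorized).
#' @param cycleCap detection limit in cycles (default 44).
#' @return delta-Ct in cycles; \code{NA} for non-detects.
#' @export
deltaCt <- function(ctPremature, ctMature, cycleCap = 44) {
  if (any(ctPremature <= 0, na.rm = TRUE) ||
      any(ctMature <= 0, na.rm = TRUE))
    stop("Ct values must be positive", call. = FALSE)
  nd <- ctPremature >= cycleCap | ctMature >= cycleCap
  out <- ctMature - ctPremature
  out[nd] <- NA_real_
  out
}

#' Fold change from delta-Ct
#'
#' Assumes ideal exponential amplification: each cycle multiplies the
#' product by \code{efficiency} (default 2, perfect doubling), so the
#' premature-to-mature fold change is \code{efficiency^deltaCt}. Strictly
#' positive, strictly increasing in delta-Ct, and reciprocal under sign
#' flip.
#'
#' @param deltaCt delta-Ct in cycles (vectorized).
#' @param efficiency per-cycle amplification factor (> 1).
#' @return fold change(s).
#' @examples
#' foldChange(1)              # one cycle ahead = 2-fold
#' foldChange(log2(130))      # ~7.02 cycles = 130-fold
#' @export
foldChange <- function(deltaCt, efficiency = 2) {
  stopifnot(efficiency > 1)
  efficiency^deltaCt
}

#' Delta-Ct fold changes for a Ct table
#'
#' @param ct \code{data.frame} with columns \code{gene_id},
#'   \code{ct_premature}, \code{ct_mature}.
#' @param efficiency see [foldChange()].
#' @param cycleCap see [deltaCt()]; non-detect rows are dropped with a
#'   warning.
#' @return the table with added \code{delta_ct} and \code{fold_change}
#'   columns (fold change of premature relative to mature).
#' @export
qpcrFoldChanges <- function(ct, efficiency = 2, cycleCap = 44) {
  stopifnot(all(c("gene_id", "ct_premature", "ct_mature") %in%
                  colnames(ct)))
  d <- deltaCt(ct$ct_premature, ct$ct_mature, cycleCap = cycleCap)
  if (anyNA(d)) {
    warning(sum(is.na(d)), " non-detect measurement(s) excluded")
    ct <- ct[!is.na(d), , drop = FALSE]
    d <- d[!is.na(d)]
  }
  ct$delta_ct <- d
  ct$fold_change <- foldChange(d, efficiency = efficiency)
  ct
}
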