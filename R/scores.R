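#' Filter under-represented clusters
#'
#' Clusters with frequency strictly below `min_freq` (default 0.005, i.e.
#' 0.5%) are discarded; a cluster at exactly 0.5% is retained.
#'
#' @param freqs named numeric vector of cluster frequencies in `[0, 1]`.
#' @param min_freq discard cutoff as a proportion.
#' @return names (or indices) of retained clusters.
#' @export
filter_rare_clusters <- function(freqs, min_freq = 0.005) {
  if (any(freqs < 0 | freqs > 1)) stop("frequencies must lie in [0, 1]")
  keep <- freqs >= min_freq
  if (is.null(names(freqs))) which(keep) else names(freqs)[keep]
}

#' Integrated MFI (iMFI), rescaled 0-100
#'
#' Multiplies each cluster's mean fluorescence intensity by the cluster
#' frequency and min-max rescales the products to `[0, 100]` per marker
#' (across clusters). If all of a marker's raw products are equal the
#' rescaling is degenerate and every cluster maps to 0 for that marker.
#'
#' @param mfi matrix (clusters x markers) of mean fluorescence intensities.
#' @param freqs cluster frequencies, aligned to the rows of `mfi`.
#' @return matrix of iMFI values in `[0, 100]`, same shape as `mfi`.
#' @export
imfi <- function(mfi, freqs) {
  mfi <- as.matrix(mfi)
  if (nrow(mfi) < 1) stop("need at least one cluster")
  if (length(freqs) != nrow(mfi))
    stop("freqs must have one entry per cluster (row of mfi)")
  if (any(mfi < 0) || any(freqs < 0)) stop("MFI and frequencies must be >= 0")
  raw <- mfi * freqs
  apply(raw, 2, function(v) {
    rng <- range(v)
    if (diff(rng) == 0) rep(0, length(v))
    else (v - rng[1]) / diff(rng) * 100
  })
}

#' Per-cell gene-signature score
#'
#' For each cell, the score is the sum of counts of the signature genes
#' divided by the cell's total counts (a proportion in `[0, 1]`). A cell is
#' flagged `emphasized` when its score strictly exceeds the 80th percentile
#' (empirical quantile, linear interpolation) of the scores of all cells.
#'
#' @param counts matrix of nonnegative integer counts, genes x cells, with
#'   gene rownames.
#' @param signature character vector of signature gene names (genes absent
#'   from the matrix contribute zero).
#' @param emphasis_quantile percentile used for the emphasis flag.
#' @return data.frame with `cell`, `score`, `emphasized`.
#' @export
signature_score <- function(counts, signature, emphasis_quantile = 0.8) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene rownames")
  if (any(counts < 0)) stop("counts must be nonnegative")
  totals <- colSums(counts)
  if (any(totals == 0)) stop("every cell must have total counts > 0")
  sig <- intersect(signature, rownames(counts))
  sig_sum <- if (length(sig) == 0) rep(0, ncol(counts)) else
    colSums(counts[sig, , drop = FALSE])
  score <- sig_sum / totals
  q <- unname(quantile(score, emphasis_quantile, type = 7))
  data.frame(cell = colnames(counts) %||% seq_len(ncol(counts)),
             score = unname(score),
             emphasized = unname(score > q),
             stringsAsFactors = FALSE)
}

#' Cytolytic index
#'
#' Geometric mean of granzyme A and perforin expression.
#'
#' @param gzma,prf1 nonnegative expression values (vectorized).
#' @return `sqrt(gzma * prf1)`.
#' @export
cytolytic_index <- function(gzma, prf1) {
  if (any(gzma < 0) || any(prf1 < 0))
    stop("expression values must be >= 0")
  sqrt(gzma * prf1)
}
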