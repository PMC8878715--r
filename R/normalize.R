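#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors (Robinson & Oshlack): a
#' reference sample is chosen by upper quartile, per-gene log-ratios (M)
#' and log-abundances (A) are computed over genes expressed in both
#' samples, the 30% M and 5% A tails are trimmed, and the factor is the
#' precision-weighted mean of the remaining M values; factors are rescaled
#' to geometric mean 1. Computed via edgeR, the standard implementation.
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return Numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) {
    abort("TMM needs at least 2 samples", class = "bcellrepseq_argument_error")
  }
  if (any(colSums(counts) == 0)) {
    abort("sample with all-zero counts", class = "bcellrepseq_argument_error")
  }
  if (any(counts < 0)) {
    abort("negative counts", class = "bcellrepseq_argument_error")
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  setNames(as.numeric(f), colnames(counts))
}

#' Normalized pseudo-counts
#'
#' Rescales counts to the common effective library size (library size x TMM
#' factor, geometric-mean target): the equivalent counts had all samples
#' been sequenced to the same effective depth.
#'
#' @param counts Genes x samples count matrix.
#' @param factors Per-sample factors from [tmm_factors()].
#' @return Numeric matrix of the same shape and dimnames.
#' @export
pseudo_counts <- function(counts, factors = tmm_factors(counts)) {
  counts <- as.matrix(counts)
  eff <- colSums(counts) * factors
  target <- exp(mean(log(eff)))
  sweep(counts, 2, target / eff, `*`)
}
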