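#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / c` with `Z` the dosage matrix column-centred at twice the
#' allele frequencies and `c = 2 * sum_j p_j (1 - p_j)`. By default the
#' centering frequencies are computed on the full cohort in `g` (train and
#' test jointly, matching a pipeline that merges and filters one marker set
#' before prediction); pass `freqs` to centre on a reference subset instead.
#' Markers fixed in the centering frequencies (p of 0 or 1) carry no
#' relationship information and are dropped with a warning.
#'
#' @param g a [genotype_matrix()] without missing values.
#' @param freqs optional named per-marker centering frequencies.
#' @return Symmetric matrix of class `grm` with attributes `freqs` (the
#'   centering frequencies used) and `scale_c`.
#' @export
compute_grm <- function(g, freqs = NULL) {
  if (anyNA(g$dosage)) stop("missing genotypes; impute before the GRM")
  p <- freqs %||% allele_frequencies(g)
  p <- p[marker_ids(g)]
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("all markers monomorphic at the centering frequencies")
  if (any(!keep))
    warning(sum(!keep), " monomorphic marker(s) dropped from the GRM")
  Z <- sweep(g$dosage[, keep, drop = FALSE], 2, 2 * p[keep])
  cc <- 2 * sum(p[keep] * (1 - p[keep]))
  G <- tcrossprod(Z) / cc
  structure(G, class = c("grm", "matrix"), freqs = p[keep], scale_c = cc)
}

#' Centred dosage matrix for marker-effect models
#'
#' `Z = dosage - 2 p`, using cohort frequencies by default. The frequencies
#' are attached so that new samples can be centred identically (never with
#' their own frequencies).
#'
#' @inheritParams compute_grm
#' @param drop_fixed drop markers fixed at the centering frequencies.
#' @return Centred matrix with attribute `freqs`.
#' @export
center_dosage <- function(g, freqs = NULL, drop_fixed = TRUE) {
  if (anyNA(g$dosage)) stop("missing genotypes; impute first")
  p <- (freqs %||% allele_frequencies(g))[marker_ids(g)]
  keep <- if (drop_fixed) p > 0 & p < 1 else rep(TRUE, length(p))
  Z <- sweep(g$dosage[, keep, drop = FALSE], 2, 2 * p[keep])
  attr(Z, "freqs") <- p[keep]
  Z
}
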