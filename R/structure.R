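#' Principal component analysis of a dosage matrix
#'
#' Column-centres the dosage matrix (per-marker mean) without unit-variance
#' scaling — the usual convention for SNP dosage PCA — and decomposes it.
#'
#' @param g a [genotype_matrix()] without missing values (impute first).
#' @param n_components number of components to return.
#' @return List with `scores` (samples x components), `var_explained`
#'   (fractions, non-increasing) and `rotation`.
#' @export
pca_genotypes <- function(g, n_components = 10) {
  d <- g$dosage
  if (anyNA(d)) stop("missing genotypes; impute before PCA")
  k <- min(n_components, nrow(d) - 1, ncol(d))
  pc <- prcomp(d, center = TRUE, scale. = FALSE, rank. = k)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       var_explained = ve, rotation = pc$rotation)
}

#' Pairwise Euclidean genetic distance
#'
#' `d(a, b) = sqrt(sum_j (x_aj - x_bj)^2)` on the 0/1/2 dosage coding, via
#' [stats::dist()].
#'
#' @param g a [genotype_matrix()] without missing values.
#' @return Symmetric labelled distance matrix.
#' @export
pairwise_distance <- function(g) {
  if (anyNA(g$dosage)) stop("missing genotypes; impute before distances")
  as.matrix(dist(g$dosage, method = "euclidean"))
}

#' Mean between-group genetic distance
#'
#' Aggregates a pairwise distance matrix to a single group-to-group scalar:
#' the mean of all between-group pairwise distances (symmetric in the two
#' groups and robust to group size).
#'
#' @param d symmetric distance matrix with sample ids as dimnames.
#' @param groups named vector mapping sample id to group label.
#' @param a,b the two group labels (must be disjoint, non-empty).
#' @return Scalar mean distance.
#' @seealso [group_centroid_distance()] for the centroid variant.
#' @export
group_distance <- function(d, groups, a, b) {
  ia <- names(groups)[groups == a]
  ib <- names(groups)[groups == b]
  if (length(ia) == 0 || length(ib) == 0) stop("empty group")
  if (length(intersect(ia, ib)) > 0) stop("groups overlap")
  mean(d[ia, ib, drop = FALSE])
}

#' Euclidean distance between group dosage centroids
#'
#' @param g a [genotype_matrix()] without missing values.
#' @param groups named vector mapping sample id to group label.
#' @param a,b group labels.
#' @return Scalar centroid distance.
#' @export
group_centroid_distance <- function(g, groups, a, b) {
  ia <- names(groups)[groups == a]
  ib <- names(groups)[groups == b]
  if (length(ia) == 0 || length(ib) == 0) stop("empty group")
  ca <- colMeans(g$dosage[ia, , drop = FALSE])
  cb <- colMeans(g$dosage[ib, , drop = FALSE])
  sqrt(sum((ca - cb)^2))
}

#' UPGMA (average-linkage) clustering of a distance matrix
#'
#' Agglomerates with [stats::hclust()] `method = "average"`. The returned
#' tree is also provided as an \pkg{ape} `phylo` (edge lengths are
#' merge-height differences, so cophenetic distances reproduce ultrametric
#' input exactly) and as a newick string.
#'
#' @param d symmetric distance matrix, `n >= 2`, no NaN.
#' @return List with `hclust`, `phylo` and `newick`.
#' @export
upgma_cluster <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 2) stop("need at least two samples")
  if (any(is.nan(d))) stop("NaN distances")
  hc <- hclust(as.dist(d), method = "average")
  stopifnot(!is.unsorted(hc$height))
  phy <- ape::as.phylo(hc)
  list(hclust = hc, phylo = phy, newick = ape::write.tree(phy))
}

#' Rank candidates by mean distance to a target set
#'
#' Scores every candidate by its mean distance to all target samples and
#' sorts ascending (closest first); ties are broken by candidate id. This is
#' the ordering used to assemble distance-optimised training sets for a
#' breeding population.
#'
#' @param d symmetric distance matrix with sample ids as dimnames.
#' @param candidates candidate sample ids.
#' @param target target sample ids (non-empty, disjoint from candidates).
#' @return Character vector: `candidates` ordered by ascending mean
#'   distance, with the scores as names.
#' @export
rank_by_distance <- function(d, candidates, target) {
  if (length(target) == 0) stop("empty target set")
  if (length(intersect(candidates, target)) > 0)
    stop("candidates and target overlap")
  score <- rowMeans(d[candidates, target, drop = FALSE])
  ord <- order(score, candidates)
  setNames(candidates[ord], format(score[ord], trim = TRUE))
}
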