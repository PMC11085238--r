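#' Quality-control configuration
#'
#' Thresholds mirroring common SNP-array practice: markers with minor allele
#' frequency below `maf_min` or per-marker missing fraction above
#' `missing_max` are discarded. Both thresholds are exclusive on the removal
#' side: a marker with MAF exactly `maf_min`, or missingness exactly
#' `missing_max`, is retained.
#'
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param missing_max maximum per-marker missing fraction (default 0.10).
#' @return A `qc_config` list.
#' @export
qc_config <- function(maf_min = 0.05, missing_max = 0.10) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, missing_max >= 0, missing_max <= 1)
  structure(list(maf_min = maf_min, missing_max = missing_max),
            class = "qc_config")
}

#' Filter markers on MAF and missingness
#'
#' MAF is computed on non-missing calls only. Removal reasons are tallied
#' per criterion (a marker failing both counts under both).
#'
#' @param g a [genotype_matrix()]; recoded to minor-allele convention first
#'   if necessary so that the MAF filter is well defined.
#' @param qc a [qc_config()].
#' @return List with elements `genotypes` (the filtered matrix) and `report`
#'   (data frame of per-marker MAF, missing fraction and kept flag, with a
#'   summary attached as attribute `"summary"`).
#' @export
filter_markers <- function(g, qc = qc_config()) {
  if (g$coding != "minor") g <- recode_minor(g)
  p <- allele_frequencies(g)
  maf <- pmin(p, 1 - p)
  miss <- colMeans(is.na(g$dosage))
  fail_maf <- maf < qc$maf_min
  fail_miss <- miss > qc$missing_max
  keep <- !(fail_maf | fail_miss)
  if (!any(keep)) stop("all markers removed by QC filters")
  report <- data.frame(marker = marker_ids(g), maf = unname(maf),
                       missing = unname(miss), kept = unname(keep),
                       stringsAsFactors = FALSE)
  attr(report, "summary") <- data.frame(
    n_input = ncol(g$dosage),
    n_removed_maf = sum(fail_maf),
    n_removed_missing = sum(fail_miss),
    n_retained = sum(keep))
  list(genotypes = g[, which(keep)], report = report)
}

#' Impute missing genotype calls
#'
#' Simple per-marker imputation intended for downstream models that consume
#' continuous dosages: `marker_mean` replaces missing cells by the mean
#' dosage of the observed calls (fractional values allowed), `marker_mode`
#' by the modal observed dosage (ties resolved toward the smaller dosage).
#' Observed cells are never touched.
#'
#' @param g a [genotype_matrix()].
#' @param method `"marker_mean"` or `"marker_mode"`.
#' @return The imputed `genotype_matrix` (`imputed = TRUE`).
#' @export
impute_missing <- function(g, method = c("marker_mean", "marker_mode")) {
  method <- match.arg(method)
  d <- g$dosage
  n_obs <- colSums(!is.na(d))
  if (any(n_obs == 0))
    stop("marker(s) with no observed calls cannot be imputed: ",
         paste(head(marker_ids(g)[n_obs == 0]), collapse = ", "))
  for (j in which(colSums(is.na(d)) > 0)) {
    obs <- d[, j][!is.na(d[, j])]
    fill <- if (method == "marker_mean") mean(obs)
            else as.numeric(names(which.max(table(obs))))
    d[is.na(d[, j]), j] <- fill
  }
  g$dosage <- d
  g$imputed <- TRUE
  g
}

#' Merge two genotype cohorts
#'
#' Combines the samples of two cohorts on the intersection of their marker
#' ids, the way public panels and in-house breeding lines genotyped on the
#' same array are pooled before joint filtering. Map consistency
#' (chromosome/position and allele set) is checked at shared markers; cohort
#' `b` is re-oriented to `a`'s allele labels where the two files encode
#' opposite alleles. The minor-allele convention is then recomputed on the
#' merged cohort, so a marker that was minor-coded in one cohort may flip
#' after merging.
#'
#' @param a,b [genotype_matrix()] objects with disjoint sample ids.
#' @return The merged `genotype_matrix` (minor-allele coding on the union).
#' @export
merge_cohorts <- function(a, b) {
  if (length(intersect(sample_ids(a), sample_ids(b))) > 0)
    stop("sample ids overlap between cohorts")
  common <- intersect(marker_ids(a), marker_ids(b))
  if (length(common) == 0) stop("no shared markers between cohorts")
  a <- a[, common]
  b <- b[, common]
  ia <- match(common, a$map$marker); ib <- match(common, b$map$marker)
  known_map <- !is.na(a$map$chrom[ia]) & !is.na(b$map$chrom[ib]) &
    a$map$chrom[ia] != "0" & b$map$chrom[ib] != "0"
  bad <- known_map & (a$map$chrom[ia] != b$map$chrom[ib] |
                        a$map$pos[ia] != b$map$pos[ib])
  if (any(bad))
    stop("map mismatch at shared marker(s): ",
         paste(head(common[bad]), collapse = ", "))
  # orient b onto a's alleles where both cohorts carry labels
  have_al <- !is.na(a$map$ref[ia]) & !is.na(b$map$ref[ib])
  same <- b$map$ref[ib] == a$map$ref[ia] & b$map$alt[ib] == a$map$alt[ia]
  swapped <- b$map$ref[ib] == a$map$alt[ia] & b$map$alt[ib] == a$map$ref[ia]
  if (any(have_al & !(same | swapped)))
    stop("allele mismatch at shared marker(s): ",
         paste(head(common[have_al & !(same | swapped)]), collapse = ", "))
  flip <- which(have_al & swapped)
  if (length(flip)) {
    cols <- match(common[flip], b$map$marker)
    b$dosage[, cols] <- 2 - b$dosage[, cols]
    b$map$ref[cols] <- a$map$ref[ia][flip]
    b$map$alt[cols] <- a$map$alt[ia][flip]
  }
  ord <- a$map$marker
  merged <- genotype_matrix(
    rbind(a$dosage[, ord, drop = FALSE], b$dosage[, ord, drop = FALSE]),
    chrom = a$map$chrom, pos = a$map$pos, ref = a$map$ref, alt = a$map$alt,
    coding = "alt", imputed = a$imputed || b$imputed)
  recode_minor(merged)
}
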