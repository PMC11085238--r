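#' Construct a genotype matrix
#'
#' The central genotype container: a sample-by-marker matrix of allele
#' dosages in \{0, 1, 2\} (or `NA` for missing calls), together with a marker
#' map and the allele-coding convention. Under the `"minor"` convention a
#' dosage counts copies of the minor allele on the coded cohort (0 = major
#' homozygote, 1 = heterozygote, 2 = minor homozygote); under `"alt"` it
#' counts copies of an arbitrary designated allele (e.g. the VCF ALT allele,
#' or the simulator's derived allele).
#'
#' Markers are sorted by (chromosome, position) at construction. Mean-imputed
#' matrices (`imputed = TRUE`) may hold fractional dosages in \[0, 2\].
#'
#' @param dosage numeric matrix, samples in rows, markers in columns; must
#'   carry unique row and column names.
#' @param chrom chromosome label per marker (defaults to a single dummy
#'   chromosome when no map is known, e.g. for plain dosage tables).
#' @param pos marker position per marker, non-decreasing within chromosome.
#'   Units are whatever the source provides (bp for VCF, cM for simulated
#'   maps); the package only relies on the ordering.
#' @param ref,alt optional allele labels per marker (single characters);
#'   `NA` when unknown.
#' @param coding `"minor"` or `"alt"` (see above).
#' @param imputed logical; `TRUE` once missing cells have been filled, after
#'   which fractional dosages are permitted.
#' @return An object of class `genotype_matrix`.
#' @seealso [read_genotypes()], [recode_minor()], [filter_markers()]
#' @export
genotype_matrix <- function(dosage, chrom = NULL, pos = NULL,
                            ref = NULL, alt = NULL,
                            coding = c("alt", "minor"), imputed = FALSE) {
  coding <- match.arg(coding)
  if (!is.matrix(dosage)) stop("`dosage` must be a matrix")
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stop("`dosage` must have sample (row) and marker (column) names")
  if (anyDuplicated(rownames(dosage))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(dosage))) stop("duplicate marker ids")
  m <- ncol(dosage)
  chrom <- as.character(chrom %||% rep("0", m))
  pos <- as.numeric(pos %||% seq_len(m))
  ref <- as.character(ref %||% rep(NA_character_, m))
  alt <- as.character(alt %||% rep(NA_character_, m))
  if (length(chrom) != m || length(pos) != m)
    stop("map length does not match marker count")
  if (!imputed) {
    vals <- dosage[!is.na(dosage)]
    if (length(vals) && !all(vals %in% c(0, 1, 2)))
      stop("dosages must be 0, 1, 2 or NA")
  }
  ord <- order(chrom, pos)
  g <- structure(
    list(dosage = dosage[, ord, drop = FALSE],
         map = data.frame(marker = colnames(dosage)[ord],
                          chrom = chrom[ord], pos = pos[ord],
                          ref = ref[ord], alt = alt[ord],
                          stringsAsFactors = FALSE),
         coding = coding, imputed = imputed),
    class = "genotype_matrix")
  g
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- dim(x$dosage)
  miss <- mean(is.na(x$dosage))
  cat(sprintf("genotype_matrix: %d samples x %d markers (%s-allele coding%s, %.2f%% missing)\n",
              d[1], d[2], x$coding, if (x$imputed) ", imputed" else "",
              100 * miss))
  invisible(x)
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(j)) j <- match(j, x$map$marker)
  genotype_matrix(x$dosage[i, j, drop = FALSE],
                  chrom = x$map$chrom[j], pos = x$map$pos[j],
                  ref = x$map$ref[j], alt = x$map$alt[j],
                  coding = x$coding, imputed = x$imputed)
}

#' Sample and marker identifiers
#' @param g a [genotype_matrix()].
#' @return Character vector of ids.
#' @export
sample_ids <- function(g) rownames(g$dosage)

#' @rdname sample_ids
#' @export
marker_ids <- function(g) g$map$marker

#' Per-marker allele frequencies
#'
#' Frequency of the coded allele per marker, `p_j` = mean dosage / 2 over the
#' non-missing calls of the selected samples.
#'
#' @param g a [genotype_matrix()].
#' @param subset optional sample ids (or logical/integer index); defaults to
#'   all samples.
#' @return Named numeric vector of frequencies in \[0, 1\].
#' @export
allele_frequencies <- function(g, subset = NULL) {
  d <- g$dosage
  if (!is.null(subset)) {
    d <- d[subset, , drop = FALSE]
    if (nrow(d) == 0) stop("empty sample subset")
  }
  colMeans(d, na.rm = TRUE) / 2
}

#' Recode a genotype matrix to the minor-allele convention
#'
#' Flips any marker whose coded-allele frequency exceeds 0.5 (dosage becomes
#' `2 - dosage`, allele labels swap) so that every dosage counts minor-allele
#' copies on this cohort. At a frequency of exactly 0.5 the orientation is
#' resolved by allele label: the alphabetically first allele is kept as the
#' major (reference) allele; without allele labels the current orientation is
#' kept. This tie-break makes the coding deterministic.
#'
#' @param g a [genotype_matrix()].
#' @return The recoded `genotype_matrix` with `coding = "minor"`.
#' @export
recode_minor <- function(g) {
  p <- allele_frequencies(g)
  flip <- p > 0.5
  tie <- !is.na(p) & p == 0.5 & !is.na(g$map$ref) & !is.na(g$map$alt) &
    g$map$alt < g$map$ref
  flip <- flip | tie
  if (any(flip)) {
    g$dosage[, flip] <- 2 - g$dosage[, flip]
    tmp <- g$map$ref[flip]
    g$map$ref[flip] <- g$map$alt[flip]
    g$map$alt[flip] <- tmp
  }
  g$coding <- "minor"
  g
}
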