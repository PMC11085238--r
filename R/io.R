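#' Read genotypes from VCF or a TSV dosage table
#'
#' VCF input (v4.x, biallelic SNPs, `GT` field) is parsed with
#' \pkg{vcfR}; multiallelic records are rejected with a message giving the
#' count, and half-missing calls (`./0` etc.) become missing. After loading,
#' dosages are recoded to the minor-allele convention computed on the loaded
#' cohort (see [recode_minor()]).
#'
#' TSV input is a plain dosage table, samples in rows, first column
#' `sample`, remaining header fields the marker ids, `NA` for missing; such
#' tables carry no map or allele labels, so markers keep their file order on
#' a dummy chromosome.
#'
#' @param path file path.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by file extension).
#' @return A [genotype_matrix()] with `coding = "minor"`.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  g <- if (format == "vcf") .read_vcf(path) else .read_dosage_tsv(path)
  recode_minor(g)
}

.read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  keep <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1 &
    nchar(fix[, "ALT"]) == 1
  n_multi <- sum(!keep)
  if (n_multi > 0)
    message(n_multi, " multiallelic/non-SNP record(s) dropped")
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  if (ncol(gt) == 0) stop("VCF contains zero samples")
  # alt-allele dosage; any missing allele makes the call missing
  dos <- apply(gt, c(1, 2), function(x) {
    if (is.na(x)) return(NA_real_)
    al <- strsplit(x, "[/|]")[[1]]
    if (any(al == ".") || length(al) != 2) return(NA_real_)
    sum(al == "1")
  })
  ids <- fix[, "ID"]
  if (any(is.na(ids) | ids == "."))
    ids <- paste0(fix[, "CHROM"], "_", fix[, "POS"])
  dos <- t(dos)  # samples x markers
  colnames(dos) <- ids
  genotype_matrix(dos, chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
                  ref = fix[, "REF"], alt = fix[, "ALT"], coding = "alt")
}

.read_dosage_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("malformed dosage table: ", path)
  if (colnames(tab)[1] != "sample") stop("malformed header: first column must be 'sample'")
  dos <- as.matrix(tab[, -1, drop = FALSE])
  mode(dos) <- "numeric"
  rownames(dos) <- tab$sample
  if (nrow(dos) == 0) stop("dosage table contains zero samples")
  genotype_matrix(dos, coding = "alt")
}

#' Write genotypes to VCF or a TSV dosage table
#'
#' The VCF writer emits plain-text VCF v4.2 with GT-only FORMAT; the major
#' allele is written as REF and the minor allele as ALT, so dosages
#' round-trip through [read_genotypes()]. Markers with unknown alleles are
#' written as `A`/`B`. The TSV writer emits the dosage table described in
#' [read_genotypes()] (map information is not stored in that format).
#'
#' @param g a [genotype_matrix()] (integer dosages; write imputed matrices as
#'   TSV only).
#' @param path output path.
#' @param format `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- data.frame(sample = sample_ids(g), g$dosage, check.names = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  if (g$imputed)
    stop("fractional (imputed) dosages cannot be written as VCF genotypes")
  ref <- ifelse(is.na(g$map$ref), "A", g$map$ref)
  alt <- ifelse(is.na(g$map$alt), "B", g$map$alt)
  gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- apply(g$dosage, 2, function(col) {
    out <- gt_codes[as.character(col)]
    out[is.na(col)] <- "./."
    out
  })  # samples x markers
  if (!is.matrix(body)) body <- matrix(body, nrow = nrow(g$dosage))
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=soypred",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids(g)), collapse = "\t"),
    vapply(seq_len(ncol(g$dosage)), function(j) {
      paste(c(g$map$chrom[j], format(g$map$pos[j], scientific = FALSE, trim = TRUE),
              g$map$marker[j], ref[j], alt[j], ".", "PASS", ".", "GT",
              body[, j]), collapse = "\t")
    }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
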