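test_that("VCF writing and reading round-trips dosages, map and missing cells", {
  st <- simulate_founder_panels(sim_panel_config(n_markers = 120, scale = 0.02,
                                                 seed = 21))
  g <- recode_minor(inject_missing(st$genotypes, 0.03, seed = 4))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes(g, path, "vcf")
  g2 <- read_genotypes(path, "vcf")
  expect_identical(g2$dosage, g$dosage)
  expect_equal(g2$map$chrom, g$map$chrom)
  expect_equal(g2$map$pos, g$map$pos)
})

test_that("TSV dosage tables round-trip including NA cells", {
  g <- recode_minor(toy_qc_matrix())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, path, "tsv")
  g2 <- read_genotypes(path, "tsv")
  expect_identical(g2$dosage, g$dosage)
})

test_that("half-missing and fully missing VCF calls become NA, multiallelics are dropped", {
  vcf <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
           "1\t100\tv1\tA\tC\t.\tPASS\t.\tGT\t0/1\t./.\t./1",
           "1\t200\tv2\tA\tC,G\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0",
           "1\t300\tv3\tG\tT\t.\tPASS\t.\tGT\t1/1\t1/1\t0/1")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  expect_message(g <- read_genotypes(path, "vcf"), "multiallelic")
  expect_equal(ncol(g$dosage), 2)  # v2 dropped
  expect_true(is.na(g$dosage["s2", "v1"]))
  expect_true(is.na(g$dosage["s3", "v1"]))
})

test_that("minor-allele orientation is computed on the loaded cohort", {
  # alt-allele counts {2,2,1}: alt frequency 5/6, so REF is the minor
  # allele and dosages are complemented on load
  vcf <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
           "1\t100\tv1\tA\tC\t.\tPASS\t.\tGT\t1/1\t1/1\t0/1")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  g <- read_genotypes(path, "vcf")
  expect_equal(unname(g$dosage[, "v1"]), c(0, 0, 1))
  expect_equal(g$map$ref, "C")  # major allele becomes the reference
  expect_equal(g$map$alt, "A")
})

test_that("merging cohorts intersects markers and recomputes the coding", {
  dos_a <- rbind(a1 = c(0, 0, 1), a2 = c(0, 1, 2), a3 = c(1, 0, 2))
  colnames(dos_a) <- c("m1", "m2", "m3")
  a <- recode_minor(genotype_matrix(dos_a, chrom = c("1", "1", "2"),
                                    pos = c(10, 20, 5),
                                    ref = c("A", "A", "A"),
                                    alt = c("B", "B", "B")))
  # same genotypes under renamed samples: doubles rows, keeps markers
  b_dos <- dos_a
  rownames(b_dos) <- c("b1", "b2", "b3")
  b <- recode_minor(genotype_matrix(b_dos, chrom = c("1", "1", "2"),
                                    pos = c(10, 20, 5),
                                    ref = c("A", "A", "A"),
                                    alt = c("B", "B", "B")))
  m <- merge_cohorts(a, b)
  expect_equal(dim(m$dosage), c(6, 3))
  # partial marker overlap reduces to the intersection
  b2 <- b[, c("m2", "m3")]
  m2 <- merge_cohorts(a, b2)
  expect_setequal(marker_ids(m2), c("m2", "m3"))
  expect_error(merge_cohorts(a, a), "overlap")
})

test_that("a marker minor in one cohort can flip after merging", {
  # m1 has alt frequency 1/3 in cohort a (alt = minor) but 5/6 in the
  # 3-sample cohort b, pooled 7/12 > 1/2, so the merged coding flips
  dos_a <- rbind(a1 = 0, a2 = 1, a3 = 1)
  colnames(dos_a) <- "m1"
  a <- recode_minor(genotype_matrix(dos_a, chrom = "1", pos = 1,
                                    ref = "A", alt = "B"))
  dos_b <- rbind(b1 = 2, b2 = 2, b3 = 1)
  colnames(dos_b) <- "m1"
  b <- genotype_matrix(dos_b, chrom = "1", pos = 1, ref = "A", alt = "B")
  expect_equal(unname(allele_frequencies(a)), 1 / 3)
  m <- merge_cohorts(a, b)
  # coded (minor) allele after merge is A, so a's dosages complement
  expect_equal(unname(m$dosage[, "m1"]), c(2, 1, 1, 0, 0, 1))
  expect_lte(unname(allele_frequencies(m)), 0.5)
})

test_that("the QC filter retains exactly the clean markers of the toy fixture", {
  g <- toy_qc_matrix()
  res <- filter_markers(g, qc_config(maf_min = 0.05, missing_max = 0.10))
  expect_equal(attr(res$report, "summary")$n_retained, 3)
  expect_setequal(marker_ids(res$genotypes), c("m3", "m4", "m5"))
  # identity configuration keeps everything
  res2 <- filter_markers(g, qc_config(maf_min = 0, missing_max = 1))
  expect_equal(ncol(res2$genotypes$dosage), 5)
  # boundary convention: MAF exactly at the threshold is retained
  dos <- rbind(s1 = c(0, 0), s2 = c(0, 0), s3 = c(0, 0), s4 = c(0, 0),
               s5 = c(1, 0), s6 = c(0, 0), s7 = c(0, 0), s8 = c(0, 0),
               s9 = c(0, 0), s10 = c(1, 1))
  colnames(dos) <- c("keep", "drop")  # MAF 0.10 and 0.05
  g3 <- genotype_matrix(dos)
  res3 <- filter_markers(g3, qc_config(maf_min = 0.10, missing_max = 1))
  expect_setequal(marker_ids(res3$genotypes), "keep")
  expect_error(filter_markers(g3, qc_config(maf_min = 0.5)), "all markers")
})

test_that("imputation fills missing cells as documented", {
  dos <- rbind(s1 = c(0, 0), s2 = c(2, 0), s3 = c(NA, 0), s4 = c(2, NA))
  colnames(dos) <- c("m1", "m2")
  g <- genotype_matrix(dos)
  gi <- impute_missing(g, "marker_mean")
  expect_equal(unname(gi$dosage["s3", "m1"]), 4 / 3)
  expect_equal(unname(gi$dosage["s4", "m2"]), 0)
  gm <- impute_missing(g, "marker_mode")
  expect_true(all(gm$dosage %in% c(0, 1, 2)))
  expect_equal(unname(gm$dosage["s3", "m1"]), 2)
  # no missing data: identity
  expect_identical(impute_missing(gi, "marker_mean")$dosage, gi$dosage)
  # a marker with observed (0, 2) imputes to 1.0
  dos2 <- rbind(s1 = 0, s2 = 2, s3 = NA)
  colnames(dos2) <- "m1"
  expect_equal(unname(impute_missing(genotype_matrix(dos2))$dosage["s3", 1]), 1)
})

test_that("allele frequencies are subset means, order-invariant", {
  dos <- rbind(s1 = c(0, 0), s2 = c(1, 0), s3 = c(2, 0))
  colnames(dos) <- c("m1", "m2")
  g <- genotype_matrix(dos)
  expect_equal(unname(allele_frequencies(g)), c(0.5, 0))
  expect_equal(allele_frequencies(g, c("s3", "s1", "s2")),
               allele_frequencies(g))
  expect_error(allele_frequencies(g, character(0)), "empty")
})

test_that("the pipeline convention is merge first, then filter", {
  # a marker rare in cohort a alone (MAF 1/6) but common in the union
  # survives QC only because filtering happens after merging; the reverse
  # order would discard it inside cohort a
  dos_a <- rbind(a1 = c(0, 0), a2 = c(0, 1), a3 = c(0, 1))
  dos_b <- rbind(b1 = c(1, 2), b2 = c(2, 1), b3 = c(1, 2))
  colnames(dos_a) <- colnames(dos_b) <- c("m1", "m2")
  a <- genotype_matrix(dos_a, ref = c("A", "A"), alt = c("B", "B"))
  b <- genotype_matrix(dos_b, ref = c("A", "A"), alt = c("B", "B"))
  qc <- qc_config(maf_min = 0.25, missing_max = 0.1)
  merged_then_filtered <- filter_markers(merge_cohorts(a, b), qc)
  expect_setequal(marker_ids(merged_then_filtered$genotypes), c("m1", "m2"))
  filtered_a <- filter_markers(a, qc)   # m1 fails inside cohort a alone
  expect_false("m1" %in% marker_ids(filtered_a$genotypes))
})
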