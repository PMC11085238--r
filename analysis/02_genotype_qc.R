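#!/usr/bin/env Rscript
# Stage 2 — merge cohorts and run genotype QC.
#
# Reads the panel and breeding-population VCFs written by stage 1, merges
# them on the shared marker set (minor-allele orientation recomputed on the
# combined cohort, as the study filtered the combined SNP set), removes
# markers with MAF < 5% or missingness > 10%, and mean-imputes the rest.

suppressPackageStartupMessages(library(soypred))

ind <- "results/simdata"
out <- "results/qc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

panels <- read_genotypes(file.path(ind, "panels.vcf"))
bp <- read_genotypes(file.path(ind, "bp.vcf"))
merged <- merge_cohorts(panels, bp)
message(sprintf("merged cohort: %d samples x %d shared markers",
                nrow(merged$dosage), ncol(merged$dosage)))

qc <- qc_config(maf_min = 0.05, missing_max = 0.10)
res <- filter_markers(merged, qc)
summ <- attr(res$report, "summary")
message(sprintf("QC: %d markers in, %d failed MAF, %d failed missingness, %d retained",
                summ$n_input, summ$n_removed_maf, summ$n_removed_missing,
                summ$n_retained))

imputed <- impute_missing(res$genotypes, "marker_mean")
write_genotypes(imputed, file.path(out, "merged_imputed_dosage.tsv"), "tsv")
write.table(res$report, file.path(out, "qc_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(summ, file.path(out, "qc_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS(imputed, file.path(out, "merged_imputed.rds"))  # scratch for later stages

message("wrote ", out)
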