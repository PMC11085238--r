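#!/usr/bin/env Rscript
# Stage 1 — simulate the study populations.
#
# Generates the six-panel germplasm collection (two diverged clusters:
# cultivated A-D, wild E-F) at desk scale, breeds a 175-line F2:6 RIL
# population from two inbred parents drawn out of panel A, assigns two
# negatively correlated polygenic traits (oil, protein), and writes every
# artifact downstream stages need: genotypes (VCF + dosage TSV, with a
# little injected missingness so QC has work to do), panel membership,
# multi-environment trial records for the BP, line means for the panels,
# and a truth file for recovery checks.

suppressPackageStartupMessages(library(soypred))

seed <- 1
out <- "results/simdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_panel_config(seed = seed)          # 2000 markers, scale 0.2
sim <- simulate_founder_panels(cfg)
message(sprintf("simulated %d accessions x %d markers in %d panels",
                nrow(sim$genotypes$dosage), ncol(sim$genotypes$dosage),
                length(unique(sim$panels))))

pA <- allele_frequencies(sim$genotypes, names(sim$panels)[sim$panels == "A"])
set.seed(seed + 2000)
parent1 <- draw_inbred_parent(pA)   # stands in for the high-protein parent
parent2 <- draw_inbred_parent(pA)   # stands in for the high-oil parent
rils <- simulate_biparental_rils(parent1, parent2, sim$map,
                                 ril_config(175, 6, seed = seed))
message(sprintf("bred %d F2:6 RILs; residual heterozygosity %.3f (expect ~%.3f)",
                nrow(rils$dosage), mean(rils$dosage == 1), 0.5^5))

arch <- trait_architecture()        # n_qtl 200, rho -0.7, h2 0.9, e 6, r 3
effects <- assign_qtl_effects(
  recode_minor(merge_cohorts(sim$genotypes, rils)), arch, seed = seed)

# BP trial records: 6 environments x 3 replicates
bp_pheno <- simulate_phenotypes(rils, effects[marker_ids(rils), ], arch,
                                seed = seed + 1)
# panel phenotypes are line means, as public descriptor data effectively are
panel_means <- simulate_line_means(sim$genotypes,
                                   effects[marker_ids(sim$genotypes), ],
                                   h2 = 0.9, arch = arch, seed = seed + 2)

# inject 2% missing calls before writing, so stage 2 exercises QC
g_panels <- inject_missing(sim$genotypes, 0.02, seed = seed + 3)
g_bp <- inject_missing(rils, 0.02, seed = seed + 4)
write_genotypes(g_panels, file.path(out, "panels.vcf"), "vcf")
write_genotypes(g_bp, file.path(out, "bp.vcf"), "vcf")
write_genotypes(g_panels, file.path(out, "panels_dosage.tsv"), "tsv")

write.table(data.frame(sample = names(sim$panels), panel = sim$panels,
                       cluster = sim$clusters),
            file.path(out, "panel_assignment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.csv(bp_pheno, file.path(out, "bp_trial_records.csv"), row.names = FALSE)
write.csv(panel_means, file.path(out, "panel_line_means.csv"),
          row.names = FALSE)

truth <- attr(bp_pheno, "truth")
jsonlite::write_json(
  list(seed = seed,
       qtl = attr(effects, "qtl"),
       effects = list(oil = unname(effects[, "oil"]),
                      protein = unname(effects[, "protein"])),
       markers = rownames(effects),
       variance_components = truth$components),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)

message("wrote ", out)
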