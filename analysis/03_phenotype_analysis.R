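#!/usr/bin/env Rscript
# Stage 3 — phenotype summarisation.
#
# Produces the descriptive-statistics table for every population (panels
# A-F from line means, BP from its trial records), the BP ANOVA with
# variance components and broad-sense heritability for both traits, the
# oil-protein correlation per population, and the BP BLUEs used as the
# prediction target in later stages.

suppressPackageStartupMessages(library(soypred))

ind <- "results/simdata"
out <- "results/pheno"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

panels <- read.table(file.path(ind, "panel_assignment.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
panel_means <- read.csv(file.path(ind, "panel_line_means.csv"),
                        stringsAsFactors = FALSE)
bp <- read.csv(file.path(ind, "bp_trial_records.csv"),
               stringsAsFactors = FALSE)

# BLUEs across environments for the breeding population
blues <- compute_blues(bp)
write.table(blues, file.path(out, "bp_blues.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# descriptive statistics (the Table-1-shaped report)
panel_means$panel <- panels$panel[match(panel_means$line, panels$sample)]
desc <- do.call(rbind, lapply(c("oil", "protein"), function(tr) {
  rows <- lapply(split(panel_means[[tr]], panel_means$panel),
                 descriptive_stats)
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, descriptive_stats(blues[[tr]]))
  data.frame(trait = tr, population = c(names(rows), "BP"), tab)
}))
write.table(desc, file.path(out, "descriptive_stats.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# ANOVA variance components and heritability (the Table-2-shaped report)
anova_tab <- do.call(rbind, lapply(c("oil", "protein"), function(tr) {
  vc <- anova_components(bp, tr)
  data.frame(trait = tr, ms_E = vc$ms[["E"]], ms_G = vc$ms[["G"]],
             ms_GE = vc$ms[["GE"]], ms_error = vc$ms[["error"]],
             sigma2_G = vc$sigma2_G, sigma2_GE = vc$sigma2_GE,
             sigma2_e = vc$sigma2_e, h2 = round(vc$h2, 2))
}))
write.table(anova_tab, file.path(out, "bp_anova_h2.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("BP broad-sense h2: oil %.2f, protein %.2f (target 0.9)",
                anova_tab$h2[1], anova_tab$h2[2]))

# oil-protein correlation per population
cors <- do.call(rbind, lapply(split(panel_means, panel_means$panel),
  function(d) data.frame(population = d$panel[1], n = nrow(d),
                         r_oil_protein = trait_correlation(d$oil, d$protein))))
cors <- rbind(cors, data.frame(population = "BP", n = nrow(blues),
                               r_oil_protein = trait_correlation(blues$oil,
                                                                 blues$protein)))
write.table(cors, file.path(out, "trait_correlations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("oil-protein correlation in BP: %.2f",
                cors$r_oil_protein[cors$population == "BP"]))
message("wrote ", out)
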