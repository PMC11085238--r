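#!/usr/bin/env Rscript
# Stage 5 — within-population prediction ability.
#
# Ten-fold cross-validation inside the breeding population for all five
# whole-genome regression models (G-BLUP, RR-BLUP, BRR, BL, BayesB), both
# traits. The Bayesian models run reduced chains (2,000 iterations, 500
# burn-in) at this desk scale; single fits elsewhere keep the full
# 10,000/2,000 default.

suppressPackageStartupMessages(library(soypred))

out <- "results/within_cv"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1

geno <- readRDS("results/qc/merged_imputed.rds")
blues <- read.table("results/pheno/bp_blues.tsv", header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
message("reduced MCMC chains (2000/500) in cross-validation sweeps")
mc <- mcmc_config(n_iter = 2000, burn_in = 500, seed = seed)

rows <- list()
for (tr in c("oil", "protein")) {
  y <- setNames(blues[[tr]], blues$line)
  for (model in c("GBLUP", "RRBLUP", "BRR", "BL", "BayesB")) {
    cv <- kfold_cv(geno, y, model = model, k = 10, seed = seed, mcmc = mc)
    rows[[paste(tr, model)]] <-
      data.frame(trait = tr, model = model, cv$per_fold)
    message(sprintf("%-8s %-7s mean PA %.3f (SE %.3f)", tr, model,
                    cv$summary$mean_pa, cv$summary$se_pa))
  }
}
per_fold <- do.call(rbind, rows)
write.table(per_fold, file.path(out, "per_fold.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
summ <- aggregate(pa ~ trait + model, per_fold, function(x)
  c(mean = mean(x), se = sd(x) / sqrt(length(x))))
summ <- data.frame(summ[1:2], mean_pa = summ$pa[, "mean"],
                   se_pa = summ$pa[, "se"])
write.table(summ, file.path(out, "summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote ", out)
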