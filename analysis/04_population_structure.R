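#!/usr/bin/env Rscript
# Stage 4 — population structure and relatedness.
#
# PCA of the merged, QC-filtered, imputed cohort; pairwise and group-level
# Euclidean genetic distances; UPGMA dendrogram of the seven populations;
# and the distance-ranked candidate list used for training-set optimisation.

suppressPackageStartupMessages(library(soypred))

out <- "results/structure"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

geno <- readRDS("results/qc/merged_imputed.rds")
panels <- read.table("results/simdata/panel_assignment.tsv", header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
groups <- setNames(panels$panel, panels$sample)
bp_ids <- setdiff(sample_ids(geno), panels$sample)
groups[bp_ids] <- "BP"

pc <- pca_genotypes(geno, 5)
scores <- data.frame(sample = rownames(pc$scores), group = groups[rownames(pc$scores)],
                     pc$scores)
write.table(scores, file.path(out, "pca_scores.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("PC1 explains %.1f%%, PC2 %.1f%% of dosage variance",
                100 * pc$var_explained[1], 100 * pc$var_explained[2]))

D <- pairwise_distance(geno)
labs <- c("A", "B", "C", "D", "E", "F", "BP")
GD <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
for (i in labs) for (j in labs)
  if (i != j) GD[i, j] <- group_distance(D, groups, i, j)
write.table(data.frame(group = rownames(GD), round(GD, 3)),
            file.path(out, "group_distances.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("group distances to BP (ascending):")
print(sort(GD["BP", labs != "BP"]))

up <- upgma_cluster(GD)
writeLines(up$newick, file.path(out, "upgma_groups.nwk"))
ct <- cutree(up$hclust, k = 2)
message("two-group cut of the UPGMA tree: ",
        paste(names(ct), ct, sep = "=", collapse = " "))

ranked <- rank_by_distance(D, names(groups)[groups != "BP"], bp_ids)
write.table(data.frame(rank = seq_along(ranked), sample = ranked,
                       panel = groups[ranked],
                       mean_distance_to_bp = as.numeric(names(ranked))),
            file.path(out, "candidates_ranked_by_distance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote ", out)
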