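# Scenario builders shared by the experiment-level and acceptance tests.
# Each returns a complete simulated study: structured germplasm panels, a
# biparental RIL breeding population (BP) bred from cluster-I parents, and
# line-mean phenotypes for two negatively correlated traits.

bp_study <- function(seed, n_markers = 800, scale = 0.15, n_lines = 175,
                     n_qtl = 100, h2 = 0.9, chrom_length_cM = 40) {
  cfg <- sim_panel_config(n_markers = n_markers, scale = scale,
                          chrom_length_cM = chrom_length_cM, seed = seed)
  sim <- simulate_founder_panels(cfg)
  pA <- allele_frequencies(sim$genotypes,
                           names(sim$panels)[sim$panels == "A"])
  set.seed(seed + 2000)
  p1 <- draw_inbred_parent(pA)
  p2 <- draw_inbred_parent(pA)
  rils <- simulate_biparental_rils(p1, p2, sim$map,
                                   ril_config(n_lines, 6, seed = seed))
  geno <- recode_minor(merge_cohorts(sim$genotypes, rils))
  arch <- trait_architecture(n_qtl = n_qtl)
  eff <- assign_qtl_effects(geno, arch, seed = seed)
  ph <- simulate_line_means(geno, eff, h2 = h2, arch = arch,
                            seed = seed + 500)
  bp_ids <- sample_ids(rils)
  groups <- c(sim$panels,
              stats::setNames(rep("BP", length(bp_ids)), bp_ids))
  list(geno = geno, panels = sim$panels, clusters = sim$clusters,
       groups = groups, bp_ids = bp_ids, pheno = ph, effects = eff,
       map = sim$map, arch = arch)
}

pheno_vec <- function(study, trait) {
  stats::setNames(study$pheno[[trait]], study$pheno$line)
}

# Panels drifted from a common ancestor at a gradient of Fst values, plus a
# biparental RIL family bred from the low-drift source population.
gradient_study <- function(seed, fsts = c(0.05, 0.2, 0.45, 0.8),
                           n_markers = 1000, n_train = 400, n_lines = 175) {
  set.seed(seed)
  p_anc <- runif(n_markers, 0.1, 0.9)
  map <- make_marker_map(n_markers, 20, 40)
  labels <- paste0("P", seq_along(fsts))
  sim <- simulate_drifted_panels(
    p_anc,
    panel_fst = stats::setNames(c(0.02, fsts), c("S", labels)),
    panel_sizes = stats::setNames(c(40, rep(n_train, length(fsts))),
                                  c("S", labels)),
    map = map)
  pS <- allele_frequencies(sim$genotypes,
                           names(sim$panels)[sim$panels == "S"])
  set.seed(seed + 3000)
  rils <- simulate_biparental_rils(draw_inbred_parent(pS),
                                   draw_inbred_parent(pS), map,
                                   ril_config(n_lines, 6, seed = seed))
  geno <- recode_minor(merge_cohorts(sim$genotypes, rils))
  bp_ids <- sample_ids(rils)
  groups <- c(sim$panels,
              stats::setNames(rep("BP", length(bp_ids)), bp_ids))
  list(geno = geno, panels = sim$panels, groups = groups, bp_ids = bp_ids,
       panel_labels = labels, fsts = fsts, map = map)
}

# The printed 4 x 5 QC fixture: one monomorphic marker, one with 50%
# missing calls, three clean markers with MAF >= 0.125.
toy_qc_matrix <- function() {
  dos <- rbind(s1 = c(0, NA, 0, 1, 2),
               s2 = c(0, NA, 1, 0, 2),
               s3 = c(0, 0, 2, 0, 2),
               s4 = c(0, 2, 0, 0, 1))
  colnames(dos) <- paste0("m", 1:5)
  genotype_matrix(dos)
}
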