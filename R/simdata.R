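#' Configuration for simulated germplasm panels
#'
#' Describes a set of germplasm panels arranged in two diverged clusters —
#' four cultivated-type panels (A–D, cluster I) and two wild-type panels
#' (E–F, cluster II) — whose joint size at `scale = 1` is 4141 accessions.
#' Differentiation is generated by hierarchical Balding–Nichols drift: an
#' ancestral allele frequency per marker, a cluster-level draw at
#' `fst_between_cluster`, then a panel-level draw at `fst_within_cluster`.
#'
#' The desk-scale default (`scale = 0.2`, 2000 markers on 20 chromosomes)
#' keeps every downstream stage runnable in seconds while preserving the
#' cluster structure; `scale = 1` reproduces the full panel sizes.
#'
#' @param n_markers total marker count (default 2000).
#' @param n_chromosomes number of chromosomes (default 20, as in soybean).
#' @param chrom_length_cM genetic map length per chromosome in centimorgans
#'   (recycled; default 120).
#' @param panel_sizes named accession counts per panel before scaling.
#' @param cluster_assignment named map from panel label to `"I"` or `"II"`.
#' @param fst_within_cluster Fst of each panel around its cluster frequency.
#' @param fst_between_cluster Fst of each cluster around the ancestral
#'   frequency; must exceed `fst_within_cluster`.
#' @param scale multiplier applied to `panel_sizes` (sizes are rounded and
#'   floored at 2).
#' @param seed integer seed making the simulation reproducible.
#' @return A `sim_panel_config` list.
#' @export
sim_panel_config <- function(n_markers = 2000, n_chromosomes = 20,
                             chrom_length_cM = 120,
                             panel_sizes = c(A = 1007, B = 607, C = 965,
                                             D = 811, E = 508, F = 243),
                             cluster_assignment = c(A = "I", B = "I", C = "I",
                                                    D = "I", E = "II", F = "II"),
                             fst_within_cluster = 0.05,
                             fst_between_cluster = 0.30,
                             scale = 0.2, seed = 1L) {
  sizes <- pmax(2L, as.integer(round(panel_sizes * scale)))
  names(sizes) <- names(panel_sizes)
  stopifnot(all(sizes >= 2),
            fst_within_cluster >= 0,
            fst_within_cluster < fst_between_cluster,
            fst_between_cluster < 1,
            setequal(names(panel_sizes), names(cluster_assignment)),
            all(cluster_assignment %in% c("I", "II")))
  structure(list(n_markers = as.integer(n_markers),
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_cM = rep_len(chrom_length_cM, n_chromosomes),
                 panel_sizes = sizes,
                 cluster_assignment = cluster_assignment[names(sizes)],
                 fst_within_cluster = fst_within_cluster,
                 fst_between_cluster = fst_between_cluster,
                 seed = as.integer(seed)),
            class = "sim_panel_config")
}

#' Trait architecture for two correlated polygenic traits
#'
#' Defaults emulate soybean seed oil and protein content: a strong negative
#' genetic correlation between the traits' QTL effects, line-mean
#' broad-sense heritability around 0.9 from a replicated multi-environment
#' trial, and trait means anchored to the two breeding parents (a
#' high-protein parent at oil 17 / protein 46 and a high-oil parent at oil
#' 24 / protein 36, in % of seed weight).
#'
#' @param n_qtl number of causal markers (default 200).
#' @param effect_correlation correlation of the two traits' QTL effect
#'   pairs (default −0.7).
#' @param target_h2 line-mean broad-sense heritability per trait
#'   (default 0.9).
#' @param n_env number of environments `e` (default 6: two years by three
#'   locations).
#' @param n_rep replicates per environment `r` (default 3).
#' @param gxe_variance_ratio genotype-by-environment interaction variance as
#'   a fraction of genetic variance (default 0.1).
#' @param env_variance_ratio,rep_variance_ratio environment and
#'   replicate-within-environment variances as fractions of genetic variance
#'   (cosmetic; they do not enter line-mean heritability).
#' @param genetic_sd per-trait genetic standard deviation, in trait units
#'   (% seed weight); defaults follow the spread observed in biparental
#'   soybean material.
#' @param parent_means 2 x 2 matrix of parent trait means (rows = parents,
#'   columns = traits) used only to centre the traits on realistic values.
#' @return A `trait_architecture` list.
#' @export
trait_architecture <- function(n_qtl = 200, effect_correlation = -0.7,
                               target_h2 = 0.9, n_env = 6, n_rep = 3,
                               gxe_variance_ratio = 0.1,
                               env_variance_ratio = 2,
                               rep_variance_ratio = 0.2,
                               genetic_sd = c(oil = 1.0, protein = 1.8),
                               parent_means = rbind(
                                 JD12 = c(oil = 17, protein = 46),
                                 NF58 = c(oil = 24, protein = 36))) {
  stopifnot(effect_correlation >= -1, effect_correlation <= 1,
            target_h2 > 0, target_h2 <= 1, n_env >= 1, n_rep >= 1,
            gxe_variance_ratio >= 0, all(genetic_sd > 0))
  structure(list(n_qtl = as.integer(n_qtl),
                 effect_correlation = effect_correlation,
                 target_h2 = target_h2, n_env = as.integer(n_env),
                 n_rep = as.integer(n_rep),
                 gxe_variance_ratio = gxe_variance_ratio,
                 env_variance_ratio = env_variance_ratio,
                 rep_variance_ratio = rep_variance_ratio,
                 genetic_sd = genetic_sd, parent_means = parent_means),
            class = "trait_architecture")
}

#' Configuration for a biparental RIL population
#'
#' @param n_lines number of recombinant inbred lines (default 175).
#' @param final_generation selfing generation of the lines (default 6, i.e.
#'   F6: five selfing meioses after the F1).
#' @param seed integer seed.
#' @return A `ril_config` list.
#' @export
ril_config <- function(n_lines = 175, final_generation = 6, seed = 1L) {
  stopifnot(n_lines >= 1, final_generation >= 2)
  structure(list(n_lines = as.integer(n_lines),
                 final_generation = as.integer(final_generation),
                 seed = as.integer(seed)),
            class = "ril_config")
}

#' Evenly spaced marker map
#'
#' Positions in cM, markers divided as evenly as possible over chromosomes.
#'
#' @param n_markers total marker count.
#' @param n_chromosomes chromosome count.
#' @param chrom_length_cM map length per chromosome (recycled).
#' @return Data frame with columns `marker`, `chrom`, `pos`.
#' @export
make_marker_map <- function(n_markers, n_chromosomes = 20,
                            chrom_length_cM = 120) {
  len <- rep_len(chrom_length_cM, n_chromosomes)
  per <- rep(n_markers %/% n_chromosomes, n_chromosomes)
  extra <- n_markers %% n_chromosomes
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
  chrom <- rep(sprintf("chr%02d", seq_len(n_chromosomes)), per)
  pos <- unlist(lapply(seq_len(n_chromosomes), function(c) {
    if (per[c] == 0) return(numeric(0))
    seq(0, len[c], length.out = per[c] + 2)[seq_len(per[c]) + 1]
  }))
  data.frame(marker = sprintf("m%05d", seq_len(n_markers)),
             chrom = chrom, pos = round(pos, 4), stringsAsFactors = FALSE)
}

.rbeta_bn <- function(p, fst) {
  # Balding-Nichols draw of a descendant frequency around p at drift fst
  if (fst <= 0) return(p)
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  stats::rbeta(length(p), a, b)
}

#' Simulate panels drifted from shared ancestral frequencies
#'
#' Lower-level generator behind [simulate_founder_panels()]: each panel's
#' allele frequencies are one Balding–Nichols draw from the supplied
#' ancestral frequencies at a panel-specific Fst, and genotypes are
#' Hardy–Weinberg binomial draws within panel. Useful on its own to build
#' panels at a controlled divergence gradient from a reference population.
#'
#' @param p_anc ancestral allele frequency per marker.
#' @param panel_fst named per-panel Fst relative to the ancestor.
#' @param panel_sizes named per-panel accession counts.
#' @param map marker map (see [make_marker_map()]); defaults to a single
#'   dummy chromosome.
#' @param seed integer seed; the caller may instead manage the RNG state.
#' @return List with `genotypes` (a [genotype_matrix()], dosages counting
#'   the "derived" allele), `panels` (named character vector sample ->
#'   panel) and `panel_freqs` (marker x panel frequency matrix).
#' @export
simulate_drifted_panels <- function(p_anc, panel_fst, panel_sizes,
                                    map = NULL, seed = NULL) {
  stopifnot(length(panel_fst) == length(panel_sizes),
            !is.null(names(panel_fst)), setequal(names(panel_fst), names(panel_sizes)))
  if (!is.null(seed)) set.seed(seed)
  m <- length(p_anc)
  labels <- names(panel_sizes)
  pf <- sapply(labels, function(l) .rbeta_bn(p_anc, panel_fst[[l]]))
  dos <- do.call(rbind, lapply(labels, function(l) {
    n <- panel_sizes[[l]]
    matrix(rbinom(n * m, 2, rep(pf[, l], each = n)), nrow = n,
           dimnames = list(sprintf("%s_%04d", l, seq_len(n)), NULL))
  }))
  map <- map %||% data.frame(marker = sprintf("m%05d", seq_len(m)),
                             chrom = "0", pos = seq_len(m))
  colnames(dos) <- map$marker
  g <- genotype_matrix(dos, chrom = map$chrom, pos = map$pos,
                       ref = rep("A", m), alt = rep("B", m), coding = "alt")
  panels <- rep(labels, panel_sizes[labels])
  names(panels) <- rownames(dos)
  list(genotypes = g, panels = panels, panel_freqs = pf)
}

#' Simulate the structured germplasm panels
#'
#' Draws ancestral allele frequencies uniformly on (0.05, 0.95), applies
#' cluster-level Balding–Nichols drift at `fst_between_cluster` and
#' panel-level drift at `fst_within_cluster`, then samples Hardy–Weinberg
#' genotypes within each panel. Markers whose frequency ends up fixed in
#' every panel are redrawn (up to 20 rounds); if more than half the markers
#' are nevertheless monomorphic in the realized genotypes, a warning is
#' issued.
#'
#' @param config a [sim_panel_config()].
#' @return List with `genotypes`, `panels`, `clusters` (named character
#'   vector sample -> cluster), `ancestral_freqs`, `panel_freqs` and `map`.
#' @export
simulate_founder_panels <- function(config = sim_panel_config()) {
  set.seed(config$seed)
  m <- config$n_markers
  labels <- names(config$panel_sizes)
  map <- make_marker_map(m, config$n_chromosomes, config$chrom_length_cM)

  draw_freqs <- function(idx) {
    p_anc <- runif(length(idx), 0.05, 0.95)
    pc <- vapply(c(I = "I", II = "II"), function(cl)
      .rbeta_bn(p_anc, config$fst_between_cluster),
      numeric(length(idx)))
    if (!is.matrix(pc)) pc <- matrix(pc, nrow = 1, dimnames = list(NULL, c("I", "II")))
    pf <- vapply(labels, function(l)
      .rbeta_bn(pc[, config$cluster_assignment[[l]]],
                config$fst_within_cluster),
      numeric(length(idx)))
    if (!is.matrix(pf)) pf <- matrix(pf, nrow = 1, dimnames = list(NULL, labels))
    list(p_anc = p_anc, pf = pf)
  }

  fr <- draw_freqs(seq_len(m))
  for (round in seq_len(20)) {
    fixed <- rowSums(fr$pf > 1e-6 & fr$pf < 1 - 1e-6) == 0
    if (!any(fixed)) break
    redraw <- draw_freqs(which(fixed))
    fr$p_anc[fixed] <- redraw$p_anc
    fr$pf[fixed, ] <- redraw$pf
  }

  dos <- do.call(rbind, lapply(labels, function(l) {
    n <- config$panel_sizes[[l]]
    matrix(rbinom(n * m, 2, rep(fr$pf[, l], each = n)), nrow = n,
           dimnames = list(sprintf("%s_%04d", l, seq_len(n)), NULL))
  }))
  colnames(dos) <- map$marker
  g <- genotype_matrix(dos, chrom = map$chrom, pos = map$pos,
                       ref = rep("A", m), alt = rep("B", m), coding = "alt")
  mono <- mean(apply(dos, 2, function(x) length(unique(x[!is.na(x)])) == 1))
  if (mono > 0.5)
    warning(sprintf("%.0f%% of markers are monomorphic in the simulated panels",
                    100 * mono))
  panels <- rep(labels, config$panel_sizes[labels])
  names(panels) <- rownames(dos)
  clusters <- setNames(unname(config$cluster_assignment[panels]), names(panels))
  list(genotypes = g, panels = panels, clusters = clusters,
       ancestral_freqs = fr$p_anc, panel_freqs = fr$pf, map = map)
}

#' Draw a fully inbred parent from panel allele frequencies
#'
#' @param freqs allele frequency per marker.
#' @return Homozygous dosage vector (0 or 2 at every marker).
#' @export
draw_inbred_parent <- function(freqs) 2 * rbinom(length(freqs), 1, freqs)

.haldane <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

.recomb_probs <- function(map) {
  # per-marker transition probability used during gamete formation: the
  # first marker of each chromosome segregates independently (prob 1/2)
  m <- nrow(map)
  r <- numeric(m)
  new_chrom <- c(TRUE, map$chrom[-1] != map$chrom[-m])
  d <- c(0, diff(map$pos))
  r[!new_chrom] <- .haldane(d[!new_chrom])
  r[new_chrom] <- 0.5
  r
}

.gamete <- function(hapA, hapB, rprob) {
  cross <- rbinom(length(rprob), 1, rprob)
  strand <- cumsum(cross) %% 2
  ifelse(strand == 0, hapA, hapB)
}

#' Simulate a biparental RIL population by single seed descent
#'
#' Crosses two fully inbred parents and advances each F1-derived lineage by
#' repeated selfing with a single offspring kept per generation (single seed
#' descent), to the configured generation (default F6). Meiosis follows
#' Haldane's map function — recombination probability
#' `(1 - exp(-2 d / 100)) / 2` for an interval of `d` cM, no interference —
#' and chromosomes assort independently. Residual heterozygosity is kept
#' (about `0.5^(final_generation - 1)` per locus at F6, i.e. ~3%), as real
#' F2-derived lines retain it.
#'
#' @param parent1,parent2 homozygous dosage vectors (0/2) over the markers
#'   of `map`.
#' @param map marker map sorted by chromosome and position (columns
#'   `marker`, `chrom`, `pos` with `pos` in cM).
#' @param config a [ril_config()].
#' @return A [genotype_matrix()] of the RILs (dosages count the same allele
#'   as the parents' coding).
#' @export
simulate_biparental_rils <- function(parent1, parent2, map,
                                     config = ril_config()) {
  m <- nrow(map)
  stopifnot(length(parent1) == m, length(parent2) == m)
  if (!all(parent1 %in% c(0, 2)) || !all(parent2 %in% c(0, 2)))
    stop("parents must be homozygous (dosage 0 or 2) at every marker")
  if (is.unsorted(order(map$chrom, map$pos)) ||
      any(stats::ave(map$pos, map$chrom, FUN = function(x) c(0, diff(x))) < 0))
    stop("marker map must be sorted by position within chromosome")
  set.seed(config$seed)
  rprob <- .recomb_probs(map)
  h1 <- parent1 / 2
  h2 <- parent2 / 2
  n_meioses <- config$final_generation - 1
  dos <- matrix(NA_real_, config$n_lines, m,
                dimnames = list(sprintf("RIL_%03d", seq_len(config$n_lines)),
                                map$marker))
  for (i in seq_len(config$n_lines)) {
    a <- h1; b <- h2  # the F1
    for (gen in seq_len(n_meioses)) {
      ga <- .gamete(a, b, rprob)
      gb <- .gamete(a, b, rprob)
      a <- ga; b <- gb
    }
    dos[i, ] <- a + b
  }
  genotype_matrix(dos, chrom = map$chrom, pos = map$pos,
                  ref = rep("A", m), alt = rep("B", m), coding = "alt")
}

#' Assign bivariate QTL effects to markers
#'
#' Chooses `n_qtl` markers uniformly at random and draws their (oil,
#' protein) effect pairs from a standard bivariate normal with correlation
#' `effect_correlation`; all other markers get zero effects.
#'
#' @param genotypes a [genotype_matrix()] (only its marker ids are used).
#' @param arch a [trait_architecture()].
#' @param seed integer seed.
#' @return Numeric matrix markers x 2 (columns `oil`, `protein`) with the
#'   chosen QTL ids in attribute `"qtl"`.
#' @export
assign_qtl_effects <- function(genotypes, arch = trait_architecture(),
                               seed = 1L) {
  m <- ncol(genotypes$dosage)
  stopifnot(arch$n_qtl <= m, abs(arch$effect_correlation) <= 1)
  set.seed(seed)
  qtl <- sort(sample.int(m, arch$n_qtl))
  rho <- arch$effect_correlation
  eff <- matrix(0, m, 2, dimnames = list(marker_ids(genotypes),
                                         c("oil", "protein")))
  eff[qtl, ] <- MASS::mvrnorm(arch$n_qtl, mu = c(0, 0),
                              Sigma = matrix(c(1, rho, rho, 1), 2))
  attr(eff, "qtl") <- marker_ids(genotypes)[qtl]
  eff
}

.scaled_genetic_values <- function(genotypes, effects, sds, centre = 0) {
  gv <- genotypes$dosage %*% effects
  for (t in seq_len(ncol(gv))) {
    s <- sd(gv[, t])
    if (s == 0) stop("zero genetic variance for trait ", colnames(gv)[t])
    gv[, t] <- (gv[, t] - mean(gv[, t])) / s * sds[t]
  }
  gv
}

#' Simulate multi-environment replicated phenotypes
#'
#' Generates trial records `Y_ijk = mu + E_i + R_j(E_i) + G_k + GE_ik +
#' e_ijk` for both traits jointly. Genetic values come from the marker
#' effects, rescaled to the architecture's per-trait genetic SD and centred
#' on the midparent mean. The genotype-by-environment and residual
#' variances are solved from the target line-mean broad-sense heritability
#' `h2 = s2G / (s2G + s2GE/e + s2e/(r e))`, so the realized ANOVA estimate
#' of h2 is close to target by construction. Environment and
#' replicate-within-environment effects are i.i.d. normal with variances
#' set by the architecture's cosmetic ratios; they cancel from line means
#' and from the heritability.
#'
#' @param genotypes a [genotype_matrix()] of the phenotyped lines.
#' @param effects marker-effect matrix from [assign_qtl_effects()].
#' @param arch a [trait_architecture()].
#' @param seed integer seed.
#' @return Long data frame (`line`, `env`, `rep`, `trait`, `value`) with a
#'   `"truth"` attribute carrying the genetic values and the variance
#'   components used per trait.
#' @export
simulate_phenotypes <- function(genotypes, effects,
                                arch = trait_architecture(), seed = 1L) {
  set.seed(seed)
  gv <- .scaled_genetic_values(genotypes, effects, arch$genetic_sd)
  n <- nrow(gv); e <- arch$n_env; r <- arch$n_rep
  lines <- sample_ids(genotypes)
  envs <- sprintf("E%d", seq_len(e))
  reps <- sprintf("R%d", seq_len(r))
  out <- list(); truth_vc <- list()
  for (t in colnames(gv)) {
    s2G <- arch$genetic_sd[[t]]^2
    s2GE <- arch$gxe_variance_ratio * s2G
    s2e <- r * e * (s2G / arch$target_h2 - s2G - s2GE / e)
    if (s2e < -1e-9)
      stop("target_h2 unattainable with this gxe_variance_ratio")
    s2e <- max(s2e, 0)
    mu <- mean(arch$parent_means[, t])
    env_eff <- rnorm(e, 0, sqrt(arch$env_variance_ratio * s2G))
    rep_eff <- matrix(rnorm(e * r, 0, sqrt(arch$rep_variance_ratio * s2G)),
                      e, r)
    ge_eff <- matrix(rnorm(n * e, 0, sqrt(s2GE)), n, e)
    grid <- expand.grid(line = seq_len(n), rep = seq_len(r),
                        env = seq_len(e))
    val <- mu + env_eff[grid$env] + rep_eff[cbind(grid$env, grid$rep)] +
      gv[grid$line, t] + ge_eff[cbind(grid$line, grid$env)] +
      rnorm(nrow(grid), 0, sqrt(s2e))
    out[[t]] <- data.frame(line = lines[grid$line], env = envs[grid$env],
                           rep = reps[grid$rep], trait = t, value = val,
                           stringsAsFactors = FALSE)
    truth_vc[[t]] <- list(mu = mu, sigma2_G = s2G, sigma2_GE = s2GE,
                          sigma2_e = s2e, e = e, r = r,
                          h2 = s2G / (s2G + s2GE / e + s2e / (r * e)))
  }
  pheno <- do.call(rbind, out)
  rownames(pheno) <- NULL
  attr(pheno, "truth") <- list(genetic_values = gv,
                               components = truth_vc)
  pheno
}

#' Simulate line-mean phenotypes at a given heritability
#'
#' Convenience generator for germplasm panels whose public phenotypes are
#' effectively line means: genetic value plus one normal deviate with
#' variance `s2G (1/h2 - 1)`, i.e. line-mean heritability `h2`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param effects marker-effect matrix.
#' @param h2 line-mean heritability.
#' @param arch a [trait_architecture()] supplying trait scales and means.
#' @param seed integer seed.
#' @return Data frame (`line`, `oil`, `protein`) with `"truth"` attribute
#'   carrying the genetic values.
#' @export
simulate_line_means <- function(genotypes, effects, h2 = 0.9,
                                arch = trait_architecture(), seed = 1L) {
  stopifnot(h2 > 0, h2 <= 1)
  set.seed(seed)
  gv <- .scaled_genetic_values(genotypes, effects, arch$genetic_sd)
  out <- data.frame(line = sample_ids(genotypes), stringsAsFactors = FALSE)
  for (t in colnames(gv)) {
    s2G <- arch$genetic_sd[[t]]^2
    noise_sd <- sqrt(s2G * (1 / h2 - 1))
    out[[t]] <- mean(arch$parent_means[, t]) + gv[, t] +
      rnorm(nrow(gv), 0, noise_sd)
  }
  attr(out, "truth") <- list(genetic_values = gv, h2 = h2)
  out
}

#' Mask genotype calls at random
#'
#' Each cell is masked independently with probability `rate`; the mask is
#' recorded in the `missing_mask` element so QC and imputation can be
#' checked against it.
#'
#' @param g a [genotype_matrix()].
#' @param rate missing probability in \[0, 1).
#' @param seed integer seed.
#' @return The masked `genotype_matrix`.
#' @export
inject_missing <- function(g, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  set.seed(seed)
  mask <- matrix(runif(length(g$dosage)) < rate, nrow(g$dosage),
                 dimnames = dimnames(g$dosage))
  g$dosage[mask] <- NA
  g$missing_mask <- mask
  g
}

#' Hudson's Fst between two sample groups
#'
#' Ratio-of-averages Hudson estimator with the finite-sample correction on
#' the numerator; markers whose between-group heterozygosity is zero are
#' dropped.
#'
#' @param g a [genotype_matrix()].
#' @param samples1,samples2 sample ids of the two groups.
#' @return Scalar Fst estimate.
#' @export
hudson_fst <- function(g, samples1, samples2) {
  freq_n <- function(ids) {
    d <- g$dosage[ids, , drop = FALSE]
    n <- 2 * colSums(!is.na(d))
    list(p = colMeans(d, na.rm = TRUE) / 2, n = n)
  }
  a <- freq_n(samples1); b <- freq_n(samples2)
  num <- (a$p - b$p)^2 - a$p * (1 - a$p) / (a$n - 1) -
    b$p * (1 - b$p) / (b$n - 1)
  den <- a$p * (1 - b$p) + b$p * (1 - a$p)
  ok <- is.finite(num) & is.finite(den) & den > 0
  sum(num[ok]) / sum(den[ok])
}
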