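test_that("founder panels have the configured dimensions, coding and determinism", {
  cfg <- sim_panel_config(scale = 0.1, n_markers = 2000, seed = 11)
  sim <- simulate_founder_panels(cfg)
  expect_equal(dim(sim$genotypes$dosage), c(414, 2000))
  expect_true(all(sim$genotypes$dosage %in% c(0, 1, 2)))
  expect_equal(unname(table(sim$panels)[c("A", "B", "C", "D", "E", "F")]),
               c(101, 61, 96, 81, 51, 24),
               ignore_attr = TRUE)
  sim2 <- simulate_founder_panels(cfg)
  expect_identical(sim$genotypes$dosage, sim2$genotypes$dosage)
  expect_identical(sim$panel_freqs, sim2$panel_freqs)
})

test_that("realized between-cluster Fst tracks the configured differentiation", {
  # no-differentiation limit
  cfg0 <- sim_panel_config(n_markers = 1500, scale = 0.1,
                           fst_between_cluster = 1e-9,
                           fst_within_cluster = 0, seed = 3)
  sim0 <- simulate_founder_panels(cfg0)
  cl <- sim0$clusters
  f0 <- hudson_fst(sim0$genotypes, names(cl)[cl == "I"],
                   names(cl)[cl == "II"])
  expect_lt(abs(f0), 0.01)
  # configured Fst of 0.3 is realized within +-0.05
  cfg <- sim_panel_config(n_markers = 2000, scale = 0.1,
                          fst_between_cluster = 0.3,
                          fst_within_cluster = 0.02, seed = 5)
  sim <- simulate_founder_panels(cfg)
  cl <- sim$clusters
  f <- hudson_fst(sim$genotypes, names(cl)[cl == "I"], names(cl)[cl == "II"])
  expect_lt(abs(f - 0.3), 0.05)
})

test_that("config invariants are enforced", {
  expect_error(sim_panel_config(fst_within_cluster = 0.4,
                                fst_between_cluster = 0.3))
  expect_error(ril_config(final_generation = 1))
  expect_error(trait_architecture(effect_correlation = -1.5))
  # full-scale default sizes sum to the published panel total
  expect_equal(sum(sim_panel_config(scale = 1)$panel_sizes), 4141)
})

test_that("RILs are fixed where parents share an allele and dosages stay valid", {
  map <- make_marker_map(60, 4, 40)
  p1 <- rep(c(0, 2, 2), each = 20)
  p2 <- rep(c(0, 0, 2), each = 20)
  rils <- simulate_biparental_rils(p1, p2, map, ril_config(40, 6, seed = 9))
  expect_true(all(rils$dosage %in% c(0, 1, 2)))
  shared0 <- which(p1 == 0 & p2 == 0)
  shared2 <- which(p1 == 2 & p2 == 2)
  expect_true(all(rils$dosage[, shared0] == 0))
  expect_true(all(rils$dosage[, shared2] == 2))
  expect_error(simulate_biparental_rils(rep(1, 60), p2, map, ril_config(5)),
               "homozygous")
})

test_that("residual heterozygosity halves per selfing generation", {
  map <- make_marker_map(4, 2, 40)
  for (fg in c(4, 6)) {
    r <- simulate_biparental_rils(rep(0, 4), rep(2, 4), map,
                                  ril_config(6000, fg, seed = 2))
    het <- mean(r$dosage == 1)
    expected <- 0.5^(fg - 1)
    se <- sqrt(expected * (1 - expected) / (6000 * 4))
    expect_lt(abs(het - expected), 4 * se)
  }
})

test_that("two-locus segregation matches the selfing Markov-chain oracle", {
  # two adjacent markers 1 cM apart on one chromosome
  map <- data.frame(marker = c("mA", "mB"), chrom = "chr01",
                    pos = c(10, 11))
  n <- 4000
  rils <- simulate_biparental_rils(c(0, 0), c(2, 2), map,
                                   ril_config(n, 6, seed = 31))
  c_rec <- haldane_oracle(1)
  p_expect <- recombinant_homozygote_prob(c_rec, 5)
  recomb <- mean((rils$dosage[, 1] == 0 & rils$dosage[, 2] == 2) |
                   (rils$dosage[, 1] == 2 & rils$dosage[, 2] == 0))
  se <- sqrt(p_expect * (1 - p_expect) / n)
  expect_lt(abs(recomb - p_expect), 4 * se)
  # the F-infinity closed form 2c/(1+2c) is approached from below
  expect_lt(p_expect, 2 * c_rec / (1 + 2 * c_rec))
  expect_gt(p_expect, 0.8 * 2 * c_rec / (1 + 2 * c_rec))
})

test_that("QTL effect pairs honour the architecture", {
  g <- simulate_founder_panels(sim_panel_config(n_markers = 500, scale = 0.05,
                                                seed = 1))$genotypes
  # degenerate correlation: trait 2 is an exact negative multiple
  eff1 <- assign_qtl_effects(g, trait_architecture(n_qtl = 50,
                                                   effect_correlation = -1),
                             seed = 2)
  qtl <- attr(eff1, "qtl")
  expect_equal(eff1[qtl, "protein"], -eff1[qtl, "oil"], tolerance = 1e-10)
  # sampled correlation close to the target
  eff2 <- assign_qtl_effects(g, trait_architecture(n_qtl = 200,
                                                   effect_correlation = -0.7),
                             seed = 3)
  qtl2 <- attr(eff2, "qtl")
  expect_lt(abs(cor(eff2[qtl2, 1], eff2[qtl2, 2]) + 0.7), 0.15)
  # non-QTL rows are exactly zero; boundary n_qtl = n_markers has none
  expect_true(all(eff2[setdiff(rownames(eff2), qtl2), ] == 0))
  eff3 <- assign_qtl_effects(g, trait_architecture(n_qtl = 500), seed = 4)
  expect_true(all(rowSums(abs(eff3)) > 0))
})

test_that("phenotypes reduce to the deterministic model when noise-free", {
  g <- simulate_founder_panels(sim_panel_config(n_markers = 300, scale = 0.02,
                                                seed = 7))$genotypes
  arch <- trait_architecture(n_qtl = 100, target_h2 = 1,
                             gxe_variance_ratio = 0)
  eff <- assign_qtl_effects(g, arch, seed = 8)
  ph <- simulate_phenotypes(g, eff, arch, seed = 9)
  truth <- attr(ph, "truth")
  d <- ph[ph$trait == "oil", ]
  # within each line and environment, replicates differ only through the
  # replicate effect; removing line value, mean and env effect leaves a
  # residual that is identical across lines (rep-within-env effect)
  gv <- truth$genetic_values[, "oil"]
  d$resid <- d$value - truth$components$oil$mu - gv[match(d$line, rownames(truth$genetic_values))]
  spread <- tapply(d$resid, interaction(d$env, d$rep), function(x)
    max(x) - min(x))
  expect_lt(max(spread), 1e-9)
})

test_that("the two traits are negatively correlated in every simulated study", {
  for (s in 1:5) {
    st <- bp_study(s, n_markers = 300, scale = 0.04, n_lines = 120)
    expect_lt(trait_correlation(st$pheno$oil, st$pheno$protein), 0)
  }
})

test_that("missing-data injection is calibrated, recorded and reversible", {
  g <- simulate_founder_panels(sim_panel_config(n_markers = 1000, scale = 0.05,
                                                seed = 13))$genotypes
  expect_identical(inject_missing(g, 0, seed = 1)$dosage, g$dosage)
  gm <- inject_missing(g, 0.05, seed = 1)
  n_cells <- length(g$dosage)
  frac <- mean(is.na(gm$dosage))
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n_cells))
  expect_identical(is.na(gm$dosage), unname(gm$missing_mask) | is.na(g$dosage))
  # imputation touches only masked cells
  gi <- impute_missing(gm, "marker_mean")
  expect_equal(gi$dosage[!gm$missing_mask], g$dosage[!gm$missing_mask])
  expect_error(inject_missing(g, 1))
})
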