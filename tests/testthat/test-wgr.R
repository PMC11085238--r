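make_instance <- function(seed, n, m, h2 = 0.5, sparse_qtl = NULL) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  dos <- matrix(rbinom(n * m, 2, rep(p, each = n)), n,
                dimnames = list(sprintf("s%04d", seq_len(n)),
                                sprintf("m%04d", seq_len(m))))
  g <- genotype_matrix(dos)
  beta <- if (is.null(sparse_qtl)) rnorm(m) else {
    b <- rep(0, m); b[sparse_qtl] <- rnorm(length(sparse_qtl), 0, 3); b
  }
  gv <- drop(scale(dos %*% beta))
  y <- gv + rnorm(n, 0, sqrt(1 / h2 - 1))
  names(y) <- rownames(dos)
  list(g = g, y = y, beta = beta, gv = gv)
}

test_that("the GRM matches the hand-computed VanRaden example and its symmetries", {
  dos <- rbind(s1 = c(0, 2), s2 = c(2, 0))
  colnames(dos) <- c("m1", "m2")
  G <- compute_grm(genotype_matrix(dos))
  expect_equal(unclass(G)[, ], rbind(s1 = c(s1 = 2, s2 = -2),
                                     s2 = c(s1 = -2, s2 = 2)))
  expect_equal(attr(G, "scale_c"), 1)
  # duplicated individual: identical rows, off-diagonal equals diagonal
  dos2 <- rbind(dos, s3 = dos["s1", ])
  rownames(dos2)[3] <- "s3"
  G2 <- compute_grm(genotype_matrix(dos2))
  expect_equal(G2["s1", ], G2["s3", ])
  expect_equal(G2["s1", "s3"], G2["s1", "s1"])
  # invariance to marker order
  inst <- make_instance(1, 30, 50)
  G3 <- compute_grm(inst$g)
  perm <- sample(50)
  G4 <- compute_grm(inst$g[, perm])
  expect_equal(unclass(G3)[, ], unclass(G4)[, ], tolerance = 1e-12)
  # PSD up to tolerance and near-unit mean diagonal under HWE
  ev <- eigen(unclass(G3), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
  expect_lt(abs(mean(diag(unclass(G3))) - 1), 0.15)
})

test_that("REML G-BLUP handles the null case and recovers heritability", {
  inst <- make_instance(2, 40, 60)
  y0 <- setNames(rep(1, 40), names(inst$y))
  G <- compute_grm(inst$g)
  f0 <- reml_gblup(y0, G)
  expect_equal(unname(f0$sigma2_g), 0)
  expect_lt(max(abs(f0$gebv - f0$gebv[1])), 1e-10)
  # parameter recovery: narrow-sense h2 = 0.5, n = 500
  h2_hat <- vapply(1:20, function(s) {
    inst <- make_instance(100 + s, 500, 400, h2 = 0.5)
    fit <- reml_gblup(inst$y, compute_grm(inst$g))
    fit$h2
  }, numeric(1))
  expect_lt(abs(mean(h2_hat) - 0.5), 0.1)
})

test_that("RR-BLUP and G-BLUP are the same model on matched kernels", {
  inst <- make_instance(42, 50, 300, h2 = 0.6)
  train <- names(inst$y)[1:40]
  G <- compute_grm(inst$g)
  Z <- center_dosage(inst$g)
  f1 <- reml_gblup(inst$y[train], G)
  f2 <- rrblup(inst$y[train], Z)
  expect_lt(max(abs(f1$gebv - f2$gebv)), 1e-6)         # held-in and held-out
  expect_equal(f1$sigma2_g, attr(G, "scale_c") * f2$sigma2_beta,
               tolerance = 1e-4)
  expect_equal(f1$mu, f2$mu, tolerance = 1e-8)
})

test_that("RR-BLUP recovers signal in rank-1 and polygenic settings", {
  # single marker, y proportional to dosage: GEBVs perfectly correlated
  dos <- cbind(m1 = c(0, 1, 2, 0, 2, 1, 0, 2))
  rownames(dos) <- sprintf("s%d", 1:8)
  g <- genotype_matrix(dos)
  y <- setNames(2 * dos[, 1] + 3, rownames(dos))
  fit <- rrblup(y, center_dosage(g))
  expect_equal(cor(fit$gebv, y), 1, tolerance = 1e-8)
  # polygenic effects: effect estimates correlate with truth
  inst <- make_instance(7, 300, 1000, h2 = 0.8)
  fit2 <- rrblup(inst$y, center_dosage(inst$g))
  expect_gt(cor(fit2$beta, inst$beta), 0.4)
})

test_that("adding a constant to phenotypes shifts only the intercept", {
  inst <- make_instance(9, 60, 100)
  Z <- center_dosage(inst$g)
  f1 <- rrblup(inst$y, Z)
  f2 <- rrblup(inst$y + 100, Z)
  expect_equal(f2$mu, f1$mu + 100, tolerance = 1e-6)
  expect_equal(f1$gebv, f2$gebv, tolerance = 1e-6)
})

test_that("Gibbs BRR with frozen variances matches the closed-form ridge solution", {
  set.seed(7)
  n <- 100; m <- 200
  Z <- matrix(rnorm(n * m), n, dimnames = list(sprintf("t%03d", 1:n),
                                               sprintf("q%03d", 1:m)))
  bt <- rnorm(m, 0, sqrt(0.5 / m))
  y <- drop(Z %*% bt) + rnorm(n, 0, sqrt(0.5))
  names(y) <- rownames(Z)
  s2b <- 0.5 / m; s2e <- 0.5
  fit <- gibbs_brr(y, Z, mcmc_config(2000, 500, seed = 3),
                   hyper = list(fix_var = TRUE, sigma2_beta = s2b,
                                sigma2_e = s2e))
  oracle <- ridge_oracle(Z, y, s2e / s2b)
  expect_gte(cor(fit$beta, oracle), 0.999)
})

test_that("Gibbs BRR shrinks null signals and reproduces across seeds", {
  set.seed(15)
  n <- 80; m <- 150
  Z <- matrix(rnorm(n * m), n, dimnames = list(sprintf("a%03d", 1:n),
                                               sprintf("b%03d", 1:m)))
  y <- setNames(rnorm(n), rownames(Z))
  fit <- gibbs_brr(y, Z, mcmc_config(1500, 300, seed = 1))
  expect_lt(mean(abs(fit$beta)), 3 * sd(fit$beta) + 0.02)
  # chain reproducibility: same seed identical, different seeds consistent
  inst <- make_instance(16, 200, 500, h2 = 0.7)
  Zi <- center_dosage(inst$g)
  fa <- gibbs_brr(inst$y, Zi, mcmc_config(2000, 500, seed = 5))
  fb <- gibbs_brr(inst$y, Zi, mcmc_config(2000, 500, seed = 5))
  expect_identical(fa$beta, fb$beta)
  fc <- gibbs_brr(inst$y, Zi, mcmc_config(2000, 500, seed = 6))
  expect_gte(cor(fa$gebv, fc$gebv), 0.99)
})

test_that("Bayesian LASSO limits behave as penalised regression", {
  set.seed(23)
  n <- 100; m <- 20
  Z <- matrix(rnorm(n * m), n, dimnames = list(sprintf("s%03d", 1:n),
                                               sprintf("m%03d", 1:m)))
  beta <- rnorm(m)
  y <- setNames(drop(Z %*% beta) + rnorm(n), rownames(Z))
  # infinite penalty collapses the effects
  f_inf <- gibbs_bl(y, Z, mcmc_config(1200, 300, seed = 2),
                    hyper = list(fix_lambda2 = 1e8))
  expect_lt(mean(abs(f_inf$beta)), 0.05)
  # vanishing penalty with frozen residual variance approaches OLS
  f_ols <- gibbs_bl(y, Z, mcmc_config(2000, 500, seed = 3),
                    hyper = list(fix_lambda2 = 1e-4, fix_sigma2_e = 1))
  ols <- qr.solve(cbind(1, Z), y)[-1]
  expect_gt(cor(f_ols$beta, ols), 0.999)
  expect_lt(max(abs(f_ols$beta - ols)), 0.1)
})

test_that("Bayesian LASSO concentrates effects on sparse causal markers", {
  hits <- vapply(1:10, function(s) {
    inst <- make_instance(200 + s, 150, 500, h2 = 0.6, sparse_qtl = 1:10)
    fit <- gibbs_bl(inst$y, center_dosage(inst$g),
                    mcmc_config(1200, 300, seed = s))
    qtl_ids <- colnames(inst$g$dosage)[1:10]
    mean(abs(fit$beta[qtl_ids])) >
      mean(abs(fit$beta[setdiff(names(fit$beta), qtl_ids)]))
  }, logical(1))
  expect_true(all(hits))
})

test_that("BayesB nests ridge at full inclusion and ranks causal markers by inclusion", {
  set.seed(21)
  n <- 200; m <- 300
  Z <- matrix(rnorm(n * m), n, dimnames = list(sprintf("s%03d", 1:n),
                                               sprintf("m%03d", 1:m)))
  b <- rnorm(m, 0, sqrt(2 / m))
  y <- setNames(drop(Z %*% b) + rnorm(n), rownames(Z))
  f1 <- gibbs_bayesb(y, Z, mcmc_config(3000, 500, seed = 1),
                     hyper = list(pi_fix = 1, pi0 = 1))
  f2 <- gibbs_brr(y, Z, mcmc_config(3000, 500, seed = 2))
  expect_gte(cor(f1$gebv, f2$gebv), 0.98)
  # pure noise: posterior inclusion stays near the prior mean
  y0 <- setNames(rnorm(n), rownames(Z))
  f0 <- gibbs_bayesb(y0, Z, mcmc_config(1500, 300, seed = 3))
  expect_lt(abs(mean(f0$pip) - f0$pi), 0.1)
  # sparse truth: causal markers receive higher inclusion in every seed
  hits <- vapply(1:10, function(s) {
    inst <- make_instance(300 + s, 150, 500, h2 = 0.6, sparse_qtl = 1:10)
    fit <- gibbs_bayesb(inst$y, center_dosage(inst$g),
                        mcmc_config(1200, 300, seed = s))
    qtl_ids <- colnames(inst$g$dosage)[1:10]
    mean(fit$pip[qtl_ids]) > mean(fit$pip[setdiff(names(fit$pip), qtl_ids)])
  }, logical(1))
  expect_true(all(hits))
})

test_that("predictions are reproducible from the stored fit, including via JSON", {
  inst <- make_instance(33, 60, 120, h2 = 0.7)
  train <- names(inst$y)[1:45]
  held <- names(inst$y)[46:60]
  for (model in c("RRBLUP", "GBLUP")) {
    fit <- gs_fit(inst$g, inst$y[train], model = model)
    # predicting the training cohort reproduces stored GEBVs
    pred <- predict_gebv(fit, inst$g)
    expect_lt(max(abs(pred - fit$gebv[names(pred)])), 1e-10)
    # a duplicate of a training sample gets that sample's GEBV
    ddos <- inst$g$dosage[c(1, 1), , drop = FALSE]
    rownames(ddos) <- c("orig", "copy")
    dup <- genotype_matrix(ddos, chrom = inst$g$map$chrom,
                           pos = inst$g$map$pos)
    pd <- predict_gebv(fit, dup)
    expect_equal(pd[["orig"]], pd[["copy"]])
    # JSON round trip preserves predictions bit-for-bit
    path <- withr::local_tempfile(fileext = ".json")
    write_model_fit(fit, path)
    fit2 <- read_model_fit(path)
    expect_equal(predict_gebv(fit2, inst$g), pred, tolerance = 1e-12)
  }
  # marker-effect and kernel paths agree on held-out samples
  f1 <- gs_fit(inst$g, inst$y[train], model = "GBLUP")
  f2 <- gs_fit(inst$g, inst$y[train], model = "RRBLUP")
  expect_lt(max(abs(f1$gebv[held] - f2$gebv[held])), 1e-6)
})
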