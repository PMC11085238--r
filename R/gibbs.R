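#' MCMC settings for the Bayesian whole-genome regressions
#'
#' Defaults follow common practice for these samplers: a single chain of
#' 10,000 iterations with the first 2,000 discarded as burn-in and no
#' thinning (every post-burn-in sample contributes to the posterior mean).
#'
#' @param n_iter total iterations.
#' @param burn_in discarded iterations (must be `< n_iter`).
#' @param thin keep every `thin`-th post-burn-in sample.
#' @param seed integer seed; the chain is deterministic given the seed.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(n_iter = 10000, burn_in = 2000, thin = 1, seed = 1L) {
  stopifnot(burn_in < n_iter, burn_in >= 0, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "mcmc_config")
}

# Shared prior bookkeeping: scaled-inverse-chi-square scales from the
# heuristic that half of the phenotypic variance is genetic (R2 = 0.5),
# with df0 = 5 — community defaults for these samplers.
.wgr_hyper <- function(y, Z, hyper) {
  h <- list(df0 = 5, R2 = 0.5)
  h[names(hyper)] <- hyper
  vy <- var(y)
  msx <- sum(apply(Z, 2, var))
  if (msx <= 0) msx <- sum(colMeans(Z^2))
  list(df0 = h$df0, R2 = h$R2, vy = vy, msx = msx,
       S0_e = vy * (1 - h$R2) * (h$df0 + 2),
       S0_b = vy * h$R2 / msx * (h$df0 + 2),
       extra = h)
}

.finish_gibbs <- function(res, model, Z, train, mcmc, extra = list()) {
  beta <- drop(res$beta)
  names(beta) <- colnames(Z)
  gebv <- drop(Z %*% beta)
  names(gebv) <- rownames(Z)
  structure(c(list(model = model, mu = res$mu, beta = beta, gebv = gebv,
                   sigma2_e = res$sigma2_e, freqs = attr(Z, "freqs"),
                   train_ids = train, mcmc = mcmc), extra),
            class = "wgr_fit")
}

#' Bayesian ridge regression by Gibbs sampling
#'
#' `y = 1 mu + Z beta + e` with a common normal prior
#' `beta_j ~ N(0, s2b)`. Both variances carry scaled-inverse-chi-square
#' priors (df 5, scales from the half-genetic-variance heuristic) and are
#' sampled from their full conditionals; posterior-mean effects and GEBVs
#' are returned.
#'
#' @param y named vector of training phenotypes.
#' @param Z centred dosage matrix from [center_dosage()] (rows may include
#'   samples to predict; only `names(y)` rows train the model).
#' @param mcmc an [mcmc_config()].
#' @param hyper optional overrides: `df0`, `R2`, or `fix_var = TRUE` with
#'   `sigma2_beta`/`sigma2_e` to freeze the variances (used to validate the
#'   sampler against the closed-form ridge solution).
#' @return A `wgr_fit` with posterior means.
#' @export
gibbs_brr <- function(y, Z, mcmc = mcmc_config(), hyper = list()) {
  train <- names(y)
  stopifnot(!is.null(train), all(train %in% rownames(Z)))
  hp <- .wgr_hyper(y, Z[train, , drop = FALSE], hyper)
  fix <- isTRUE(hp$extra$fix_var)
  set.seed(mcmc$seed)
  res <- gibbs_brr_cpp(unname(y), Z[train, , drop = FALSE],
                       mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                       hp$df0, hp$S0_b, hp$S0_e, fix,
                       hp$extra$sigma2_beta %||% 0,
                       hp$extra$sigma2_e %||% 0)
  .finish_gibbs(res, "BRR", Z, train, mcmc,
                list(sigma2_beta = res$sigma2_beta))
}

#' Bayesian LASSO by Gibbs sampling
#'
#' Park–Casella hierarchy: `beta_j ~ N(0, s2e tau2_j)`,
#' `tau2_j ~ Exp(lambda2 / 2)`, with an inverse-Gaussian full conditional
#' for `1/tau2_j` and a gamma full conditional for `lambda2` (prior shape
#' 1.1, rate set so the prior mode matches the half-genetic-variance
#' heuristic).
#'
#' @inheritParams gibbs_brr
#' @param hyper optional overrides: `df0`, `R2`, `shape0`, or
#'   `fix_lambda2 = <value>` / `fix_sigma2_e = <value>` to freeze the
#'   penalty or the residual variance (used in the infinite- and
#'   zero-penalty limit checks).
#' @return A `wgr_fit` with posterior means (`lambda2` included).
#' @export
gibbs_bl <- function(y, Z, mcmc = mcmc_config(), hyper = list()) {
  train <- names(y)
  stopifnot(!is.null(train), all(train %in% rownames(Z)))
  hp <- .wgr_hyper(y, Z[train, , drop = FALSE], hyper)
  shape0 <- hp$extra$shape0 %||% 1.1
  lambda2_0 <- 2 * (1 - hp$R2) / hp$R2 * hp$msx
  rate0 <- (shape0 - 1) / lambda2_0
  fix_lambda <- !is.null(hp$extra$fix_lambda2)
  fix_s2e <- !is.null(hp$extra$fix_sigma2_e)
  set.seed(mcmc$seed)
  res <- gibbs_bl_cpp(unname(y), Z[train, , drop = FALSE],
                      mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                      hp$df0, hp$S0_e, shape0, rate0,
                      hp$extra$fix_lambda2 %||% lambda2_0,
                      fix_lambda, fix_s2e, hp$extra$fix_sigma2_e %||% 0)
  .finish_gibbs(res, "BL", Z, train, mcmc, list(lambda2 = res$lambda2))
}

#' BayesB by Gibbs sampling
#'
#' Spike-and-slab prior `beta_j = delta_j alpha_j`,
#' `delta_j ~ Bernoulli(pi)`, with a marker-specific slab variance
#' (scaled-inverse-chi-square, df 5, heuristic scale divided by the prior
#' inclusion probability) and `pi ~ Beta(2, 2)` (weakly informative, mean
#' 0.5). Inclusion indicator and effect are updated jointly per marker from
#' the marginal odds; posterior inclusion probabilities are returned along
#' with posterior-mean effects `E[delta alpha]`.
#'
#' @inheritParams gibbs_brr
#' @param hyper optional overrides: `df0`, `R2`, `pi0` (prior mean used in
#'   the slab scale), `pi_fix` to freeze the inclusion probability (e.g.
#'   `pi_fix = 1` reduces the model to marker-specific-variance ridge).
#' @return A `wgr_fit` with posterior means and `pip`.
#' @export
gibbs_bayesb <- function(y, Z, mcmc = mcmc_config(), hyper = list()) {
  train <- names(y)
  stopifnot(!is.null(train), all(train %in% rownames(Z)))
  hp <- .wgr_hyper(y, Z[train, , drop = FALSE], hyper)
  pi0 <- hp$extra$pi0 %||% 0.5
  S0_B <- hp$S0_b / pi0
  set.seed(mcmc$seed)
  res <- gibbs_bayesb_cpp(unname(y), Z[train, , drop = FALSE],
                          mcmc$n_iter, mcmc$burn_in, mcmc$thin,
                          hp$df0, S0_B, hp$S0_e, 2, 2,
                          hp$extra$pi_fix %||% -1)
  pip <- drop(res$pip)
  names(pip) <- colnames(Z)
  .finish_gibbs(res, "BayesB", Z, train, mcmc,
                list(pip = pip, pi = res$pi))
}
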