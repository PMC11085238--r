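#' Fit a whole-genome regression model and predict every sample
#'
#' Uniform front end used by the experiment designs: given one analysis
#' cohort (training and prediction samples together, merged, filtered and
#' imputed), centres the dosages at the cohort frequencies, trains the
#' requested model on the phenotyped samples and returns GEBVs for every
#' sample in the cohort. Using one joint centering (and one joint GRM for
#' G-BLUP) matches a pipeline in which a single combined marker set serves
#' both populations.
#'
#' @param geno a [genotype_matrix()] (no missing values) holding the
#'   analysis cohort.
#' @param y named vector of training phenotypes (BLUEs or line means);
#'   names must be a subset of the cohort's sample ids.
#' @param model one of `"GBLUP"`, `"RRBLUP"`, `"BRR"`, `"BL"`, `"BayesB"`.
#' @param mcmc an [mcmc_config()] for the Bayesian models.
#' @param freqs optional centering frequencies (defaults to the cohort's).
#' @param hyper hyper-parameter overrides passed to the Gibbs samplers.
#' @return A `wgr_fit` whose `$gebv` covers all samples of `geno`.
#' @export
gs_fit <- function(geno, y,
                   model = c("GBLUP", "RRBLUP", "BRR", "BL", "BayesB"),
                   mcmc = mcmc_config(), freqs = NULL, hyper = list()) {
  model <- match.arg(model)
  stopifnot(!is.null(names(y)), all(names(y) %in% sample_ids(geno)))
  if (model == "GBLUP") {
    G <- compute_grm(geno, freqs = freqs)
    fit <- reml_gblup(y, G)
    # stash training genotypes so predict_gebv() works on unseen cohorts
    Z <- center_dosage(geno, freqs = attr(G, "freqs"))
    fit$train_Z <- Z[fit$train_ids, , drop = FALSE]
    return(fit)
  }
  Z <- center_dosage(geno, freqs = freqs)
  switch(model,
         RRBLUP = rrblup(y, Z),
         BRR = gibbs_brr(y, Z, mcmc, hyper),
         BL = gibbs_bl(y, Z, mcmc, hyper),
         BayesB = gibbs_bayesb(y, Z, mcmc, hyper))
}
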