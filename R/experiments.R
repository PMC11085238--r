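#' Prediction ability
#'
#' Pearson correlation between observed values (or BLUEs) and GEBVs, the
#' standard accuracy statistic of genomic-selection studies. Vectors are
#' aligned by name when both are named; pairs with a missing observed value
#' are dropped with a message giving the count.
#'
#' @param observed observed phenotypes.
#' @param gebv predicted breeding values.
#' @return Pearson r in \[-1, 1\].
#' @export
prediction_ability <- function(observed, gebv) {
  if (!is.null(names(observed)) && !is.null(names(gebv))) {
    ids <- intersect(names(observed), names(gebv))
    observed <- observed[ids]; gebv <- gebv[ids]
  }
  stopifnot(length(observed) == length(gebv))
  drop_na <- is.na(observed)
  if (any(drop_na)) {
    message(sum(drop_na), " pair(s) with missing observed values dropped")
    observed <- observed[!drop_na]; gebv <- gebv[!drop_na]
  }
  if (length(observed) < 3) stop("need at least 3 aligned pairs")
  if (sd(observed) == 0 || sd(gebv) == 0) stop("zero variance")
  cor(observed, gebv)
}

.fold_assignment <- function(ids, k, seed) {
  n <- length(ids)
  stopifnot(k >= 2, n >= k)
  set.seed(seed)
  perm <- sample(ids)
  sizes <- rep(n %/% k, k)
  if (n %% k > 0) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1
  split(perm, rep(seq_len(k), sizes))
}

.pa_summary <- function(values) {
  data.frame(mean_pa = mean(values),
             se_pa = if (length(values) > 1) sd(values) / sqrt(length(values))
                     else 0,
             n = length(values))
}

#' k-fold cross-validated prediction ability within a population
#'
#' Randomly partitions the phenotyped samples into `k` near-equal disjoint
#' folds (a seeded permutation cut into contiguous blocks), fits the model
#' `k` times on the complement and computes the prediction ability per
#' held-out fold; the reported value is the fold average, as is standard for
#' within-population genomic prediction.
#'
#' @param geno analysis cohort, a [genotype_matrix()] without missing calls.
#' @param y named phenotype vector (the population to cross-validate).
#' @param model,mcmc,hyper passed to [gs_fit()].
#' @param k number of folds (default 10).
#' @param seed seed for the fold assignment.
#' @return A `prediction_result` list: `per_fold` data frame, `summary`
#'   (mean and SE over folds), and the design metadata.
#' @export
kfold_cv <- function(geno, y, model = "GBLUP", k = 10, seed = 1L,
                     mcmc = mcmc_config(), hyper = list()) {
  folds <- .fold_assignment(names(y), k, seed)
  if (any(lengths(folds) < 3)) stop("fold with fewer than 3 samples")
  cohort <- geno[match(names(y), sample_ids(geno)), ]
  per_fold <- do.call(rbind, lapply(seq_along(folds), function(i) {
    test <- folds[[i]]
    fit <- gs_fit(cohort, y[setdiff(names(y), test)], model = model,
                  mcmc = mcmc, hyper = hyper)
    data.frame(fold = i, n_test = length(test),
               pa = prediction_ability(y[test], fit$gebv[test]))
  }))
  structure(list(experiment = "kfold_cv", model = model, k = k, seed = seed,
                 folds = folds, per_fold = per_fold,
                 summary = .pa_summary(per_fold$pa)),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("%s [%s]: mean PA = %.3f (SE %.3f, n = %d)\n",
              x$experiment, x$model, x$summary$mean_pa, x$summary$se_pa,
              x$summary$n))
  invisible(x)
}

#' Across-population prediction
#'
#' Fits the model once on the full training set and predicts the entire
#' test population; one prediction ability is returned. Train and test must
#' be disjoint and already harmonised to a common marker set (merge then
#' filter).
#'
#' @param geno analysis cohort containing both populations.
#' @param y_train named training phenotypes.
#' @param test_ids sample ids of the test population.
#' @param y_test named observed values (or BLUEs) of the test population;
#'   omit to return GEBVs without a PA.
#' @param model,mcmc,hyper passed to [gs_fit()].
#' @return A `prediction_result` with the single PA, the test GEBVs and the
#'   fit.
#' @export
across_population <- function(geno, y_train, test_ids, y_test = NULL,
                              model = "GBLUP", mcmc = mcmc_config(),
                              hyper = list()) {
  if (length(intersect(names(y_train), test_ids)) > 0)
    stop("training and test populations overlap")
  stopifnot(all(test_ids %in% sample_ids(geno)))
  cohort_ids <- c(names(y_train), test_ids)
  cohort <- geno[match(cohort_ids, sample_ids(geno)), ]
  fit <- gs_fit(cohort, y_train, model = model, mcmc = mcmc, hyper = hyper)
  gebv <- fit$gebv[test_ids]
  pa <- if (!is.null(y_test)) prediction_ability(y_test, gebv) else NA_real_
  structure(list(experiment = "across_population", model = model,
                 n_train = length(y_train), n_test = length(test_ids),
                 gebv = gebv, fit = fit, pa = pa,
                 per_fold = data.frame(fold = 1, n_test = length(test_ids),
                                       pa = pa),
                 summary = .pa_summary(pa)),
            class = "prediction_result")
}

#' Training-set composition sweep
#'
#' Evaluates across-population prediction for each candidate panel singly
#' and for the nested unions along a supplied panel ordering (closest panel,
#' closest two, and so on) — the design used to ask which public panels,
#' alone or combined, best predict a breeding population.
#'
#' @param geno analysis cohort.
#' @param y named phenotypes of all candidate training samples.
#' @param panels named vector mapping training sample id to panel label.
#' @param panel_order panel labels ordered by increasing distance to the
#'   test population.
#' @param test_ids,y_test test population and its observed values.
#' @param model,mcmc,hyper passed to [gs_fit()].
#' @return Data frame with one row per training set (`training_set`,
#'   `n_train`, `pa`).
#' @export
tp_composition_sweep <- function(geno, y, panels, panel_order, test_ids,
                                 y_test, model = "GBLUP",
                                 mcmc = mcmc_config(), hyper = list()) {
  stopifnot(length(panel_order) >= 1, all(panel_order %in% panels))
  singles <- as.list(panel_order)
  prefixes <- lapply(seq_along(panel_order), function(i) panel_order[1:i])
  sets <- unique(c(singles, prefixes))
  do.call(rbind, lapply(sets, function(set) {
    ids <- names(panels)[panels %in% set]
    ids <- intersect(ids, names(y))
    if (length(ids) == 0) stop("empty training panel: ",
                               paste(set, collapse = ""))
    res <- across_population(geno, y[ids], test_ids, y_test, model = model,
                             mcmc = mcmc, hyper = hyper)
    data.frame(training_set = paste(set, collapse = ""),
               n_train = length(ids), pa = res$pa,
               stringsAsFactors = FALSE)
  }))
}

#' Training-set size sweep over distance-ranked candidates
#'
#' For each requested size `s`, trains on the `s` candidates closest to the
#' test population (a prefix of the ranking from [rank_by_distance()]), so
#' training sets are nested across sizes.
#'
#' @param geno analysis cohort.
#' @param y named phenotypes of the candidate pool.
#' @param ranked_ids candidate ids ordered by ascending distance to the
#'   test population.
#' @param sizes training-set sizes (ascending; all `<= length(ranked_ids)`).
#' @param test_ids,y_test test population and its observed values.
#' @param model,mcmc,hyper passed to [gs_fit()].
#' @return Data frame with one row per size (`size`, `pa`).
#' @export
tp_size_sweep <- function(geno, y, ranked_ids, sizes, test_ids, y_test,
                          model = "GBLUP", mcmc = mcmc_config(),
                          hyper = list()) {
  sizes <- sort(sizes)
  if (max(sizes) > length(ranked_ids))
    stop("size exceeds the candidate pool")
  do.call(rbind, lapply(sizes, function(s) {
    ids <- ranked_ids[seq_len(s)]
    res <- across_population(geno, y[ids], test_ids, y_test, model = model,
                             mcmc = mcmc, hyper = hyper)
    data.frame(size = s, pa = res$pa)
  }))
}

#' Marker-number sweep with random subsets
#'
#' For each marker-set size, draws `n_repeats` independent uniform random
#' marker subsets (without replacement), refits the model on each and
#' records the prediction ability; the full marker set is evaluated once
#' (its SE is 0). Mean and standard error (sample SD / sqrt(n_repeats)) per
#' size summarise the sweep.
#'
#' @param geno analysis cohort.
#' @param y_train,test_ids,y_test populations as in [across_population()].
#' @param sizes marker counts (use `ncol` of the cohort for the full set).
#' @param n_repeats random subsets per size (default 100).
#' @param seed seed for the subset draws.
#' @param model,mcmc,hyper passed to [gs_fit()].
#' @return List with `per_repeat` (size, repeat, pa) and `summary`
#'   (size, mean_pa, se_pa, n).
#' @export
marker_subset_sweep <- function(geno, y_train, test_ids, y_test, sizes,
                                n_repeats = 100, seed = 1L, model = "GBLUP",
                                mcmc = mcmc_config(), hyper = list()) {
  m <- ncol(geno$dosage)
  if (max(sizes) > m) stop("marker-set size exceeds the marker count")
  # draw every subset up front so model fitting cannot perturb the
  # subset sequence (the Bayesian samplers reseed the RNG)
  set.seed(seed)
  sizes <- sort(sizes)
  subsets <- lapply(sizes, function(s) {
    reps <- if (s == m) 1 else n_repeats
    lapply(seq_len(reps),
           function(i) if (s == m) seq_len(m) else sort(sample.int(m, s)))
  })
  per <- do.call(rbind, lapply(seq_along(sizes), function(si) {
    do.call(rbind, lapply(seq_along(subsets[[si]]), function(rep_i) {
      res <- across_population(geno[, subsets[[si]][[rep_i]]], y_train,
                               test_ids, y_test, model = model,
                               mcmc = mcmc, hyper = hyper)
      data.frame(size = sizes[si], rep = rep_i, pa = res$pa)
    }))
  }))
  summ <- do.call(rbind, lapply(split(per, per$size), function(d)
    data.frame(size = d$size[1], mean_pa = mean(d$pa),
               se_pa = if (nrow(d) > 1) sd(d$pa) / sqrt(nrow(d)) else 0,
               n = nrow(d))))
  rownames(summ) <- NULL
  list(per_repeat = per, summary = summ)
}
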