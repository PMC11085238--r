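#' Predict GEBVs for new genotypes from a fitted model
#'
#' Marker-effect models (RR-BLUP, BRR, BL, BayesB) predict
#' `GEBV = (dosage - 2 p_fit) beta_hat`, centring new samples with the
#' frequencies stored in the fit — never with the new cohort's own
#' frequencies, which would shift predictions. G-BLUP predicts through the
#' BLUP conditional expectation using the stored training weights:
#' `GEBV = G_new,train w` with `G_new,train = Z_new Z_train' / c`.
#'
#' @param fit a `wgr_fit`.
#' @param g_new a [genotype_matrix()] (imputed) whose markers include all of
#'   the fit's markers, in the same allele orientation as the training data.
#' @return Named GEBV vector (centred genetic values; add `fit$mu` for
#'   predictions on the trait scale).
#' @export
predict_gebv <- function(fit, g_new) {
  stopifnot(inherits(fit, "wgr_fit"))
  p <- fit$freqs
  if (is.null(p)) stop("fit carries no centering frequencies")
  missing <- setdiff(names(p), marker_ids(g_new))
  if (length(missing))
    stop(length(missing), " fit marker(s) absent from the new genotypes")
  Z <- sweep(g_new$dosage[, names(p), drop = FALSE], 2, 2 * p)
  if (fit$model == "GBLUP") {
    if (is.null(fit$train_Z))
      stop("this G-BLUP fit does not store training genotypes; ",
           "use gs_fit() or include the new samples in G")
    Gnt <- tcrossprod(Z, fit$train_Z) / fit$scale_c
    gebv <- drop(Gnt %*% fit$train_w)
  } else {
    gebv <- drop(Z %*% fit$beta[names(p)])
  }
  names(gebv) <- sample_ids(g_new)
  gebv
}

#' Serialize a model fit to JSON
#'
#' Stores everything needed to reproduce predictions bit-for-bit: model
#' name, intercept, marker effects (or training weights and genotypes for
#' G-BLUP), centering frequencies, variance estimates, and the MCMC
#' configuration and seed where applicable.
#'
#' @param fit a `wgr_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_fit <- function(fit, path) {
  obj <- unclass(fit)
  obj$mcmc <- if (!is.null(obj$mcmc)) unclass(obj$mcmc)
  # named numeric vectors must become objects, or jsonlite drops the names
  for (f in c("gebv", "beta", "freqs", "pip", "train_w"))
    if (!is.null(obj[[f]])) obj[[f]] <- as.list(obj[[f]])
  if (!is.null(obj$train_Z)) {
    obj$train_Z_values <- as.vector(obj$train_Z)
    obj$train_Z_rows <- rownames(obj$train_Z)
    obj$train_Z_cols <- colnames(obj$train_Z)
    obj$train_Z <- NULL
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_fit
#' @export
read_model_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("gebv", "beta", "freqs", "pip", "train_w"))
    if (!is.null(obj[[f]])) obj[[f]] <- unlist(obj[[f]])
  if (!is.null(obj$train_Z_values)) {
    obj$train_Z <- matrix(obj$train_Z_values,
                          nrow = length(obj$train_Z_rows),
                          dimnames = list(obj$train_Z_rows, obj$train_Z_cols))
    obj$train_Z_values <- obj$train_Z_rows <- obj$train_Z_cols <- NULL
  }
  if (!is.null(obj$mcmc)) class(obj$mcmc) <- "mcmc_config"
  structure(obj, class = "wgr_fit")
}
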