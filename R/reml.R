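# Exact REML for the single-kernel mixed model y = 1*mu + u + e,
# u ~ N(0, s2k * K), via a one-dimensional profile over delta = s2e / s2k
# on the eigenbasis of K (computed once). Returns everything needed for
# BLUP prediction of samples outside the training set.
.kernel_reml <- function(y, K, bounds = c(1e-8, 1e8)) {
  n <- length(y)
  if (n < 3) stop("need at least 3 training observations")
  if (var(y) < 1e-12) {
    # degenerate: no signal to partition; variance pinned at the boundary
    return(list(mu = mean(y), s2k = 0, s2e = 0, delta = Inf,
                w = rep(0, n), boundary = TRUE, loglik = NA_real_))
  }
  eig <- eigen(K, symmetric = TRUE)
  dmin <- min(eig$values)
  if (dmin < -1e-8 * max(abs(eig$values), 1))
    stop("kernel is not positive semi-definite")
  d <- pmax(eig$values, 0)
  U <- eig$vectors
  yt <- drop(crossprod(U, y))
  xt <- drop(crossprod(U, rep(1, n)))
  negll <- function(logdelta) {
    delta <- exp(logdelta)
    w <- 1 / (d + delta)
    xwx <- sum(xt^2 * w)
    mu <- sum(xt * yt * w) / xwx
    r <- yt - xt * mu
    s2 <- max(sum(r^2 * w) / (n - 1), 1e-300)
    0.5 * ((n - 1) * (log(s2) + 1) + sum(log(d + delta)) + log(xwx))
  }
  opt <- optimize(negll, log(bounds), tol = 1e-10)
  delta <- exp(opt$minimum)
  w0 <- 1 / (d + delta)
  xwx <- sum(xt^2 * w0)
  mu <- sum(xt * yt * w0) / xwx
  r <- yt - xt * mu
  s2k <- sum(r^2 * w0) / (n - 1)
  boundary <- opt$minimum < log(bounds[1]) + 1e-3 ||
    opt$minimum > log(bounds[2]) - 1e-3
  # w such that BLUP of any sample s is K[s, train] %*% w
  w <- drop(U %*% (r * w0))
  list(mu = mu, s2k = s2k, s2e = delta * s2k, delta = delta, w = w,
       boundary = boundary, loglik = -opt$objective)
}

#' G-BLUP by exact REML
#'
#' Fits `y = 1 mu + g + e`, `g ~ N(0, s2g G)`, by restricted maximum
#' likelihood: the restricted log-likelihood is profiled over the variance
#' ratio `delta = s2e / s2g` on the eigendecomposition of the training block
#' of `G` (computed once), and minimised by one-dimensional search. Breeding
#' values for every sample in `G` — including unphenotyped ones — follow by
#' the BLUP conditional expectation
#' `g_hat = s2g G[., train] V^{-1} (y - 1 mu)`.
#'
#' @param y named vector of training phenotypes (names must index rows of
#'   `G`); `n >= 10` recommended for a stable variance ratio.
#' @param G relationship matrix from [compute_grm()] (or any PSD kernel with
#'   sample dimnames) covering training and prediction samples.
#' @return A `wgr_fit` with model `"GBLUP"`: variance components, the
#'   heritability implied by them, GEBVs for all samples of `G`, and the
#'   stored training quantities needed by [predict_gebv()]. A fit at the
#'   variance-ratio boundary is flagged in `$boundary`.
#' @export
reml_gblup <- function(y, G) {
  train <- names(y)
  if (is.null(train) || !all(train %in% rownames(G)))
    stop("`y` must be named by samples present in G")
  fit <- .kernel_reml(y, G[train, train])
  gebv <- drop(G[, train, drop = FALSE] %*% fit$w)
  names(gebv) <- rownames(G)
  structure(list(model = "GBLUP", mu = fit$mu, gebv = gebv,
                 sigma2_g = fit$s2k, sigma2_e = fit$s2e,
                 h2 = if (fit$s2k + fit$s2e > 0)
                   fit$s2k / (fit$s2k + fit$s2e) else 0,
                 beta = NULL, freqs = attr(G, "freqs"),
                 scale_c = attr(G, "scale_c"),
                 train_ids = train, train_w = fit$w,
                 boundary = fit$boundary, loglik = fit$loglik),
            class = "wgr_fit")
}

#' RR-BLUP (ridge-regression BLUP) by exact REML
#'
#' Fits `y = 1 mu + Z beta + e` with `beta_j ~ N(0, s2b)` i.i.d. The
#' variance components are estimated by REML on the equivalent
#' individual-level kernel `Z Z'`, and marker effects recovered as
#' `beta_hat = s2b Z' V^{-1} (y - 1 mu)`. With `G = Z Z' / c` and
#' `s2g = c s2b` this model is algebraically identical to [reml_gblup()];
#' the two implementations share the same REML core, so their GEBVs agree
#' to numerical precision.
#'
#' @param y named vector of training phenotypes.
#' @param Z centred dosage matrix from [center_dosage()] covering at least
#'   the training samples (rows indexed by sample id).
#' @return A `wgr_fit` with model `"RRBLUP"`: marker effects (trait units
#'   per coded-allele copy), variance components, and GEBVs `Z beta_hat`
#'   for every row of `Z`.
#' @export
rrblup <- function(y, Z) {
  train <- names(y)
  if (is.null(train) || !all(train %in% rownames(Z)))
    stop("`y` must be named by rows of Z")
  Zt <- Z[train, , drop = FALSE]
  fit <- .kernel_reml(y, tcrossprod(Zt))
  beta <- drop(crossprod(Zt, fit$w))
  names(beta) <- colnames(Z)
  gebv <- drop(Z %*% beta)
  names(gebv) <- rownames(Z)
  structure(list(model = "RRBLUP", mu = fit$mu, gebv = gebv,
                 sigma2_beta = fit$s2k, sigma2_e = fit$s2e,
                 beta = beta, freqs = attr(Z, "freqs"),
                 train_ids = train, boundary = fit$boundary,
                 loglik = fit$loglik),
            class = "wgr_fit")
}

#' @export
print.wgr_fit <- function(x, ...) {
  cat(sprintf("wgr_fit: %s, %d training samples\n", x$model,
              length(x$train_ids)))
  if (!is.null(x$beta))
    cat(sprintf("  %d marker effects, mu = %.4g\n", length(x$beta), x$mu))
  if (!is.null(x$sigma2_g))
    cat(sprintf("  sigma2_g = %.4g, sigma2_e = %.4g (h2 = %.3f)\n",
                x$sigma2_g, x$sigma2_e, x$h2))
  invisible(x)
}
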