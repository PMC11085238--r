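#' Best linear unbiased estimates of line means across environments
#'
#' Fits the trial model `Y_ijk = mu + E_i + R_j(E_i) + G_k + e_ijk` per
#' trait with genotype as the effect of interest and environment and
#' replicate-within-environment as nuisance terms, and returns each line's
#' least-squares adjusted mean (the prediction for that line averaged over
#' every environment-by-replicate cell present in the data). For balanced
#' data this is identical to the mixed-model BLUE with random environment
#' terms; unbalanced data are handled by the same least-squares fit with a
#' warning. With a single environment and single replicate the estimate
#' reduces to the raw observation.
#'
#' @param pheno long-format data frame with columns `line`, `env`, `rep`,
#'   `trait`, `value` (replicate ids nested within environment).
#' @return Wide data frame, one row per line, one column per trait.
#' @export
compute_blues <- function(pheno) {
  .check_pheno(pheno)
  traits <- unique(pheno$trait)
  lines <- unique(pheno$line)
  out <- data.frame(line = lines, stringsAsFactors = FALSE)
  for (t in traits) {
    d <- pheno[pheno$trait == t, , drop = FALSE]
    counts <- table(d$line)
    if (any(!(lines %in% d$line)))
      stop("line(s) without records for trait ", t)
    d$line <- factor(d$line, levels = lines)
    d$env <- factor(d$env)
    d$rep <- factor(d$rep)
    cells <- table(d$env, d$rep, d$line)
    if (length(unique(as.vector(cells))) > 1)
      warning("unbalanced design for trait ", t,
              "; least-squares adjusted means returned")
    terms <- "line"
    if (nlevels(d$env) > 1) terms <- c(terms, "env")
    if (nlevels(d$rep) > 1) terms <- c(terms, "env:rep")
    fit <- lm(stats::reformulate(terms, response = "value"), data = d)
    grid <- unique(d[, c("env", "rep")])
    newdata <- merge(data.frame(line = factor(lines, levels = lines)), grid)
    pred <- predict(fit, newdata = newdata)
    out[[t]] <- as.vector(tapply(pred, newdata$line, mean)[lines])
  }
  rownames(out) <- NULL
  out
}

.check_pheno <- function(pheno) {
  need <- c("line", "env", "rep", "trait", "value")
  if (!all(need %in% names(pheno)))
    stop("phenotype table needs columns: ", paste(need, collapse = ", "))
  if (nrow(pheno) == 0) stop("phenotype table is empty")
  if (any(!is.finite(pheno$value))) stop("non-finite trait values")
  invisible(TRUE)
}

#' Two-way ANOVA variance components for a replicated trial
#'
#' Computes the sequential ANOVA of `value ~ env + env:rep + line +
#' env:line` for one trait and derives method-of-moments variance
#' components from the expected mean squares of the balanced design:
#' `s2e = MS_error`, `s2GE = (MS_GE - MS_error) / r`,
#' `s2G = (MS_G - MS_GE) / (r e)`. Negative component estimates are
#' truncated at zero with a warning. Unbalanced designs (unequal cell
#' counts) fall back to the same Type-I sums of squares with a warning.
#'
#' @param pheno long-format phenotype table (see [compute_blues()]).
#' @param trait trait name to analyse (defaults to the only trait present).
#' @return A `variance_components` object: mean squares, components, `e`,
#'   `r`, and broad-sense heritability computed by [broad_sense_h2()] (the
#'   component path, asserted equal to the mean-square shortcut
#'   `(MS_G - MS_GE) / MS_G` whenever no truncation occurred).
#' @export
anova_components <- function(pheno, trait = NULL) {
  .check_pheno(pheno)
  trait <- trait %||% unique(pheno$trait)
  if (length(trait) != 1)
    stop("specify `trait`: table contains ", paste(unique(pheno$trait), collapse = ", "))
  d <- pheno[pheno$trait == trait, , drop = FALSE]
  d$line <- factor(d$line); d$env <- factor(d$env); d$rep <- factor(d$rep)
  e <- nlevels(d$env); r <- nlevels(d$rep)
  if (e < 2 || r < 2)
    stop("ANOVA needs >= 2 environments and >= 2 replicates")
  cells <- table(d$env, d$rep, d$line)
  if (length(unique(as.vector(cells))) > 1)
    warning("unbalanced design; Type-I sums of squares used")
  fit <- lm(value ~ env + env:rep + line + env:line, data = d)
  tab <- anova(fit)
  ms <- tab[["Mean Sq"]]
  names(ms) <- rownames(tab)
  ms_E <- ms[["env"]]; ms_R <- ms[["env:rep"]]
  ms_G <- ms[["line"]]; ms_GE <- ms[["env:line"]]
  ms_err <- ms[["Residuals"]]
  s2e <- ms_err
  s2GE <- (ms_GE - ms_err) / r
  s2G <- (ms_G - ms_GE) / (r * e)
  truncated <- s2GE < 0 || s2G < 0
  if (truncated) {
    warning("negative variance component estimate truncated at zero")
    s2GE <- max(s2GE, 0); s2G <- max(s2G, 0)
  }
  vc <- variance_components(sigma2_G = s2G, sigma2_GE = s2GE, sigma2_e = s2e,
                            e = e, r = r,
                            ms = c(G = ms_G, GE = ms_GE, E = ms_E,
                                   rep_in_E = ms_R, error = ms_err))
  if (!truncated) {
    h2_ms <- h2_from_mean_squares(ms_G, ms_GE)
    stopifnot(abs(vc$h2 - h2_ms) < 1e-12)
  }
  vc
}

#' Variance components container
#'
#' @param sigma2_G,sigma2_GE,sigma2_e genetic, genotype-by-environment and
#'   residual variance components (non-negative).
#' @param e,r environment and replicate counts of the design.
#' @param ms optional named vector of the ANOVA mean squares the components
#'   derive from.
#' @return A `variance_components` list including the broad-sense
#'   heritability `h2`.
#' @export
variance_components <- function(sigma2_G, sigma2_GE, sigma2_e, e, r,
                                ms = NULL) {
  stopifnot(sigma2_G >= 0, sigma2_GE >= 0, sigma2_e >= 0, e >= 1, r >= 1)
  vc <- structure(list(sigma2_G = sigma2_G, sigma2_GE = sigma2_GE,
                       sigma2_e = sigma2_e, e = e, r = r, ms = ms),
                  class = "variance_components")
  vc$h2 <- broad_sense_h2(vc)
  vc
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance components (e = %d, r = %d):\n", x$e, x$r))
  cat(sprintf("  sigma2_G = %.4g, sigma2_GE = %.4g, sigma2_e = %.4g\n",
              x$sigma2_G, x$sigma2_GE, x$sigma2_e))
  cat(sprintf("  broad-sense h2 = %.4f\n", x$h2))
  invisible(x)
}

#' Broad-sense heritability on the line-mean basis
#'
#' `h2 = s2G / (s2G + s2GE/e + s2e/(r e))`. When the components come from
#' balanced-ANOVA mean squares this reduces algebraically to
#' `(MS_G - MS_GE) / MS_G`, independent of `e` and `r`; the shortcut is
#' available as [h2_from_mean_squares()] and the two paths agree to
#' numerical precision whenever no truncation was applied.
#'
#' @param vc a [variance_components()] object.
#' @return Heritability in \[0, 1\].
#' @export
broad_sense_h2 <- function(vc) {
  den <- vc$sigma2_G + vc$sigma2_GE / vc$e + vc$sigma2_e / (vc$r * vc$e)
  if (den <= 0) stop("zero denominator: all variance components are zero")
  h2 <- vc$sigma2_G / den
  stopifnot(h2 >= 0, h2 <= 1)
  h2
}

#' @rdname broad_sense_h2
#' @param ms_G,ms_GE genotype and genotype-by-environment mean squares.
#' @export
h2_from_mean_squares <- function(ms_G, ms_GE) {
  stopifnot(ms_G > 0)
  max((ms_G - ms_GE) / ms_G, 0)
}

#' Descriptive statistics for one trait in one population
#'
#' Moment-based summary as reported for germplasm phenotype tables: min,
#' max, mean, SD (n-1 denominator), coefficient of variation, and
#' moment-estimator skewness and excess kurtosis.
#'
#' @param x numeric vector, `n >= 2`.
#' @return One-row data frame.
#' @export
descriptive_stats <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need at least 2 finite values")
  s <- sd(x)
  data.frame(n = length(x), min = min(x), max = max(x), mean = mean(x),
             sd = s, cv = s / mean(x),
             skewness = if (s == 0) 0 else e1071::skewness(x, type = 1),
             kurtosis = if (s == 0) 0 else e1071::kurtosis(x, type = 1))
}

#' Pearson correlation between two traits
#'
#' @param x,y aligned numeric vectors of length >= 3 with nonzero variance.
#' @return Pearson product-moment correlation.
#' @export
trait_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  cor(x, y)
}
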