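#' Theoretically expected out-of-sample predictive power
#'
#' `R2 = h2^2 / (h2 + M/N)`: the expected fraction of phenotypic variance
#' explained by a PGI trained on a GWAS of size `N` for a phenotype with
#' SNP heritability `h2`, with `M` effective independent SNPs.
#'
#' @param h2 SNP heritability in (0, 1].
#' @param n GWAS (equivalent) sample size.
#' @param m effective number of independent SNPs (default 60,000).
#' @return Expected R2.
#' @export
expected_r2 <- function(h2, n, m = 60000) {
  if (any(h2 <= 0 | h2 > 1)) stop("h2 must be in (0, 1]")
  stopifnot(all(n > 0), all(m > 0))
  h2^2 / (h2 + m / n)
}

#' Per-SNP effective sample size
#'
#' `Neff = 1 / (2 SE^2 MAF (1 - MAF))`.
#'
#' @param se per-SNP standard error (> 0).
#' @param maf minor allele frequency in (0, 1).
#' @return Effective sample size.
#' @export
effective_n <- function(se, maf) {
  if (any(se <= 0)) stop("se must be positive")
  if (any(maf <= 0 | maf >= 1)) stop("maf must be in (0, 1)")
  1 / (2 * se^2 * maf * (1 - maf))
}

#' Filter summary statistics by effective sample size
#'
#' Removes SNPs whose effective sample size falls strictly below 0.8 times
#' the median effective sample size; SNPs exactly at the boundary are
#' retained.
#'
#' @param sumstats a `summary_stats` data frame with `se` and `maf`.
#' @param threshold multiplier on the median (default 0.8).
#' @return Filtered `summary_stats` with attribute `n_removed`.
#' @export
filter_by_neff <- function(sumstats, threshold = 0.8) {
  stopifnot(nrow(sumstats) >= 1)
  maf_minor <- pmin(sumstats$maf, 1 - sumstats$maf)
  neff <- effective_n(sumstats$se, maf_minor)
  cut <- threshold * stats::median(neff)
  keep <- !(neff < cut)
  out <- sumstats[keep, , drop = FALSE]
  if (!nrow(out)) stop("no SNPs survive the effective-sample-size filter")
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Errors-in-variables attenuation parameter rho
#'
#' `rho = sqrt(h2 / R2) >= 1` quantifies attenuation from finite GWAS
#' sampling error; it asymptotes to 1 as the GWAS grows. The delta-method
#' SE treats R2 as a known constant and propagates only the heritability
#' SE: `SE(rho) = SE(h2) / (2 rho R2)`. Set `propagate_r2 = TRUE` to
#' propagate SE(h2) through R2 as well (R2 itself a function of h2).
#'
#' @param h2 associational SNP heritability.
#' @param r2 predictive R2 of the PGI (0 < r2 <= h2).
#' @param se_h2 standard error of h2 (optional).
#' @param n,m GWAS size and SNP count, only used when `propagate_r2 = TRUE`.
#' @param propagate_r2 logical; full propagation through the expected-R2
#'   formula.
#' @return list(`rho`, `se`).
#' @export
attenuation_rho <- function(h2, r2, se_h2 = NULL, n = NULL, m = 60000,
                            propagate_r2 = FALSE) {
  if (any(r2 <= 0) || any(r2 > h2)) stop("r2 must be in (0, h2]")
  rho <- sqrt(h2 / r2)
  se <- NULL
  if (!is.null(se_h2)) {
    if (propagate_r2) {
      if (is.null(n)) stop("n required for full propagation")
      # numeric gradient of sqrt(h2 / R2(h2)) in h2
      g <- vapply(seq_along(h2), function(i) {
        f <- function(h) sqrt(h / expected_r2(h, n[i] %||% n, m))
        (f(h2[i] + 1e-6) - f(h2[i] - 1e-6)) / 2e-6
      }, numeric(1))
      se <- abs(g) * se_h2
    } else {
      se <- se_h2 / (2 * rho * r2)
    }
  }
  list(rho = rho, se = se)
}

#' Proportional bias factor of family-based PGI coefficients
#'
#' `factor = Corr(x gamma, x mu) / rho`, the combined attenuation of the
#' main-effect and interaction coefficients in a family-based PGI
#' regression relative to those from a noiseless causal-factor PGI. The SE
#' assumes the correlation and rho estimates are independent:
#' `sqrt(SE(corr)^2 / rho^2 + corr^2 SE(rho)^2 / rho^4)`.
#'
#' @param corr correlation between causal and associational additive SNP
#'   factors, in (0, 1].
#' @param se_corr its standard error.
#' @param rho attenuation parameter (>= 1 in theory).
#' @param se_rho its standard error.
#' @return list(`factor`, `se`).
#' @export
bias_factor <- function(corr, se_corr = NULL, rho, se_rho = NULL) {
  if (any(corr <= 0)) stop("corr must be positive")
  f <- corr / rho
  se <- if (!is.null(se_corr) && !is.null(se_rho)) {
    sqrt(se_corr^2 / rho^2 + corr^2 * se_rho^2 / rho^4)
  } else NULL
  list(factor = f, se = se)
}

#' Correct attenuated coefficients (and their SEs)
#'
#' Divides an estimate by the proportional bias factor; the SE is divided
#' by the same factor, since the sampling error of the attenuated estimate
#' shrinks by the same proportion as the coefficient.
#'
#' @param beta_hat attenuated estimate.
#' @param se its standard error.
#' @param factor proportional bias factor in (0, 1].
#' @return list(`estimate`, `se`).
#' @export
correct_coefficients <- function(beta_hat, se = NULL, factor) {
  if (any(factor <= 0) || any(factor > 1)) stop("factor must be in (0, 1]")
  list(estimate = beta_hat / factor,
       se = if (!is.null(se)) se / factor else NULL)
}

round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Proportional-bias report for a set of phenotypes
#'
#' For each input row (`phenotype`, `n`, `h2`, `se_h2`, `corr`, `se_corr`)
#' computes the expected R2, the attenuation parameter rho with its
#' delta-method SE, and the proportional bias factor Corr/rho with its SE.
#' By default each derived column is rounded (half-up, `digits` decimals)
#' before feeding the next stage, which reproduces published summary
#' tables that chain display-precision values; `chain_rounded = FALSE`
#' carries full precision throughout.
#'
#' @param rows data frame of inputs; see [repository_bias_inputs()] for the
#'   bundled worked example.
#' @param m effective number of independent SNPs.
#' @param digits display precision.
#' @param chain_rounded chain display-precision values (default TRUE).
#' @return An `attenuation_report` data frame with columns `phenotype`,
#'   `n`, `h2`, `se_h2`, `r2`, `rho`, `se_rho`, `corr`, `se_corr`,
#'   `bias_factor`, `se_bias_factor`.
#' @export
attenuation_report <- function(rows, m = 60000, digits = 3,
                               chain_rounded = TRUE) {
  need <- c("phenotype", "n", "h2", "se_h2", "corr", "se_corr")
  stopifnot(all(need %in% names(rows)))
  rnd <- if (chain_rounded) function(x) round_half_up(x, digits) else identity
  r2 <- rnd(expected_r2(rows$h2, rows$n, m))
  rh <- attenuation_rho(rows$h2, r2, rows$se_h2)
  rho <- rnd(rh$rho); se_rho <- rnd(rh$se)
  bf <- bias_factor(rows$corr, rows$se_corr, rho, se_rho)
  out <- data.frame(
    phenotype = rows$phenotype, n = rows$n, h2 = rows$h2, se_h2 = rows$se_h2,
    r2 = r2, rho = rho, se_rho = se_rho,
    corr = rows$corr, se_corr = rows$se_corr,
    bias_factor = rnd(bf$factor), se_bias_factor = rnd(bf$se),
    stringsAsFactors = FALSE
  )
  class(out) <- c("attenuation_report", "data.frame")
  out
}

#' Published inputs for the proportional-bias worked example
#'
#' The eight repository phenotypes with their GWAS-equivalent sample
#' sizes, SNP heritabilities (LDSC), and estimated correlations between
#' the causal and associational additive SNP factors, as published for the
#' Polygenic Index Repository. These are the inputs from which
#' [attenuation_report()] reproduces the published expected R2, rho, and
#' Corr/rho columns.
#'
#' @return Input data frame for [attenuation_report()].
#' @export
repository_bias_inputs <- function() {
  data.frame(
    phenotype = c("Educational Attainment", "Ever-smoker", "Height", "BMI",
                  "Age at first birth (women)", "Cognitive performance",
                  "Non-HDL cholesterol", "Asthma"),
    n = c(2155939, 1150055, 3839667, 582457, 181585, 222914, 926571, 353336),
    h2 = c(0.133, 0.085, 0.231, 0.247, 0.169, 0.232, 0.102, 0.135),
    se_h2 = c(0.003, 0.006, 0.011, 0.009, 0.007, 0.008, 0.018, 0.011),
    corr = c(0.859, 0.974, 0.970, 1.000, 0.881, 0.975, 0.959, 0.963),
    se_corr = c(0.028, 0.019, 0.005, 0.008, 0.067, 0.045, 0.030, 0.035),
    stringsAsFactors = FALSE
  )
}
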