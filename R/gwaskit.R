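#' Run a single-variant population GWAS
#'
#' Per-SNP ordinary least squares of the (covariate-residualized) phenotype
#' on the effect-allele dosage, over a sample of unrelated individuals.
#' Under an unlinked panel with parental effects present, the per-SNP
#' coefficient estimates the associational effect `mu = gamma + theta`.
#' Monomorphic SNPs have no defined SE and are flagged and excluded.
#'
#' @param cohort a `family_cohort`; only individuals present in `phen` are
#'   used, and they must be mutually unrelated (at most one per family).
#' @param phen phenotype table with `individual_id` and `y`.
#' @param covariates character vector of covariate columns of `phen` to
#'   residualize on before the per-SNP regressions (default none).
#' @return A `summary_stats` data frame: `snp_id`, `effect_allele`,
#'   `other_allele`, `maf`, `beta`, `se`, `n`; attribute `n_monomorphic`.
#' @export
run_population_gwas <- function(cohort, phen, covariates = NULL) {
  stopifnot(inherits(cohort, "family_cohort"))
  ids <- phen$individual_id[phen$individual_id %in% rownames(cohort$dosage)]
  if (!length(ids)) stop("no phenotyped individuals with genotypes")
  ped <- cohort$ped[match(ids, cohort$ped$individual_id), ]
  if (anyDuplicated(ids) || anyDuplicated(ped$family_id)) {
    stop("GWAS sample contains related individuals (same family)")
  }
  x <- if (identical(ids, rownames(cohort$dosage))) cohort$dosage
       else cohort$dosage[ids, , drop = FALSE]
  storage.mode(x) <- "double"
  y <- phen$y[match(ids, phen$individual_id)]
  if (length(covariates)) {
    cv <- phen[match(ids, phen$individual_id), covariates, drop = FALSE]
    y <- stats::residuals(stats::lm(y ~ ., data = cv))
  }
  n <- length(y)
  xm <- colMeans(x)
  sxx <- colSums(x^2) - n * xm^2
  mono <- sxx <= 0
  yc <- y - mean(y)
  sxy <- drop(crossprod(x, yc))
  beta <- sxy / sxx
  syy <- sum(yc^2)
  # residual variance per SNP from the simple-regression identity
  s2 <- pmax(syy - beta * sxy, 0) / (n - 2)
  se <- sqrt(s2 / sxx)
  out <- data.frame(
    snp_id = cohort$panel$snp_id,
    effect_allele = cohort$panel$effect_allele,
    other_allele = cohort$panel$other_allele,
    maf = xm / 2,
    beta = beta,
    se = se,
    n = n,
    stringsAsFactors = FALSE
  )
  out <- out[!mono, , drop = FALSE]
  attr(out, "n_monomorphic") <- sum(mono)
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Build a weight set from GWAS summary statistics
#'
#' Weights are the estimated per-allele effects times a scalar shrinkage
#' factor. Because PGIs are standardized before use, any common scalar
#' cancels; the factor matters only when raw (unstandardized) scores are
#' consumed downstream.
#'
#' @param sumstats a `summary_stats` data frame.
#' @param shrink scalar in (0, 1].
#' @return A `weight_set` data frame: `snp_id`, `effect_allele`,
#'   `other_allele`, `weight`.
#' @export
make_weightset <- function(sumstats, shrink = 1) {
  stopifnot(nrow(sumstats) >= 1)
  if (length(shrink) != 1 || shrink <= 0 || shrink > 1) {
    stop("shrink must be a scalar in (0, 1]")
  }
  w <- sumstats$beta * shrink
  if (all(w == 0)) stop("all weights are zero")
  out <- data.frame(
    snp_id = sumstats$snp_id,
    effect_allele = sumstats$effect_allele,
    other_allele = sumstats$other_allele,
    weight = w,
    stringsAsFactors = FALSE
  )
  class(out) <- c("weight_set", "data.frame")
  out
}

#' Weight set from panel truth
#'
#' Convenience constructor taking the simulation-truth effect column
#' (`gamma`, `theta`, or `mu`) as weights — e.g. the causal additive SNP
#' factor uses `which = "gamma"`.
#'
#' @param panel a [snp_panel()].
#' @param which effect column to use.
#' @return A `weight_set`.
#' @export
weightset_from_panel <- function(panel, which = c("gamma", "mu", "theta")) {
  which <- match.arg(which)
  w <- panel[[which]]
  if (all(w == 0)) stop("all weights are zero")
  out <- data.frame(
    snp_id = panel$snp_id,
    effect_allele = panel$effect_allele,
    other_allele = panel$other_allele,
    weight = w,
    stringsAsFactors = FALSE
  )
  class(out) <- c("weight_set", "data.frame")
  out
}

#' Select a scalar shrinkage factor on a held-out fold
#'
#' Evaluates each candidate scalar by the out-of-sample R2 of a regression
#' of the held-out phenotype on the raw (unstandardized) score. Since a
#' common scalar rescales scores without changing the fitted R2, candidates
#' tie; ties resolve to the largest scalar.
#'
#' @param sumstats training summary statistics.
#' @param cohort held-out `family_cohort`.
#' @param phen held-out phenotype table.
#' @param grid candidate scalars in (0, 1].
#' @return list(`shrink`, `r2`): the selected scalar and the per-candidate
#'   held-out R2.
#' @export
select_shrinkage <- function(sumstats, cohort, phen, grid = c(0.25, 0.5, 1)) {
  r2 <- vapply(grid, function(s) {
    ws <- make_weightset(sumstats, shrink = s)
    sc <- raw_score(cohort, ws)
    ids <- intersect(names(sc), phen$individual_id)
    y <- phen$y[match(ids, phen$individual_id)]
    summary(stats::lm(y ~ sc[ids]))$r.squared
  }, numeric(1))
  best <- max(which(r2 >= max(r2) - 1e-12))
  list(shrink = grid[best], r2 = stats::setNames(r2, grid))
}
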