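# Align a weight set to the dosage panel of a cohort: match on snp_id, flip
# the weight sign when effect/other alleles are swapped, drop SNPs whose
# allele pair does not match either orientation. Returns weights in dosage
# column order (NA where dropped) plus bookkeeping counts.
align_weights <- function(panel, weights) {
  idx <- match(panel$snp_id, weights$snp_id)
  w <- rep(NA_real_, nrow(panel))
  hit <- which(!is.na(idx))
  same <- weights$effect_allele[idx[hit]] == panel$effect_allele[hit] &
    weights$other_allele[idx[hit]] == panel$other_allele[hit]
  swapped <- weights$effect_allele[idx[hit]] == panel$other_allele[hit] &
    weights$other_allele[idx[hit]] == panel$effect_allele[hit]
  w[hit[same]] <- weights$weight[idx[hit[same]]]
  w[hit[swapped]] <- -weights$weight[idx[hit[swapped]]]
  n_mismatch <- sum(!same & !swapped)
  if (n_mismatch > 0) {
    message(n_mismatch, " SNP(s) dropped on allele mismatch")
  }
  list(w = w, n_overlap = sum(!is.na(w)), n_flipped = sum(swapped),
       n_mismatch = n_mismatch)
}

raw_score <- function(cohort, weights) {
  al <- align_weights(cohort$panel, weights)
  if (al$n_overlap == 0) stop("zero SNP overlap between dosage and weights")
  keep <- !is.na(al$w)
  drop(cohort$dosage[, keep, drop = FALSE] %*% al$w[keep])
}

#' Compute standardized polygenic indices
#'
#' Scores are weighted sums of effect-allele dosages after allele
#' alignment (weights flipped in sign when the weight file counts the other
#' allele), standardized to mean 0 / variance 1 within the standardization
#' sample.
#'
#' @param cohort a `family_cohort`.
#' @param weights a `weight_set`.
#' @param standardize_in optional character vector of individual ids
#'   defining the standardization sample (default: all scored individuals).
#' @return A `pgi_table` data frame: `individual_id`, `family_id`, `pgi`.
#' @export
compute_pgi <- function(cohort, weights, standardize_in = NULL) {
  sc <- raw_score(cohort, weights)
  ref <- if (is.null(standardize_in)) sc else sc[standardize_in]
  s <- stats::sd(ref)
  if (!is.finite(s) || s == 0) stop("zero score variance in standardization sample")
  out <- data.frame(
    individual_id = cohort$ped$individual_id,
    family_id = cohort$ped$family_id,
    pgi = (sc - mean(ref)) / s,
    stringsAsFactors = FALSE
  )
  class(out) <- c("pgi_table", "data.frame")
  out
}

#' Family-wise PGI table with observed parental columns
#'
#' Scores every cohort member, then lays the scores out one row per
#' offspring with the father's and mother's PGIs alongside. All columns are
#' expressed on the scale of the proband standardization (centered on their
#' own means, divided by the proband raw-score sd) so within-family
#' coefficients are comparable across columns. The combined parental column
#' is the sum of the two parental scores on that same scale.
#'
#' @param cohort a `family_cohort` with parent roles present.
#' @param weights a `weight_set`.
#' @param combined_only collapse father+mother into a single
#'   `pgi_parental_combined` column.
#' @return A `pgi_table` with columns `individual_id`, `family_id`,
#'   `pgi_proband`, then `pgi_father` + `pgi_mother` or
#'   `pgi_parental_combined`; `source` columns flag `"observed"`.
#' @export
pgi_by_role <- function(cohort, weights, combined_only = FALSE) {
  sc <- raw_score(cohort, weights)
  ped <- cohort$ped
  off <- which(ped$role %in% c("proband", "sibling"))
  if (!length(off)) stop("cohort has no offspring rows")
  ctr <- mean(sc[off]); s <- stats::sd(sc[off])
  if (s == 0) stop("zero score variance")
  pf <- sc[ped$father_id[off]]; pm <- sc[ped$mother_id[off]]
  out <- data.frame(
    individual_id = ped$individual_id[off],
    family_id = ped$family_id[off],
    pgi_proband = (sc[off] - ctr) / s,
    stringsAsFactors = FALSE
  )
  if (combined_only) {
    out$pgi_parental_combined <- (pf + pm - mean(pf + pm)) / s
    out$source_parental <- "observed"
  } else {
    out$pgi_father <- (pf - mean(pf)) / s
    out$pgi_mother <- (pm - mean(pm)) / s
    out$source_father <- "observed"
    out$source_mother <- "observed"
  }
  class(out) <- c("pgi_table", "data.frame")
  out
}

#' Correlation between causal and associational additive SNP factors
#'
#' Sample correlation of `x gamma` (the causal additive SNP factor) and
#' `x mu` (the associational factor, `mu = gamma + theta`) over the
#' individuals in the cohort. Equals 1 when `theta = 0` or when `theta` is
#' proportional to `gamma` with a positive constant; below 1 when
#' confounding rotates `mu` away from `gamma`.
#'
#' @param panel a [snp_panel()] carrying the true `gamma` and `mu`.
#' @param cohort a `family_cohort` providing the dosages.
#' @return scalar correlation in `[-1, 1]`.
#' @export
snp_factor_correlation <- function(panel, cohort) {
  x <- cohort$dosage
  g <- drop(x %*% panel$gamma)
  m <- drop(x %*% panel$mu)
  if (stats::sd(g) == 0 || stats::sd(m) == 0) {
    stop("a SNP factor has zero variance")
  }
  stats::cor(g, m)
}
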