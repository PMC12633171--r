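#' PGI-by-subgroup interaction model
#'
#' Fits the heterogeneity regression: phenotype (standardized within each
#' subgroup) on the standardized PGI, the subgroup indicator, their
#' interaction, mean-centered covariates, and the full two-way interaction
#' block (PGI x covariates and subgroup x covariates). With
#' `with_parents = TRUE` the parental PGIs and their interactions with the
#' PGI and the subgroup indicator are added, so the base effect becomes the
#' causal effect delta and the interaction its subgroup shift. A family
#' random intercept is used whenever families contribute multiple rows.
#'
#' @param phen phenotype table with `y` and a binary `subgroup` column.
#' @param pgi a `pgi_table`.
#' @param covariates covariate columns of `phen` to include (mean-centered).
#' @param with_parents control for parental PGIs.
#' @param subgroup_col name of the subgroup indicator column.
#' @return A `hetero_result`: `base_effect` (psi or delta), `interaction`
#'   (lambda), `vcov` (2x2), `n`, `with_parents`, and the fitted model.
#' @export
fit_interaction <- function(phen, pgi, covariates = NULL,
                            with_parents = FALSE, subgroup_col = "subgroup") {
  m <- phen[[subgroup_col]]
  if (is.null(m) || length(unique(stats::na.omit(m))) < 2) {
    stop("subgroup indicator missing or constant")
  }
  d <- assemble_model_frame(phen, pgi, c(covariates, subgroup_col),
                            parental = with_parents)
  names(d)[names(d) == subgroup_col] <- "m"
  # standardize phenotype within subgroup, PGI overall
  for (g in unique(d$m)) d$y[d$m == g] <- std(d$y[d$m == g])
  d$pgi <- std(d$pgi)
  for (cv in covariates) d[[cv]] <- d[[cv]] - mean(d[[cv]])
  inter <- unlist(lapply(covariates, function(cv) {
    c(paste0("pgi:", cv), paste0("m:", cv))
  }))
  par_terms <- NULL
  if (with_parents) {
    sep <- all(c("pgi_father", "pgi_mother") %in% names(d)) &&
      !anyNA(d$pgi_father)
    par_terms <- if (sep) c("pgi_father", "pgi_mother") else "pgi_parental"
    for (pt in par_terms) d[[pt]] <- std(d[[pt]])
    inter <- c(inter, unlist(lapply(par_terms, function(pt) {
      c(paste0("pgi:", pt), paste0("m:", pt))
    })))
  }
  rhs <- paste(c("pgi", "m", "pgi:m", covariates, par_terms, inter),
               collapse = " + ")
  mixed <- needs_random_intercept(d)
  fit <- fit_glm_or_mixed(stats::as.formula(paste("y ~", rhs)), d,
                          binary = FALSE, mixed = mixed)
  V <- as.matrix(stats::vcov(fit))
  terms2 <- c("pgi", "pgi:m")
  cs_b <- coef_se(fit, "pgi"); cs_i <- coef_se(fit, "pgi:m")
  structure(list(
    base_effect = unname(cs_b["est"]), interaction = unname(cs_i["est"]),
    vcov = V[terms2, terms2], n = nrow(d), with_parents = with_parents,
    fit = fit), class = "hetero_result")
}

#' @export
print.hetero_result <- function(x, ...) {
  cat(sprintf("hetero_result: base %.4f (SE %.4f), interaction %.4f (SE %.4f)%s\n",
              x$base_effect, sqrt(x$vcov[1, 1]), x$interaction,
              sqrt(x$vcov[2, 2]),
              if (x$with_parents) " [parental controls]" else ""))
  invisible(x)
}

#' Subgroup effect ratio with delta-method SE
#'
#' Ratio of the baseline-group effect to the comparison-group effect,
#' `base / (base + interaction)`, with SE from the delta method using the
#' joint covariance of the two coefficients (gradient
#' `(lambda, -psi) / (psi + lambda)^2`).
#'
#' @param res a `hetero_result`.
#' @return A `ratio_estimate`.
#' @export
subgroup_ratio <- function(res) {
  b <- res$base_effect; l <- res$interaction
  den <- b + l
  se_den <- sqrt(res$vcov[1, 1] + res$vcov[2, 2] + 2 * res$vcov[1, 2])
  if (abs(den) / se_den < 5) {
    warning("comparison-group effect is near zero; delta-method SE withheld")
    return(structure(list(ratio = b / den, se = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, method = "delta"),
                     class = "ratio_estimate"))
  }
  grad <- c(l, -b) / den^2
  se <- sqrt(drop(t(grad) %*% res$vcov %*% grad))
  r <- b / den
  structure(list(ratio = r, se = se, ci_low = r - 1.96 * se,
                 ci_high = r + 1.96 * se, method = "delta"),
            class = "ratio_estimate")
}

r2_fixed <- function(fit, y) {
  pred <- if (inherits(fit, "merMod")) {
    drop(lme4::getME(fit, "X") %*% lme4::fixef(fit))
  } else {
    stats::fitted(fit)
  }
  # guard against numerically-constant predictions from intercept models
  if (stats::sd(pred) < 1e-10 * max(stats::sd(y), 1)) return(0)
  stats::cor(y, pred)^2
}

#' Incremental R2 of the PGI
#'
#' Difference in the coefficient of determination (squared correlation of
#' the phenotype with the fixed-effect predictions) between the model with
#' and without the PGI, covariates in both. With `with_parents = TRUE` the
#' parental PGIs enter both nested models so the increment isolates the
#' proband PGI.
#'
#' @param phen phenotype table.
#' @param pgi a `pgi_table`.
#' @param covariates covariate columns in both nested models.
#' @param with_parents include parental PGIs in both models.
#' @return scalar incremental R2.
#' @export
incremental_r2 <- function(phen, pgi, covariates = NULL,
                           with_parents = FALSE) {
  d <- assemble_model_frame(phen, pgi, covariates, parental = with_parents)
  par_terms <- NULL
  if (with_parents) {
    sep <- all(c("pgi_father", "pgi_mother") %in% names(d)) &&
      !anyNA(d$pgi_father)
    par_terms <- if (sep) c("pgi_father", "pgi_mother") else "pgi_parental"
  }
  d$pgi <- std(d$pgi)
  mixed <- needs_random_intercept(d)
  rhs0 <- paste(c("1", covariates, par_terms), collapse = " + ")
  rhs1 <- paste(c("pgi", covariates, par_terms), collapse = " + ")
  f0 <- fit_glm_or_mixed(stats::as.formula(paste("y ~", rhs0)), d, FALSE, mixed)
  f1 <- fit_glm_or_mixed(stats::as.formula(paste("y ~", rhs1)), d, FALSE, mixed)
  r2_fixed(f1, d$y) - r2_fixed(f0, d$y)
}

#' Family bootstrap for subgroup incremental R2
#'
#' Resamples whole families with replacement, stratified by subgroup, and
#' recomputes the per-group incremental R2 and the group-0 / group-1 ratio;
#' returns percentile confidence intervals. Families are assigned to the
#' subgroup of their first phenotyped member.
#'
#' @param phen phenotype table with a binary `subgroup` column.
#' @param pgi a `pgi_table`.
#' @param covariates covariate columns.
#' @param with_parents include parental PGIs in both nested models.
#' @param reps bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @param level confidence level.
#' @return list with `point` (per-group incremental R2 and ratio), `ci`
#'   (matrix of percentile CIs), and `reps`.
#' @export
bootstrap_families <- function(phen, pgi, covariates = NULL,
                               with_parents = FALSE, reps = 1000, seed,
                               level = 0.95) {
  if (reps < 100) stop("reps must be >= 100")
  fam_group <- tapply(phen$subgroup, phen$family_id, function(v) v[1])
  fams <- split(names(fam_group), unname(fam_group))
  if (any(lengths(fams) < 20)) {
    warning("fewer than 20 families in a subgroup; bootstrap may be unstable")
  }
  stat <- function(ph) {
    r2 <- vapply(sort(unique(ph$subgroup)), function(g) {
      incremental_r2(ph[ph$subgroup == g, , drop = FALSE], pgi, covariates,
                     with_parents)
    }, numeric(1))
    c(r2_group0 = r2[1], r2_group1 = r2[2], ratio = r2[1] / r2[2])
  }
  point <- stat(phen)
  alpha <- (1 - level) / 2
  fam_rows <- split(seq_len(nrow(phen)), phen$family_id)
  draws <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(b) {
      pick <- unlist(lapply(fams, function(f) sample(f, replace = TRUE)))
      rows <- fam_rows[pick]
      ph <- phen[unlist(rows), , drop = FALSE]
      # families drawn more than once must enter as distinct clusters
      ph$family_id <- rep(paste0(pick, "#", seq_along(pick)), lengths(rows))
      stat(ph)
    }, numeric(3))
  })
  ci <- t(apply(draws, 1, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE))
  colnames(ci) <- c("lower", "upper")
  rownames(ci) <- names(point)
  list(point = point, ci = ci, reps = reps)
}
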