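new_assoc_result <- function(estimate, se, n, model, scale = "raw",
                             parental_coefs = NULL, fit = NULL) {
  structure(list(estimate = unname(estimate), se = unname(se),
                 n = unname(n), model = model,
                 scale = scale, parental_coefs = parental_coefs, fit = fit),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("assoc_result [%s, %s]: estimate %.4f (SE %.4f), n = %d\n",
              x$model, x$scale, x$estimate, x$se, x$n))
  if (!is.null(x$parental_coefs)) {
    pc <- x$parental_coefs
    cat("  parental:", paste(sprintf("%s = %.4f (%.4f)", names(pc$estimate),
                                     pc$estimate, pc$se), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Residualize a phenotype on standard covariates
#'
#' Quantitative phenotypes are residualized per wave on a second-degree
#' polynomial in age, sex, and their interactions, then averaged across
#' waves. Binary phenotypes are collapsed by the maximum across waves with
#' residualization deferred to the model covariates.
#'
#' @param phen phenotype table; wave columns named in `wave_cols`.
#' @param wave_cols character vector of phenotype columns (default `"y"`).
#' @param age_col,sex_col covariate column names.
#' @param binary logical.
#' @return The phenotype table with `y` replaced by the residualized (or
#'   collapsed) measure.
#' @export
residualize_phenotype <- function(phen, wave_cols = "y", age_col = "age",
                                  sex_col = "sex", binary = FALSE) {
  stopifnot(all(wave_cols %in% names(phen)))
  if (all(is.na(phen[[age_col]]))) stop("all-missing covariate: ", age_col)
  if (binary) {
    phen$y <- do.call(pmax, c(unname(phen[wave_cols]), list(na.rm = TRUE)))
    return(phen)
  }
  res <- sapply(wave_cols, function(cl) {
    d <- data.frame(y = phen[[cl]], age = phen[[age_col]],
                    sex = phen[[sex_col]])
    fit <- stats::lm(y ~ (age + I(age^2)) * sex, data = d)
    r <- rep(NA_real_, nrow(d))
    r[as.integer(names(stats::residuals(fit)))] <- stats::residuals(fit)
    r
  })
  phen$y <- rowMeans(as.matrix(res), na.rm = TRUE)
  phen
}

pgi_cols_present <- function(pgi) {
  has <- function(cl) cl %in% names(pgi) && any(!is.na(pgi[[cl]]))
  list(separate = has("pgi_father") && has("pgi_mother"),
       combined = has("pgi_parental_combined"))
}

std <- function(v) (v - mean(v)) / stats::sd(v)

assemble_model_frame <- function(phen, pgi, covariates, parental = FALSE) {
  prob_col <- if ("pgi_proband" %in% names(pgi)) "pgi_proband" else "pgi"
  idx <- match(phen$individual_id, pgi$individual_id)
  keep <- !is.na(idx)
  fam <- if ("family_id" %in% names(phen)) phen$family_id[keep]
         else pgi$family_id[idx[keep]]
  d <- data.frame(y = phen$y[keep],
                  family_id = fam,
                  pgi = pgi[[prob_col]][idx[keep]])
  for (cv in covariates) d[[cv]] <- phen[[cv]][keep]
  if (parental) {
    pc <- pgi_cols_present(pgi)
    if (pc$separate) {
      d$pgi_father <- pgi$pgi_father[idx[keep]]
      d$pgi_mother <- pgi$pgi_mother[idx[keep]]
    }
    if (pc$combined) {
      d$pgi_parental <- pgi$pgi_parental_combined[idx[keep]]
    }
    if (!pc$separate && !pc$combined) {
      stop("no parental PGI columns present")
    }
  }
  d <- d[stats::complete.cases(d[setdiff(names(d), c("pgi_father",
                                                     "pgi_mother",
                                                     "pgi_parental"))]), ]
  d
}

# family random intercept only when some family contributes >1 phenotyped row
needs_random_intercept <- function(d) anyDuplicated(d$family_id) > 0

fit_glm_or_mixed <- function(formula, d, binary, mixed) {
  if (mixed) {
    f2 <- stats::update(formula, . ~ . + (1 | family_id))
    if (binary) {
      lme4::glmer(f2, data = d, family = stats::binomial(), nAGQ = 1L,
                  control = lme4::glmerControl(calc.derivs = FALSE))
    } else {
      lme4::lmer(f2, data = d, REML = TRUE,
                 control = lme4::lmerControl(calc.derivs = FALSE))
    }
  } else {
    if (binary) stats::glm(formula, data = d, family = stats::binomial())
    else stats::lm(formula, data = d)
  }
}

coef_se <- function(fit, term) {
  sm <- if (inherits(fit, "merMod")) {
    as.data.frame(summary(fit)$coefficients)
  } else {
    as.data.frame(summary(fit)$coefficients)
  }
  c(est = sm[term, 1], se = sm[term, 2])
}

#' Population association of a PGI (psi)
#'
#' Regression of the phenotype on the individual's standardized PGI plus
#' covariates, in a sample of unrelated individuals: linear for
#' quantitative phenotypes, logistic for binary (estimate on the log-odds
#' scale; see [odds_ratio()]).
#'
#' @param phen phenotype table with `y` (and covariate columns).
#' @param pgi a `pgi_table` (column `pgi` or `pgi_proband`).
#' @param covariates covariate column names in `phen`.
#' @param binary logical.
#' @param allow_related permit multiple members per family (refused by
#'   default).
#' @return An `assoc_result` with the psi estimate.
#' @export
fit_population_association <- function(phen, pgi, covariates = NULL,
                                       binary = FALSE, allow_related = FALSE) {
  d <- assemble_model_frame(phen, pgi, covariates)
  if (!allow_related && anyDuplicated(d$family_id)) {
    stop("sample contains related individuals; set allow_related = TRUE to override")
  }
  if (stats::sd(d$pgi) == 0) stop("zero PGI variance")
  d$pgi <- std(d$pgi)
  rhs <- paste(c("pgi", covariates), collapse = " + ")
  fit <- fit_glm_or_mixed(stats::as.formula(paste("y ~", rhs)), d, binary,
                          mixed = FALSE)
  cs <- coef_se(fit, "pgi")
  new_assoc_result(cs["est"], cs["se"], nrow(d),
                   model = if (binary) "logistic" else "linear",
                   scale = if (binary) "log_odds" else "raw", fit = fit)
}

#' Causal (direct) effect of a PGI (delta)
#'
#' Adds the parental PGIs as controls: `y ~ PGI + PGI_father + PGI_mother +
#' covariates` when separate parental columns exist, or the combined
#' parental PGI otherwise. A family random intercept is included whenever a
#' family contributes more than one phenotyped member (linear or logistic
#' mixed model via lme4); with one member per family the fit reduces to
#' OLS/ML exactly.
#'
#' @inheritParams fit_population_association
#' @return An `assoc_result` with the delta estimate and the parental
#'   coefficients (`alpha_p`, `alpha_m`, or `alpha`).
#' @export
fit_causal_effect <- function(phen, pgi, covariates = NULL, binary = FALSE) {
  d <- assemble_model_frame(phen, pgi, covariates, parental = TRUE)
  sep <- all(c("pgi_father", "pgi_mother") %in% names(d)) &&
    !anyNA(d$pgi_father) && !anyNA(d$pgi_mother)
  par_terms <- if (sep) c("pgi_father", "pgi_mother") else "pgi_parental"
  if (!sep) {
    if (!"pgi_parental" %in% names(d) &&
        all(c("pgi_father", "pgi_mother") %in% names(d))) {
      d$pgi_parental <- d$pgi_father + d$pgi_mother
    }
    d <- d[!is.na(d$pgi_parental), ]
  }
  if (stats::sd(d$pgi) == 0) stop("zero PGI variance")
  d$pgi <- std(d$pgi)
  for (pt in par_terms) {
    if (stats::sd(d[[pt]]) == 0) stop("degenerate parental PGI variance")
    d[[pt]] <- std(d[[pt]])
  }
  mixed <- needs_random_intercept(d)
  rhs <- paste(c("pgi", par_terms, covariates), collapse = " + ")
  fit <- fit_glm_or_mixed(stats::as.formula(paste("y ~", rhs)), d, binary, mixed)
  cs <- coef_se(fit, "pgi")
  pcs <- lapply(par_terms, function(t) coef_se(fit, t))
  pnames <- if (sep) c("alpha_p", "alpha_m") else "alpha"
  model <- paste0(if (binary) "logistic" else "linear",
                  if (mixed) "_mixed" else "")
  new_assoc_result(cs["est"], cs["se"], nrow(d), model = model,
                   scale = if (binary) "log_odds" else "raw",
                   parental_coefs = list(
                     estimate = stats::setNames(vapply(pcs, `[`, 0, 1), pnames),
                     se = stats::setNames(vapply(pcs, `[`, 0, 2), pnames)),
                   fit = fit)
}

#' Sibling-difference estimator of the direct effect
#'
#' Within sibling pairs, regresses the phenotype difference on the PGI
#' difference. Consistent for delta but less efficient than controlling
#' for (imputed) parental PGIs.
#'
#' @param phen phenotype table covering both siblings.
#' @param pgi a `pgi_table` with per-individual proband PGIs.
#' @return An `assoc_result`.
#' @export
fit_sibling_difference <- function(phen, pgi) {
  prob_col <- if ("pgi_proband" %in% names(pgi)) "pgi_proband" else "pgi"
  idx <- match(phen$individual_id, pgi$individual_id)
  d <- data.frame(y = phen$y, family_id = pgi$family_id[idx],
                  pgi = pgi[[prob_col]][idx])
  d <- d[stats::complete.cases(d), ]
  d <- d[order(d$family_id), ]
  dup <- duplicated(d$family_id)
  f2 <- d$family_id[dup]
  first <- d[match(f2, d$family_id), ]
  second <- d[dup, ][match(f2, d$family_id[dup]), ]
  dy <- first$y - second$y
  dp <- first$pgi - second$pgi
  if (stats::sd(dp) == 0) stop("zero within-pair PGI variance")
  fit <- stats::lm(dy ~ dp)
  sm <- summary(fit)$coefficients
  new_assoc_result(sm["dp", 1], sm["dp", 2], length(dy),
                   model = "sib_difference", fit = fit)
}

#' Ratio of causal effect to population association, delta-method SE
#'
#' `ratio = delta / psi` with
#' `SE = sqrt(SE(delta)^2/psi^2 + delta^2 SE(psi)^2/psi^4)`; the covariance
#' term is dropped because the two estimates must come from independent
#' samples. Warns when `|psi|/SE(psi) < 5`, where the ratio's sampling
#' distribution is poorly behaved.
#'
#' @param delta,psi `assoc_result`s from disjoint samples.
#' @return A `ratio_estimate`: `ratio`, `se`, `ci_low`, `ci_high`,
#'   `method = "delta"`.
#' @export
ratio_with_delta_se <- function(delta, psi) {
  if (psi$estimate == 0) stop("psi estimate is zero; ratio undefined")
  if (abs(psi$estimate) / psi$se < 5) {
    warning("psi is within 5 SE of zero; ratio inference is not well-behaved")
  }
  r <- delta$estimate / psi$estimate
  se <- sqrt(delta$se^2 / psi$estimate^2 +
               delta$estimate^2 * psi$se^2 / psi$estimate^4)
  structure(list(ratio = unname(r), se = unname(se),
                 ci_low = unname(r - 1.96 * se),
                 ci_high = unname(r + 1.96 * se), method = "delta"),
            class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("ratio %.4f (SE %.4f), 95%% CI [%.4f, %.4f], %s method\n",
              x$ratio, x$se, x$ci_low, x$ci_high, x$method))
  invisible(x)
}

#' Test the difference psi - delta against zero
#'
#' Two-sided z test with independent-sample SEs.
#'
#' @param delta,psi `assoc_result`s from disjoint samples.
#' @return list(`z`, `p`).
#' @export
diff_test <- function(delta, psi) {
  z <- (psi$estimate - delta$estimate) / sqrt(psi$se^2 + delta$se^2)
  list(z = unname(z), p = unname(2 * stats::pnorm(-abs(z))))
}

#' Benjamini-Hochberg step-up rejection flags
#'
#' @param pvalues numeric p-values in `[0, 1]`.
#' @param q target false discovery rate.
#' @return logical rejection flags.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (!length(pvalues)) stop("empty p-value list")
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH") <= q
}

#' Inverse-variance-weighted meta-analysis
#'
#' Pools estimates with weights `1/SE^2`; a single input passes through
#' unchanged. Mixing raw and log-odds scales is refused.
#'
#' @param estimates list of `assoc_result`s.
#' @return An `assoc_result` with `model = "ivw_meta"`.
#' @export
ivw_meta <- function(estimates) {
  stopifnot(length(estimates) >= 1)
  scales <- vapply(estimates, `[[`, "", "scale")
  if (length(unique(scales)) > 1) stop("cannot pool mixed scales (raw vs log-odds)")
  est <- vapply(estimates, `[[`, 0, "estimate")
  se <- vapply(estimates, `[[`, 0, "se")
  w <- 1 / se^2
  new_assoc_result(sum(w * est) / sum(w), sqrt(1 / sum(w)),
                   sum(vapply(estimates, `[[`, 0L, "n")),
                   model = "ivw_meta", scale = scales[1])
}

#' Log-odds estimate as an odds ratio
#'
#' @param x an `assoc_result` on the log-odds scale.
#' @return list(`or`, `ci_low`, `ci_high`).
#' @export
odds_ratio <- function(x) {
  stopifnot(x$scale == "log_odds")
  list(or = exp(x$estimate),
       ci_low = exp(x$estimate - 1.96 * x$se),
       ci_high = exp(x$estimate + 1.96 * x$se))
}
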