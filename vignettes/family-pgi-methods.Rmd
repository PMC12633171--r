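---
title: "Family-based polygenic index analysis: models, simulation design, and attenuation correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based polygenic index analysis: models, simulation design, and attenuation correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgifam)
```

## The problem

A polygenic index (PGI) is a weighted sum of a person's allele counts,
$\hat g_i = x_i w / \mathrm{s.d.}(x_i w)$, built to predict a phenotype. In
observational samples of unrelated individuals, the regression coefficient
on a PGI — the *population association* $\psi$ — mixes the causal effect of
the person's own genotype with everything the genotype proxies for: effects
of the rearing environment shaped by parental genotypes ("genetic
nurture"), population stratification, and assortative mating. Controlling
for the *parents'* PGIs isolates the component identified by random
Mendelian segregation at meiosis; the coefficient on the proband PGI in
that regression — the *causal effect* $\delta$ — has a within-family causal
interpretation.

`pgifam` implements the full analysis chain for this design: a synthetic
family-cohort generator, a finite-sample population GWAS, PGI construction,
Mendelian imputation of unobserved parental genotypes, the
$\psi$/$\delta$ estimators with ratio inference, subgroup-heterogeneity
models, and the analytic attenuation correction that links what a
family-based study estimates to what a noiseless causal PGI would estimate.

## Generative model

Phenotypes follow

$$ y_i = x_i\gamma + x_{p,i}\theta + \varepsilon_i, $$

where $x_i$ is the proband's dosage vector, $x_{p,i}$ the sum of the
parental dosage vectors, $\gamma$ the direct (causal) per-allele effects
and $\theta$ the parental-genotype effects. The population regression of
$y$ on $x$ alone has coefficient $\mu = \gamma + \theta$ under random
mating: the parental-effect component loads onto the child's genotype
because child and parental genotypes are correlated
($\mathrm{Cov}(x_{ij}, x_{p,ij}) = \mathrm{Var}(x_{ij})$). This identity is
what the GWAS module's tests verify, and what makes a PGI trained on a
standard GWAS an imperfect proxy for the causal factor $x\gamma$.

### Simulator design

* **SNPs are unlinked, biallelic, and in HWE** at frequencies drawn
  uniformly (default range 0.05–0.5). The framework has no LD term, and
  every property checked here is LD-free. Founder dosages are
  Binomial(2, maf); meiosis transmits one allele per parent, uniform over
  the parent's two alleles. For two-children families the per-SNP IBD
  state (0/1/2 shared parental haplotypes) is recorded from the
  transmitted-haplotype identities, giving the exact marginal
  (1/4, 1/2, 1/4) distribution.
* **Fused generation at scale.** For large random-mating cohorts,
  `simulate_trio_cohort()` draws the joint (father, mother, child)
  genotype configuration — or the (child, parental-sum) pair when parents
  are only needed for phenotype construction — from its exact categorical
  distribution per SNP. This is distributionally identical to
  founders + pairing + meiosis and is verified against the compositional
  path's moments in the test suite.
* **Effect scaling.** Panel effects are nominal; `simulate_phenotype()`
  rescales $\gamma$ so the direct component explains `h2_direct` of the
  phenotype variance, and (optionally) $\theta$ so the parental component
  explains `parental_share`, with Gaussian noise filling the remainder to
  unit total variance. The realized decomposition is returned for test
  use. Defaults in the simulation studies use `h2_direct` in the
  0.25–0.4 range, matching SNP heritabilities typical of the phenotypes in
  the worked example (0.085–0.247).
* **Assortative mating** is noisy rank matching on a mating phenotype:
  spouses are matched on phenotype-plus-noise ranks, with the noise scale
  bisected until the realized spousal correlation is within ±0.03 of the
  target. Discrete phenotypes can cap the achievable correlation; the
  generator then warns and reports the best achievable value. The grid
  used in the property tests is 0, 0.2, 0.4 — "realistic" spousal
  correlations for behavioral phenotypes.
* **Binary phenotypes** threshold the latent liability at the requested
  prevalence (the threshold is placed from the sample mean and SD, so the
  case fraction is accurate to Monte-Carlo error).
* **Subgroup heterogeneity** multiplies the direct-effect component by a
  scale factor in one subgroup while holding total phenotype variance at 1
  in both groups — the "uniformly scaled SNP effects" model with equal
  environmental-plus-genetic variance, under which the ratio of
  standardized subgroup coefficients identifies the scale factor.

What the generator does *not* emulate: linkage disequilibrium, multigenerational
pedigrees, gene–environment interaction beyond the subgroup scaling, phasing,
genotyping error, and ascertainment. Passing tests therefore demonstrate the
statistical machinery under the model's own assumptions, not robustness to
real-data pathologies.

## Weights: finite-sample GWAS instead of LD-aware shrinkage

Because the panel is unlinked, per-SNP OLS on a population sample is an
unbiased (and noisy) estimator of $\mu$ — exactly the statistical role
that LD-aware posterior-mean methods play for real data. The `shrink`
scalar in `make_weightset()` exists for completeness: standardized PGIs
are invariant to any common scalar on the weights, so cross-validated
selection over a scalar grid ties exactly (ties resolve to the largest
value); it matters only if raw scores are consumed.

Summary statistics can be filtered by effective sample size,
$N_{\mathrm{eff}} = 1/(2\,\mathrm{SE}^2\,\mathrm{MAF}(1-\mathrm{MAF}))$,
dropping SNPs strictly below 0.8 times the median — SNPs exactly at the
boundary are retained (the boundary convention is not dictated by the
formula; strictness was chosen so a homogeneous panel is never filtered).

## Mendelian imputation of parental PGIs

When parents are ungenotyped, their expected genotypes are recovered by
exact enumeration: all parental pairs $(g_m, g_f) \in \{0,1,2\}^2$ get HWE
priors at the (estimated or supplied) allele frequency, weighted by the
Mendelian transmission likelihood of the observed children — the joint
two-child likelihood conditions on the sibling IBD state — and by the
observed parent when one is genotyped. The posterior mean of $g_m + g_f$
feeds the weight vector to give a parental PGI. Four family designs are
handled: trios (pass-through), one genotyped parent (only the other parent
is imputed), sibling pairs, and singletons. For sibling pairs the
maternal/paternal decomposition is not identified, so a single combined
parental PGI is returned — controlling for it identifies the same $\delta$
(its coefficient is the average of the two parental coefficients).

Implementation notes: enumeration is unphased (the simulator is unphased
and enumeration is exact for the designs covered); likelihood tables over
all (child, child, IBD, parent, parent) configurations are precomputed once
so imputation vectorizes over families and SNPs; genotyping error and any
assortative-mating adjustment to imputed parental PGIs are not modeled,
and the output metadata records that. The proband PGI returned alongside
imputed parental PGIs uses the same SNP intersection, preserving the
Mendelian relations the downstream regressions rely on.

The posterior mean is validated against an independently written
brute-force oracle over every configuration, and downstream: $\hat\delta$
from sib-pair-imputed controls matches $\hat\delta$ from fully observed
parents, with a smaller standard error than the sibling-difference
estimator on the same data.

## Estimation

* $\psi$: `fit_population_association()` — OLS (or logistic regression)
  of the phenotype on the standardized proband PGI in an unrelated sample;
  refuses related individuals unless overridden.
* $\delta$: `fit_causal_effect()` — adds parental PGI controls; a family
  random intercept (lme4) is used whenever a family contributes more than
  one phenotyped member, otherwise the fit reduces exactly to OLS. Binary
  phenotypes use a logistic GLMM. PGIs are standardized within the
  estimation sample before fitting.
* Ratio inference: $\hat\delta/\hat\psi$ with the independent-samples
  delta-method SE
  $\sqrt{\mathrm{SE}(\hat\delta)^2/\hat\psi^2 +
  \hat\delta^2\,\mathrm{SE}(\hat\psi)^2/\hat\psi^4}$; the covariance term
  is dropped *because* the two estimates must come from disjoint samples
  (the same-sample combination is refused for delta-SE purposes). A
  warning fires when $|\hat\psi|/\mathrm{SE} < 5$, where ratio inference
  is poorly behaved; hypothesis testing therefore uses the difference
  $\psi - \delta$ (z test), with Benjamini–Hochberg control across
  phenotypes and inverse-variance-weighted meta-analysis across cohorts.

### Subgroup heterogeneity

`fit_interaction()` fits the PGI-by-subgroup interaction model with the
phenotype standardized within each subgroup, covariates mean-centered, and
the full two-way interaction block (PGI x covariates, subgroup x
covariates; plus parental-PGI interactions when parental controls are on).
The subgroup ratio $\psi/(\psi+\lambda)$ carries a delta-method SE from
the coefficient covariance (gradient $(\lambda, -\psi)/(\psi+\lambda)^2$),
checked against numeric differentiation. Continuous grouping variables
should be median-split (ties to the lower group). Incremental $R^2$ uses
squared correlation between the phenotype and fixed-effect predictions of
nested models, with family-level bootstrap (resampling whole families,
stratified by subgroup; resampled families enter as distinct clusters) for
percentile CIs.

**A calibration caveat found by the package's own Monte-Carlo check:** the
delta-method SE for subgroup ratios is conservative. Standardizing the
phenotype within each subgroup makes the group coefficients
correlation-like — the estimated scale co-varies with the coefficient — so
the true sampling SD is smaller than the model-based vcov implies by
roughly $\sqrt{1-R^2}$. At $R^2 \approx 0.3$ the reported SE exceeds the
Monte-Carlo SD by about 25%; the $\delta/\psi$ ratio SE (no phenotype
standardization) calibrates within a few percent. Confidence intervals for
subgroup ratios are therefore conservative, not anti-conservative.

## Attenuation theory and the worked example

A family-based study that uses weights $\hat\mu$ from a finite standard
GWAS estimates coefficients attenuated relative to the ideal regression on
the causal factor PGI by

$$ \frac{\beta}{\beta_c} = \frac{\delta_k}{\delta_{c,k}} =
\frac{\mathrm{Corr}(x\gamma, x\mu)}{\rho}, \qquad
\rho = \sqrt{h^2_\mu / R^2} \ge 1 ,$$

with $h^2_\mu$ the associational SNP heritability and $R^2$ the realized
predictive power of the $\hat\mu$-PGI. $\rho$ captures errors-in-variables
attenuation from GWAS sampling noise ($\rho \to 1$ as the GWAS grows);
the correlation captures the divergence of associational from causal
weights. Setting the correlation to 1 recovers the pure
errors-in-variables correction; setting $\rho = 1$ recovers the pure
$\mu \ne \gamma$ correction. Coefficients *and their SEs* divide by the
factor to correct. The simulation studies confirm the coefficient ratio
tracks $\mathrm{Corr}/\rho$ within Monte-Carlo error at realistic
heritabilities, with two caveats observed in the package's experiments:
the SE-attenuation claim is approximate (the feasible regression's
residual variance is smaller because $\hat\mu$-PGI controls absorb
parental-effect variance, so the SE ratio deviates from the factor at
extreme heritabilities), and under assortative mating the realized
attenuation is at least as strong as the random-mating prediction.

Expected predictive power uses
$R^2_{\mathrm{theory}} = (h^2)^2 / (h^2 + M/N)$ with $M = 60{,}000$ effective
SNPs by default, and the SE of $\rho$ treats $R^2$ as fixed,
$\mathrm{SE}(\rho) = \mathrm{SE}(h^2)/(2\rho R^2)$ — that convention is
what reproduces the published SEs; full propagation through $R^2(h^2)$ is
available behind `propagate_r2 = TRUE`. The bias-factor SE assumes the
correlation and $\rho$ estimates are independent.

`attenuation_report()` applies the chain to input rows and, by default,
rounds each derived column to display precision (3 decimals, half-up)
before computing the next — published summary tables chain
display-precision values, and reproducing them exactly requires doing the
same; `chain_rounded = FALSE` carries full precision. One cell of the
bundled eight-phenotype example (the BMI expected $R^2$) cannot be
reproduced from the published inputs at 3 decimals: the printed inputs
give 0.174 where the published table shows 0.175, implying the
heritability input behind that table carried more digits than displayed.
All other cells reproduce exactly.

```{r}
attenuation_report(repository_bias_inputs())[, c("phenotype", "r2", "rho",
                                                 "se_rho", "bias_factor",
                                                 "se_bias_factor")]
```

## Problem sizes and numerical choices

The simulation studies in the test suite use 2,000 SNPs with a 40,000-person
GWAS and 4,000 trio families (20 replicates) for the attenuation
validation; 500 SNPs, 8,000-person GWAS, 1,200 sib-pair families
(20 replicates) for imputation consistency; and 1,000 replicates of
reduced-size designs (200 SNPs, 250 trio / 500 unrelated individuals) for
Monte-Carlo SE calibration — sizes at which every Monte-Carlo criterion has
its intended resolution. Seeds are explicit everywhere; identical
configuration and seed reproduce cohorts, fits, and pipeline outputs
byte-for-byte (TSV numerics are written at 10 significant digits).
Degenerate inputs fail fast: zero-variance PGIs, infeasible variance
targets, Mendel-inconsistent observations, and zero-overlap weight panels
are all explicit errors rather than silent NAs.

## Known limitations

* No LD; single-ancestry; two-generation pedigrees only.
* The attenuation formula (and its simulation validation) is derived under
  random mating; assortative mating makes it an underestimate of the true
  attenuation.
* Mendelian imputation omits genotyping error and the assortative-mating
  adjustment of imputed parental PGIs.
* Subgroup-ratio delta SEs are conservative (see above).
* Logistic mixed models use one-point adaptive quadrature (lme4 defaults);
  binary-phenotype attenuation is not corrected for ascertainment.
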