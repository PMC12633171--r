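Package: pgifam
Title: Family-Based Polygenic Index Analysis with Mendelian Imputation
    and Attenuation Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation toolkit for family-based polygenic
    index (PGI) studies. Generates synthetic family cohorts (trios,
    parent-offspring pairs, sibling pairs with per-SNP IBD states) with
    direct and parental genetic effects and optional assortative mating;
    runs finite-sample population GWAS to obtain noisy SNP weights;
    constructs standardized PGIs with effect-allele alignment; imputes
    missing parental genotypes by exact posterior-mean enumeration under
    Mendelian transmission and Hardy-Weinberg priors; estimates population
    associations and within-family causal effects with delta-method ratio
    inference, Benjamini-Hochberg FDR and inverse-variance-weighted
    meta-analysis; fits gene-by-subgroup interaction models with family
    bootstrap; and applies the unified errors-in-variables attenuation
    correction Corr(x.gamma, x.mu)/rho for PGI effect estimates, including
    the published worked example for eight repository phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
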