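# Shared fixtures and independent oracles, written before the implementation
# paths they check and kept deliberately literal (explicit loops over
# haplotype configurations, no shared code with R/).

tiny_panel <- function(j = 5, maf = seq(0.1, 0.5, length.out = j),
                       gamma = rep(1, j), theta = rep(0, j)) {
  snp_panel(maf = maf, gamma = gamma, theta = theta)
}

# Brute-force posterior mean of g_m + g_f by enumeration over ordered
# parental haplotypes and explicit transmission draws. Children are one or
# two dosages; for two, `ibd` fixes the shared-haplotype pattern.
oracle_parental_mean <- function(children, observed_parent = NULL,
                                 ibd = NULL, maf) {
  hw <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  haps <- function(g) if (g == 0) list(c(0, 0)) else
    if (g == 2) list(c(1, 1)) else list(c(0, 1), c(1, 0))
  num <- den <- 0
  for (gm in 0:2) for (gf in 0:2) {
    if (!is.null(observed_parent) && gm != observed_parent) next
    prior <- hw[gm + 1] * hw[gf + 1]
    if (!is.null(observed_parent)) prior <- hw[gf + 1]
    lik <- 0
    for (hm in haps(gm)) for (hf in haps(gf)) {
      hap_w <- 1 / (length(haps(gm)) * length(haps(gf)))
      if (length(children) == 1) {
        for (im in 1:2) for (jf in 1:2) {
          if (hm[im] + hf[jf] == children[1]) lik <- lik + hap_w / 4
        }
      } else {
        pats <- if (ibd == 2) list(c(TRUE, TRUE)) else
          if (ibd == 0) list(c(FALSE, FALSE)) else
            list(c(TRUE, FALSE), c(FALSE, TRUE))
        for (pat in pats) {
          for (im1 in 1:2) for (jf1 in 1:2) {
            im2 <- if (pat[1]) im1 else 3 - im1
            jf2 <- if (pat[2]) jf1 else 3 - jf1
            ok <- hm[im1] + hf[jf1] == children[1] &&
              hm[im2] + hf[jf2] == children[2]
            if (ok) lik <- lik + hap_w / (4 * length(pats))
          }
        }
      }
    }
    obs_part <- if (!is.null(observed_parent)) observed_parent + gf else gm + gf
    num <- num + prior * lik * obs_part
    den <- den + prior * lik
  }
  if (den == 0) return(NA_real_)
  num / den
}

# small trio cohort with phenotype, used across famfit/heterokit tests
make_family_fixture <- function(n_fam = 600, j = 120, seed = 42,
                                theta_prop = 0, theta_orth_sd = 0,
                                h2 = 0.3, parental_share = NULL,
                                n_children = 1, subgroup = NULL) {
  panel <- random_snp_panel(j, seed = seed, theta_prop = theta_prop,
                            theta_orth_sd = theta_orth_sd)
  coh <- simulate_trio_cohort(n_fam, panel, n_children = n_children,
                              seed = seed + 1)
  phen <- simulate_phenotype(coh, panel, h2_direct = h2,
                             parental_share = parental_share,
                             seed = seed + 2, subgroup = subgroup)
  list(panel = panel, cohort = coh, phen = phen)
}

# bare assoc_result for arithmetic tests of ratio/diff/meta operations
new_assoc_result_for_test <- function(estimate, se) {
  structure(list(estimate = estimate, se = se, n = 100L, model = "linear",
                 scale = "raw", parental_coefs = NULL, fit = NULL),
            class = "assoc_result")
}
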