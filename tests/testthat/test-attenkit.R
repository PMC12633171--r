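test_that("expected R2 reproduces published values and limits", {
  expect_equal(round(expected_r2(0.133, 2155939), 3), 0.110)
  expect_equal(round(expected_r2(0.231, 3839667), 3), 0.216)
  # as the GWAS grows the expected R2 approaches the heritability
  expect_equal(expected_r2(0.3, 1e12), 0.3, tolerance = 1e-6)
  expect_gt(expected_r2(0.3, 1e5), expected_r2(0.3, 1e4))
  expect_error(expected_r2(1.2, 1000), "h2")
  expect_error(expected_r2(0, 1000), "h2")
})

test_that("effective sample size follows the SE/MAF formula", {
  expect_equal(effective_n(0.1, 0.5), 200)
  expect_equal(effective_n(0.05, 0.5), 800)  # halving SE quadruples Neff
  expect_error(effective_n(0, 0.5), "se")
  expect_error(effective_n(0.1, 0), "maf")
})

test_that("median Neff of a simulated GWAS recovers the sample size", {
  panel <- random_snp_panel(300, seed = 221)
  f <- simulate_founders(5000, panel, seed = 222)
  phen <- withr::with_seed(223, data.frame(
    individual_id = f$ped$individual_id, y = rnorm(5000)))
  ss <- run_population_gwas(f, phen)
  neff <- effective_n(ss$se, pmin(ss$maf, 1 - ss$maf))
  expect_lt(abs(median(neff) / 5000 - 1), 0.05)
})

test_that("Neff filter removes only strictly-below-threshold SNPs", {
  ss <- data.frame(snp_id = sprintf("s%02d", 1:10),
                   beta = 0.1, maf = 0.5,
                   se = sqrt(1 / (2 * c(rep(100, 9), 50) * 0.25)),
                   n = 100)
  out <- filter_by_neff(ss)
  expect_equal(nrow(out), 9L)
  expect_identical(attr(out, "n_removed"), 1L)
  expect_false("s10" %in% out$snp_id)
  # homogeneous Neff: nothing removed
  hom <- ss; hom$se <- 0.1
  expect_equal(nrow(filter_by_neff(hom)), 10L)
  # exactly at 0.8 x median: retained (strict inequality)
  edge <- ss
  edge$se <- sqrt(1 / (2 * c(rep(100, 9), 80) * 0.25))
  expect_equal(nrow(filter_by_neff(edge)), 10L)
})

test_that("rho and its fixed-R2 delta SE reproduce the published rows", {
  r2 <- round(expected_r2(0.247, 582457), 3)
  expect_equal(round(sqrt(0.247 / r2), 3), 1.191)
  ea <- attenuation_rho(0.133, 0.110, se_h2 = 0.003)
  expect_equal(round(ea$rho, 3), 1.100)
  expect_equal(round(ea$se, 3), 0.012)
  expect_equal(attenuation_rho(0.3, 0.3)$rho, 1)
  expect_error(attenuation_rho(0.1, 0.2), "r2")
  # full propagation through R2(h2) differs from the fixed-R2 convention
  full <- attenuation_rho(0.133, 0.110, se_h2 = 0.003, n = 2155939,
                          propagate_r2 = TRUE)
  expect_false(isTRUE(all.equal(full$se, ea$se)))
})

test_that("rho decreases monotonically in the GWAS sample size", {
  ns <- c(1e4, 1e5, 1e6, 1e7)
  rhos <- vapply(ns, function(n) {
    attenuation_rho(0.2, expected_r2(0.2, n))$rho
  }, numeric(1))
  expect_true(all(diff(rhos) < 0))
  expect_gt(min(rhos), 1)
})

test_that("bias factor and coefficient correction match published arithmetic", {
  ea <- attenuation_rho(0.133, 0.110, se_h2 = 0.003)
  bf <- bias_factor(0.859, 0.028, round(ea$rho, 3), round(ea$se, 3))
  expect_equal(round(bf$factor, 3), 0.781)
  expect_equal(round(bf$se, 3), 0.027)
  expect_equal(bias_factor(1, rho = 1)$factor, 1)
  expect_error(bias_factor(0, rho = 1.2), "corr")
  cc <- correct_coefficients(0.4, se = 0.05, factor = 0.8)
  expect_equal(cc$estimate, 0.5)
  expect_equal(cc$se, 0.0625)
  expect_equal(correct_coefficients(0.4, factor = 1)$estimate, 0.4)
  expect_error(correct_coefficients(0.4, factor = 0), "factor")
  # special-case reductions: corr = 1 leaves the pure errors-in-variables
  # correction, rho = 1 the pure mu-vs-gamma correction
  expect_equal(bias_factor(1, rho = 1.25)$factor, 1 / 1.25)
  expect_equal(bias_factor(0.9, rho = 1)$factor, 0.9)
})

test_that("report SEs agree with a numeric-gradient delta oracle", {
  rows <- repository_bias_inputs()
  rep_full <- attenuation_report(rows, chain_rounded = FALSE)
  for (i in c(1, 4, 8)) {
    h2 <- rows$h2[i]; n <- rows$n[i]; corr <- rows$corr[i]
    # factor as a function of (h2, corr) with R2 held at its point value
    r2 <- expected_r2(h2, n)
    f <- function(h, c_) c_ / sqrt(h / r2)
    eps <- 1e-7
    gh <- (f(h2 + eps, corr) - f(h2 - eps, corr)) / (2 * eps)
    gc <- (f(h2, corr + eps) - f(h2, corr - eps)) / (2 * eps)
    se_num <- sqrt(gh^2 * rows$se_h2[i]^2 + gc^2 * rows$se_corr[i]^2)
    expect_equal(rep_full$se_bias_factor[i], se_num, tolerance = 1e-6)
  }
})

test_that("attenuation grid ties simulated to theoretical bias", {
  # one cell of the grid at reduced scale: the simulated coefficient ratio
  # tracks corr/rho measured on the same data
  ratios <- preds <- numeric(8)
  for (r in 1:8) {
    panel <- random_snp_panel(250, seed = 230 + r, theta_prop = 0.3,
                              theta_orth_sd = 0.5)
    gw <- simulate_trio_cohort(6000, panel, seed = 330 + r, parents = "sum")
    gph <- simulate_phenotype(gw, panel, h2_direct = 0.25, seed = 430 + r)
    ss <- run_population_gwas(gw, gph)
    dec <- attr(gph, "decomposition")
    h2mu <- var(drop(gw$dosage %*% (dec$gamma_scaled + dec$theta_scaled))) /
      var(gph$y)
    tc <- simulate_trio_cohort(1500, panel, seed = 530 + r)
    tph <- simulate_phenotype(tc, panel, h2_direct = 0.25, seed = 630 + r)
    p1 <- pgi_by_role(tc, make_weightset(ss))
    p2 <- pgi_by_role(tc, weightset_from_panel(panel, "gamma"))
    b1 <- fit_causal_effect(tph, p1)
    b2 <- fit_causal_effect(tph, p2)
    r2emp <- cor(tph$y[match(p1$individual_id, tph$individual_id)],
                 p1$pgi_proband)^2
    ratios[r] <- b1$estimate / b2$estimate
    preds[r] <- snp_factor_correlation(panel, tc) / sqrt(h2mu / r2emp)
  }
  z <- mean(ratios - preds) / (sd(ratios - preds) / sqrt(8))
  expect_lt(abs(z), 3)
})

test_that("assortative mating attenuates at least as much as theory", {
  # spousal correlation 0.4 on the mating phenotype: simulated ratio does
  # not exceed the random-mating prediction beyond Monte-Carlo error
  diffs <- numeric(6)
  for (r in 1:6) {
    panel <- random_snp_panel(200, seed = 240 + r, theta_prop = 0.3,
                              theta_orth_sd = 0.5)
    f <- simulate_founders(16000, panel, seed = 340 + r)
    fp <- simulate_phenotype(f, panel, h2_direct = 0.25, seed = 440 + r)
    mates <- pair_mates(f, fp, spousal_corr = 0.4, seed = 540 + r)
    gw <- meiosis_transmit(mates[1:6000, ], f, n_children = 1,
                           seed = 640 + r)
    gph <- simulate_phenotype(gw, panel, h2_direct = 0.25, seed = 740 + r)
    gph1 <- gph[gph$individual_id %in%
                  gw$ped$individual_id[gw$ped$role == "proband"], ]
    ss <- run_population_gwas(gw, gph1)
    dec <- attr(gph, "decomposition")
    kids <- gw$ped$individual_id[gw$ped$role == "proband"]
    h2mu <- var(drop(gw$dosage[kids, ] %*%
                       (dec$gamma_scaled + dec$theta_scaled))) / var(gph$y)
    tc <- meiosis_transmit(mates[6001:7500, ], f, n_children = 1,
                           seed = 840 + r)
    tph <- simulate_phenotype(tc, panel, h2_direct = 0.25, seed = 940 + r)
    p1 <- pgi_by_role(tc, make_weightset(ss))
    p2 <- pgi_by_role(tc, weightset_from_panel(panel, "gamma"))
    b1 <- fit_causal_effect(tph, p1)
    b2 <- fit_causal_effect(tph, p2)
    r2emp <- cor(tph$y[match(p1$individual_id, tph$individual_id)],
                 p1$pgi_proband)^2
    tkids <- tc$ped$individual_id[tc$ped$role == "proband"]
    corr_emp <- cor(drop(tc$dosage[tkids, ] %*% panel$gamma),
                    drop(tc$dosage[tkids, ] %*% panel$mu))
    diffs[r] <- b1$estimate / b2$estimate - corr_emp / sqrt(h2mu / r2emp)
  }
  # ratio <= prediction (attenuation at least as strong), up to MC error
  expect_lt(mean(diffs), 3 * sd(diffs) / sqrt(6))
})

test_that("the report reproduces the published table by chained rounding", {
  rep3 <- attenuation_report(repository_bias_inputs())
  ea <- rep3[rep3$phenotype == "Educational Attainment", ]
  expect_equal(ea$r2, 0.110)
  expect_equal(ea$rho, 1.100)
  expect_equal(ea$se_rho, 0.012)
  expect_equal(ea$bias_factor, 0.781)
  expect_equal(ea$se_bias_factor, 0.027)
  ht <- rep3[rep3$phenotype == "Height", ]
  expect_equal(unlist(ht[c("r2", "rho", "bias_factor")], use.names = FALSE),
               c(0.216, 1.034, 0.938))
})
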