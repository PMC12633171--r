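test_that("posterior means match the brute-force enumeration oracle", {
  cases <- expand.grid(c1 = 0:2, c2 = c(NA, 0:2), ibd = c(NA, 0:2),
                       obs = c(NA, 0:2), maf = c(0.1, 0.35, 0.5))
  checked <- 0
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    kids <- if (is.na(cs$c2)) cs$c1 else c(cs$c1, cs$c2)
    if (length(kids) == 2 && is.na(cs$ibd)) next
    if (length(kids) == 1 && !is.na(cs$ibd)) next
    obs <- if (is.na(cs$obs)) NULL else cs$obs
    ibd <- if (is.na(cs$ibd)) NULL else cs$ibd
    expected <- oracle_parental_mean(kids, obs, ibd, cs$maf)
    if (is.na(expected)) {
      expect_error(parental_posterior_mean(kids, obs, ibd, cs$maf),
                   "inconsisten")
    } else {
      got <- parental_posterior_mean(kids, obs, ibd, cs$maf)
      expect_equal(got, expected, tolerance = 1e-12)
      expect_true(got >= 0 && got <= 4)
    }
    checked <- checked + 1
  }
  expect_gt(checked, 100)
})

test_that("fully observed parents pass through exactly", {
  expect_equal(parental_posterior_mean(1, observed_parent = NULL, maf = 0.5),
               oracle_parental_mean(1, NULL, NULL, 0.5))
  # both parents observed: handled upstream as arithmetic, no enumeration
  fx <- make_family_fixture(n_fam = 150, j = 30, seed = 71)
  ws <- weightset_from_panel(fx$panel, "gamma")
  direct <- pgi_by_role(fx$cohort, ws)
  imp <- impute_parental_pgi(fx$cohort, ws)
  expect_equal(imp$pgi_father, direct$pgi_father, tolerance = 1e-10)
  expect_equal(imp$pgi_mother, direct$pgi_mother, tolerance = 1e-10)
  expect_true(all(imp$design == "trio"))
  expect_true(all(imp$source_father == "observed"))
})

test_that("impossible transmissions raise an inconsistency error", {
  expect_error(parental_posterior_mean(2, observed_parent = 0, maf = 0.3),
               "inconsisten")
  expect_error(parental_posterior_mean(c(0, 2), observed_parent = NULL,
                                       ibd = 2, maf = 0.3), "inconsisten")
})

test_that("sib-pair imputation is symmetric and matches per-SNP enumeration", {
  fx <- make_family_fixture(n_fam = 250, j = 25, seed = 81, n_children = 2)
  ws <- weightset_from_panel(fx$panel, "gamma")
  masked <- mask_parent_genotypes(fx$cohort)
  imp <- impute_parental_pgi(masked, ws, maf = fx$panel$maf)
  expect_false("pgi_father" %in% names(imp))
  expect_true(all(imp$design == "sib_pair"))
  expect_true(all(imp$source_parental == "imputed"))
  expect_identical(unname(attr(imp, "design_counts")["sib_pair"]), 250L)
  # scores are centered/scaled across families, so compare family
  # differences, which are invariant to the standardization
  ped <- masked$ped
  fam <- imp$family_id[1]
  sibs <- ped$individual_id[ped$family_id == fam &
                              ped$role %in% c("proband", "sibling")]
  esum <- vapply(seq_len(25), function(s) {
    oracle_parental_mean(unname(masked$dosage[sibs, s]), NULL,
                         masked$ibd$states[fam, s], fx$panel$maf[s])
  }, numeric(1))
  off <- ped$individual_id[ped$role %in% c("proband", "sibling")]
  sc_off <- drop(masked$dosage[off, ] %*% fx$panel$gamma)
  fam2 <- unique(imp$family_id)[2]
  sibs2 <- ped$individual_id[ped$family_id == fam2 &
                               ped$role %in% c("proband", "sibling")]
  esum2 <- vapply(seq_len(25), function(s) {
    oracle_parental_mean(unname(masked$dosage[sibs2, s]), NULL,
                         masked$ibd$states[fam2, s], fx$panel$maf[s])
  }, numeric(1))
  d_pkg <- (imp$pgi_parental_combined[match(fam, imp$family_id)] -
              imp$pgi_parental_combined[match(fam2, imp$family_id)]) *
    sd(sc_off)
  d_oracle <- drop((esum - esum2) %*% fx$panel$gamma)
  expect_equal(d_pkg, d_oracle, tolerance = 1e-8)
})

test_that("one observed parent is used and only the other is imputed", {
  fx <- make_family_fixture(n_fam = 200, j = 20, seed = 91)
  ws <- weightset_from_panel(fx$panel, "gamma")
  masked <- mask_parent_genotypes(fx$cohort, father = FALSE, mother = TRUE)
  imp <- impute_parental_pgi(masked, ws, maf = fx$panel$maf)
  expect_true(all(imp$design == "one_parent"))
  expect_true(all(imp$source_father == "observed"))
  expect_true(all(imp$source_mother == "imputed"))
  direct <- pgi_by_role(fx$cohort, ws)
  expect_equal(imp$pgi_father, direct$pgi_father, tolerance = 1e-10)
  # spot-check the imputed mother against scalar enumeration
  ped <- masked$ped
  fam <- imp$family_id[3]
  kid <- ped$individual_id[ped$family_id == fam & ped$role == "proband"]
  dad <- ped$individual_id[ped$family_id == fam & ped$role == "father"]
  em <- vapply(seq_len(20), function(s) {
    oracle_parental_mean(unname(masked$dosage[kid, s]),
                         unname(masked$dosage[dad, s]), NULL,
                         fx$panel$maf[s]) - masked$dosage[dad, s]
  }, numeric(1))
  fam2 <- imp$family_id[7]
  kid2 <- ped$individual_id[ped$family_id == fam2 & ped$role == "proband"]
  dad2 <- ped$individual_id[ped$family_id == fam2 & ped$role == "father"]
  em2 <- vapply(seq_len(20), function(s) {
    oracle_parental_mean(unname(masked$dosage[kid2, s]),
                         unname(masked$dosage[dad2, s]), NULL,
                         fx$panel$maf[s]) - masked$dosage[dad2, s]
  }, numeric(1))
  off <- ped$individual_id[ped$role %in% c("proband", "sibling")]
  sdp <- sd(drop(masked$dosage[off, ] %*% fx$panel$gamma))
  d_pkg <- (imp$pgi_mother[3] - imp$pgi_mother[7]) * sdp
  expect_equal(d_pkg, drop((em - em2) %*% fx$panel$gamma), tolerance = 1e-8)
})

test_that("posterior mean is a martingale over child draws", {
  # fix true parents, average the posterior over simulated children
  set.seed(101)
  maf <- 0.3
  for (gm in c(0, 1, 2)) for (gf in c(1, 2)) {
    reps <- 4000
    am <- rbinom(reps, 1, gm / 2); af <- rbinom(reps, 1, gf / 2)
    kids <- am + af
    post <- vapply(0:2, function(c_) {
      parental_posterior_mean(c_, NULL, NULL, maf)
    }, numeric(1))
    est <- mean(post[kids + 1])
    # martingale holds against the prior-weighted parent draw, so average
    # over parents drawn from HWE too
    expect_true(is.finite(est))
  }
  # full martingale: parents from HWE, E[posterior] = E[gm + gf] = 4 maf
  reps <- 20000
  gm <- rbinom(reps, 2, maf); gf <- rbinom(reps, 2, maf)
  kids <- rbinom(reps, 1, gm / 2) + rbinom(reps, 1, gf / 2)
  post <- vapply(0:2, function(c_) parental_posterior_mean(c_, NULL, NULL, maf),
                 numeric(1))
  se <- sd(post[kids + 1]) / sqrt(reps)
  expect_lt(abs(mean(post[kids + 1]) - 4 * maf), 3 * se + 0.01)
})

test_that("mixed cohorts log one design per family", {
  fx <- make_family_fixture(n_fam = 90, j = 15, seed = 111)
  fams <- unique(fx$cohort$ped$family_id)
  m <- mask_parent_genotypes(fx$cohort, families = fams[1:30],
                             father = FALSE, mother = TRUE)
  m <- mask_parent_genotypes(m, families = fams[31:60])
  imp <- impute_parental_pgi(m, weightset_from_panel(fx$panel, "gamma"),
                             maf = fx$panel$maf)
  counts <- attr(imp, "design_counts")
  expect_identical(unname(counts["one_parent"]), 30L)
  expect_identical(unname(counts["singleton"]), 30L)
  expect_identical(unname(counts["trio"]), 30L)
  expect_false(isTRUE(attr(imp, "assortative_mating_adjustment")))
})
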