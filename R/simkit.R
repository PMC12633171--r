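#' SNP panel constructor
#'
#' A SNP panel holds per-SNP allele frequencies together with the true
#' per-allele effect sizes used by the phenotype generator: `gamma` is the
#' direct (causal) effect of the individual's own allele count, `theta` the
#' effect of the summed parental allele count (genetic nurture / confounding).
#' The population-GWAS estimand is their sum, `mu = gamma + theta`.
#'
#' @param maf numeric vector of effect-allele frequencies, each in (0, 0.5].
#' @param gamma numeric vector of direct effects (per effect allele).
#' @param theta numeric vector of parental-genotype effects. Default 0.
#' @param snp_id character ids; generated as `snp0001, ...` when missing.
#' @param effect_allele,other_allele allele codes (recycled).
#' @return A `snp_panel` data frame with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `maf`, `gamma`, `theta`, `mu`.
#' @export
snp_panel <- function(maf, gamma, theta = 0, snp_id = NULL,
                      effect_allele = "A", other_allele = "G") {
  j <- length(maf)
  stopifnot(j >= 1)
  if (any(!is.finite(maf)) || any(maf <= 0) || any(maf > 0.5)) {
    stop("maf must lie in (0, 0.5]")
  }
  gamma <- rep_len(as.numeric(gamma), j)
  theta <- rep_len(as.numeric(theta), j)
  if (any(!is.finite(gamma)) || any(!is.finite(theta))) {
    stop("gamma and theta must be finite")
  }
  if (is.null(snp_id)) snp_id <- sprintf("snp%04d", seq_len(j))
  out <- data.frame(
    snp_id = as.character(snp_id),
    effect_allele = rep_len(effect_allele, j),
    other_allele = rep_len(other_allele, j),
    maf = as.numeric(maf),
    gamma = gamma,
    theta = theta,
    mu = gamma + theta,
    stringsAsFactors = FALSE
  )
  class(out) <- c("snp_panel", "data.frame")
  out
}

#' Draw a random SNP panel
#'
#' Allele frequencies are uniform on `maf_range`; direct effects are iid
#' Gaussian. The parental effect is `theta = theta_prop * gamma + e` with
#' `e ~ N(0, theta_orth_sd^2)`, so both a component proportional to the
#' direct effects and one orthogonal to them (in effect space) can be
#' requested. Effect scales are nominal: `simulate_phenotype()` rescales
#' them to hit the requested variance shares.
#'
#' @param n_snps number of unlinked biallelic SNPs.
#' @param seed integer seed.
#' @param maf_range length-2 numeric, within (0, 0.5].
#' @param theta_prop scalar multiplier on `gamma` entering `theta`.
#' @param theta_orth_sd sd of the `gamma`-independent component of `theta`.
#' @return A [snp_panel()].
#' @export
random_snp_panel <- function(n_snps, seed, maf_range = c(0.05, 0.5),
                             theta_prop = 0, theta_orth_sd = 0) {
  stopifnot(n_snps >= 1, length(maf_range) == 2)
  withr::with_seed(seed, {
    maf <- stats::runif(n_snps, maf_range[1], maf_range[2])
    gamma <- stats::rnorm(n_snps)
    theta <- theta_prop * gamma +
      if (theta_orth_sd > 0) stats::rnorm(n_snps, sd = theta_orth_sd) else 0
  })
  snp_panel(maf = maf, gamma = gamma, theta = theta)
}

new_family_cohort <- function(dosage, ped, panel,
                              parent_observed = NULL, ibd = NULL, seed = NA) {
  stopifnot(nrow(dosage) == nrow(ped), ncol(dosage) == nrow(panel))
  rownames(dosage) <- ped$individual_id
  colnames(dosage) <- panel$snp_id
  structure(
    list(dosage = dosage, ped = ped, panel = panel,
         parent_observed = parent_observed, ibd = ibd, seed = seed),
    class = "family_cohort"
  )
}

#' @export
print.family_cohort <- function(x, ...) {
  cat("family_cohort:", nrow(x$ped), "individuals,",
      length(unique(x$ped$family_id)), "families,",
      ncol(x$dosage), "SNPs\n")
  cat("roles:", paste(names(table(x$ped$role)), table(x$ped$role),
                      sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# dosage draw for n individuals under HWE: sum of two Bernoulli(maf) alleles,
# columns are SNPs. Kept as an integer matrix to bound memory at GWAS scale.
hwe_dosage <- function(n, maf) {
  j <- length(maf)
  p <- rep(maf, each = n)
  matrix(stats::rbinom(n * j, 2L, p), nrow = n, ncol = j)
}

#' Simulate unrelated founders under Hardy-Weinberg equilibrium
#'
#' Each dosage is the sum of two independent Bernoulli(maf) alleles,
#' independent across SNPs (unlinked panel). Sexes alternate 1/2 so the
#' founder pool always splits evenly for mating.
#'
#' @param n number of founders (>= 2).
#' @param panel a [snp_panel()].
#' @param seed integer seed.
#' @return A `family_cohort` with roles `"unrelated"`; each founder is their
#'   own family.
#' @export
simulate_founders <- function(n, panel, seed) {
  stopifnot(inherits(panel, "snp_panel"))
  if (length(n) != 1 || n < 2) stop("n must be a single count >= 2")
  dosage <- withr::with_seed(seed, hwe_dosage(n, panel$maf))
  ids <- sprintf("U%06d", seq_len(n))
  ped <- data.frame(
    individual_id = ids,
    family_id = ids,
    father_id = NA_character_,
    mother_id = NA_character_,
    sex = rep_len(c(1L, 2L), n),
    role = "unrelated",
    stringsAsFactors = FALSE
  )
  new_family_cohort(dosage, ped, panel, seed = seed)
}

#' Pair founders into mating couples, optionally assortatively
#'
#' Random mating when `spousal_corr = 0`. Otherwise mates are matched by the
#' rank of their mating phenotype perturbed with Gaussian noise; the noise
#' scale is calibrated by bisection so the realized spousal phenotype
#' correlation is within `tol` of the target. With heavily discretized
#' phenotypes the rank-matching ceiling may fall short of the target, in
#' which case a warning reports the best achievable correlation.
#'
#' @param founders a founder `family_cohort`.
#' @param phenotype a phenotype table (from [simulate_phenotype()]) giving
#'   the mating phenotype `y` per founder.
#' @param spousal_corr target spousal phenotype correlation in `[0, 1)`.
#' @param seed integer seed.
#' @param tol calibration tolerance on the realized correlation.
#' @return A data frame with one row per couple (`father_id`, `mother_id`)
#'   and attribute `realized_corr`.
#' @export
pair_mates <- function(founders, phenotype, spousal_corr = 0, seed,
                       tol = 0.03) {
  stopifnot(inherits(founders, "family_cohort"))
  if (spousal_corr < 0 || spousal_corr >= 1) stop("spousal_corr must be in [0, 1)")
  ped <- founders$ped
  males <- ped$individual_id[ped$sex == 1L]
  females <- ped$individual_id[ped$sex == 2L]
  k <- min(length(males), length(females))
  males <- males[seq_len(k)]
  females <- females[seq_len(k)]
  y <- phenotype$y[match(ped$individual_id, phenotype$individual_id)]
  names(y) <- ped$individual_id

  withr::with_seed(seed, {
    if (spousal_corr == 0) {
      pairs <- data.frame(father_id = sample(males),
                          mother_id = sample(females),
                          stringsAsFactors = FALSE)
      rc <- stats::cor(y[pairs$father_id], y[pairs$mother_id])
    } else {
      sdy <- stats::sd(y, na.rm = TRUE)
      match_at <- function(noise_sd) {
        zm <- y[males] + stats::rnorm(k, sd = noise_sd)
        zf <- y[females] + stats::rnorm(k, sd = noise_sd)
        data.frame(father_id = males[order(zm)],
                   mother_id = females[order(zf)],
                   stringsAsFactors = FALSE)
      }
      realized <- function(p) stats::cor(y[p$father_id], y[p$mother_id])
      # noisy rank matching: matched perturbed ranks give spousal correlation
      # about 1/(1 + k^2) for noise sd = k * sd(y); bisect on k around that
      k0 <- sqrt(max(1 / spousal_corr - 1, 1e-8))
      lo <- 0; hi <- 4 * k0 + 1
      pairs <- match_at(k0 * sdy); rc <- realized(pairs)
      iter <- 0
      while (abs(rc - spousal_corr) > tol && iter < 40) {
        if (rc > spousal_corr) lo <- k0 else hi <- k0
        k0 <- (lo + hi) / 2
        pairs <- match_at(k0 * sdy); rc <- realized(pairs)
        iter <- iter + 1
      }
      if (abs(rc - spousal_corr) > tol) {
        # ceiling check: perfect rank matching is the max achievable
        best <- realized(match_at(0))
        if (best < spousal_corr) {
          warning(sprintf(
            "target spousal correlation %.3f not achievable; best %.3f",
            spousal_corr, best))
          pairs <- match_at(0); rc <- best
        }
      }
    }
  })
  attr(pairs, "realized_corr") <- rc
  pairs
}

#' Transmit alleles from mated parents to children
#'
#' Each child receives, at every SNP independently, one allele drawn
#' uniformly from each parent's two alleles. For two-children families the
#' per-SNP IBD state (0/1/2 shared parental haplotypes) is recorded from the
#' transmitted haplotype identities.
#'
#' @param mates couple table from [pair_mates()].
#' @param founders the founder `family_cohort` holding parental genotypes.
#' @param n_children 1 or 2 children per family.
#' @param seed integer seed.
#' @return A `family_cohort` containing parents (roles `father`/`mother`)
#'   and children (role `proband`, second child `sibling`), with
#'   `parent_observed` flags (all TRUE) and, for `n_children = 2`, an `ibd`
#'   element: list(pairs = data.frame(family_id, sib1, sib2),
#'   states = matrix families x SNPs).
#' @export
meiosis_transmit <- function(mates, founders, n_children = 1, seed) {
  if (!n_children %in% c(1L, 2L)) stop("n_children must be 1 or 2")
  panel <- founders$panel
  nf <- nrow(mates)
  j <- nrow(panel)
  gf <- founders$dosage[mates$father_id, , drop = FALSE]
  gm <- founders$dosage[mates$mother_id, , drop = FALSE]
  fam <- sprintf("FAM%05d", seq_len(nf))

  withr::with_seed(seed, {
    if (n_children == 1L) {
      # single child: the transmitted allele from a parent with dosage g is
      # Bernoulli(g/2), exact for unlinked loci (no IBD bookkeeping needed)
      af <- stats::rbinom(nf * j, 1L, as.vector(gf) / 2)
      am <- stats::rbinom(nf * j, 1L, as.vector(gm) / 2)
      c1 <- list(dosage = matrix(af + am, nf, j))
      c2 <- NULL
    } else {
      # split each unphased parent genotype into two haplotype alleles:
      # for g=1 the order is random, so haplotype indices are exchangeable
      hap_split <- function(g) {
        a1 <- matrix(0L, nf, j)
        a1[g == 2L] <- 1L
        het <- g == 1L
        a1[het] <- stats::rbinom(sum(het), 1L, 0.5)
        list(a1, g - a1)
      }
      hf <- hap_split(gf)
      hm <- hap_split(gm)
      draw_child <- function() {
        # pick haplotype index per parent per SNP
        if_ <- matrix(stats::rbinom(nf * j, 1L, 0.5), nf, j)
        im_ <- matrix(stats::rbinom(nf * j, 1L, 0.5), nf, j)
        af <- hf[[1]] * (1L - if_) + hf[[2]] * if_
        am <- hm[[1]] * (1L - im_) + hm[[2]] * im_
        list(dosage = af + am, idx_f = if_, idx_m = im_)
      }
      c1 <- draw_child()
      c2 <- draw_child()
    }
  })

  roles <- c("father", "mother", "proband", if (n_children == 2L) "sibling")
  id_f <- sprintf("%s_F", fam); id_m <- sprintf("%s_M", fam)
  id_c1 <- sprintf("%s_C1", fam)
  id_c2 <- if (n_children == 2L) sprintf("%s_C2", fam) else NULL
  dosage <- rbind(gf, gm, c1$dosage, if (n_children == 2L) c2$dosage)
  ped <- data.frame(
    individual_id = c(id_f, id_m, id_c1, id_c2),
    family_id = rep(fam, 2L + n_children),
    father_id = c(rep(NA_character_, 2 * nf), rep(id_f, n_children)),
    mother_id = c(rep(NA_character_, 2 * nf), rep(id_m, n_children)),
    sex = c(rep(1L, nf), rep(2L, nf),
            rep_len(c(1L, 2L), nf * n_children)),
    role = rep(roles, each = nf),
    stringsAsFactors = FALSE
  )
  parent_observed <- data.frame(family_id = fam, father = TRUE, mother = TRUE,
                                stringsAsFactors = FALSE)
  ibd <- NULL
  if (n_children == 2L) {
    states <- (c1$idx_f == c2$idx_f) + (c1$idx_m == c2$idx_m)
    storage.mode(states) <- "double"
    rownames(states) <- fam
    ibd <- list(pairs = data.frame(family_id = fam, sib1 = id_c1, sib2 = id_c2,
                                   stringsAsFactors = FALSE),
                states = states)
  }
  new_family_cohort(dosage, ped, panel, parent_observed, ibd, seed)
}

#' Fast random-mating trio cohort
#'
#' Fused generator for large simulation studies: draws, for every family
#' and SNP independently, the joint (father, mother, child) genotype
#' configuration from its exact 27-cell distribution under HWE parents and
#' Mendelian transmission. Equivalent in distribution to
#' [simulate_founders()] + [pair_mates()] at zero spousal correlation +
#' [meiosis_transmit()] with one child, but with one categorical draw per
#' individual-SNP. Two-children families fall back to the general
#' haplotype-tracking path (which also records IBD states).
#'
#' @param n_families number of families.
#' @param panel a [snp_panel()].
#' @param n_children 1 (fused path) or 2 (general path).
#' @param seed integer seed.
#' @param parents `"full"` stores father and mother genotype rows;
#'   `"sum"` stores only the per-child parental dosage sum (matrix
#'   `parental_sum`), enough for phenotype generation at a third of the
#'   memory — used for large GWAS training cohorts where parental PGIs are
#'   never scored.
#' @return A `family_cohort` with father/mother/offspring rows (or
#'   offspring rows plus `parental_sum` when `parents = "sum"`).
#' @export
simulate_trio_cohort <- function(n_families, panel, n_children = 1, seed,
                                 parents = c("full", "sum")) {
  stopifnot(inherits(panel, "snp_panel"), n_families >= 1)
  parents <- match.arg(parents)
  if (n_children == 2L) {
    founders <- simulate_founders(2 * n_families, panel,
                                  seed = (seed * 7 + 1) %% .Machine$integer.max)
    ped <- founders$ped
    mates <- data.frame(father_id = ped$individual_id[ped$sex == 1L],
                        mother_id = ped$individual_id[ped$sex == 2L],
                        stringsAsFactors = FALSE)
    return(meiosis_transmit(mates, founders, n_children = 2L, seed = seed))
  }
  j <- nrow(panel)
  tb <- get_mendel_tables()
  n <- n_families
  fam <- sprintf("FAM%05d", seq_len(n))
  id_c <- sprintf("%s_C1", fam)
  if (parents == "sum") {
    # 15-cell joint over (child, parental sum), child varying fastest
    cs <- expand.grid(c = 0:2, gm = 0:2, gf = 0:2)
    key <- cs$c + 3L * (cs$gm + cs$gf)              # c + 3*s, in 0:14
    probs <- vapply(seq_len(j), function(s) {
      pg <- hwe_prior(panel$maf[s])
      w <- tb$L1[cbind(cs$c + 1, cs$gm + 1, cs$gf + 1)] *
        pg[cs$gm + 1] * pg[cs$gf + 1]
      as.vector(tapply(w, key, sum))
    }, numeric(15))
    withr::with_seed(seed, {
      idx <- vapply(seq_len(j), function(s) {
        sample.int(15L, n, replace = TRUE, prob = probs[, s])
      }, integer(n)) - 1L
    })
    child <- idx %% 3L
    psum <- idx %/% 3L
    ped <- data.frame(
      individual_id = id_c, family_id = fam,
      father_id = NA_character_, mother_id = NA_character_,
      sex = rep_len(c(1L, 2L), n), role = "proband",
      stringsAsFactors = FALSE)
    out <- new_family_cohort(child, ped, panel, NULL, NULL, seed)
    colnames(psum) <- panel$snp_id
    out$parental_sum <- psum
    return(out)
  }
  # 27-cell joint over (child, mother, father), child varying fastest
  cell <- expand.grid(c = 0:2, gm = 0:2, gf = 0:2)
  probs <- vapply(seq_len(j), function(s) {
    pg <- hwe_prior(panel$maf[s])
    tb$L1[cbind(cell$c + 1, cell$gm + 1, cell$gf + 1)] *
      pg[cell$gm + 1] * pg[cell$gf + 1]
  }, numeric(27))
  withr::with_seed(seed, {
    idx <- vapply(seq_len(j), function(s) {
      sample.int(27L, n, replace = TRUE, prob = probs[, s])
    }, integer(n)) - 1L
  })
  child <- idx %% 3L
  gm <- (idx %/% 3L) %% 3L
  gf <- idx %/% 9L
  id_f <- sprintf("%s_F", fam); id_m <- sprintf("%s_M", fam)
  dosage <- rbind(gf, gm, child)
  ped <- data.frame(
    individual_id = c(id_f, id_m, id_c),
    family_id = rep(fam, 3L),
    father_id = c(rep(NA_character_, 2 * n), id_f),
    mother_id = c(rep(NA_character_, 2 * n), id_m),
    sex = c(rep(1L, n), rep(2L, n), rep_len(c(1L, 2L), n)),
    role = rep(c("father", "mother", "proband"), each = n),
    stringsAsFactors = FALSE
  )
  parent_observed <- data.frame(family_id = fam, father = TRUE, mother = TRUE,
                                stringsAsFactors = FALSE)
  new_family_cohort(dosage, ped, panel, parent_observed, NULL, seed)
}

#' Simulate a phenotype with direct and parental genetic effects
#'
#' Generates `y = x gamma' + x_p theta' + eps` on the offspring of a family
#' cohort, where `gamma'`/`theta'` are the panel effects rescaled so the
#' direct component explains `h2_direct` of the phenotype variance (and,
#' when `parental_share` is given, the parental component explains that
#' share) in the random-mating benchmark with unit total variance. On a
#' founder cohort (no parents) the parental term is absent. Binary
#' phenotypes are generated by thresholding the latent liability at the
#' requested prevalence.
#'
#' @param cohort a `family_cohort`.
#' @param panel the matching [snp_panel()] (defaults to `cohort$panel`).
#' @param h2_direct variance share of the direct genetic component, in
#'   `[0, 1]`.
#' @param parental_share variance share of the parental component, or `NULL`
#'   to keep the panel's relative `theta` scale (theta is scaled by the same
#'   factor as gamma).
#' @param binary logical; threshold the liability.
#' @param prevalence case fraction for binary phenotypes.
#' @param seed integer seed.
#' @param subgroup optional list(`frac`, `scale`) assigning each phenotyped
#'   individual to subgroup 1 with probability `frac` and multiplying the
#'   direct genetic effect by `scale` in that subgroup, with residual
#'   variance adjusted so total phenotype variance stays 1 in both groups
#'   (uniform SNP-effect scaling at equal phenotypic variance).
#' @return A phenotype table (data frame) with columns `individual_id`,
#'   `family_id`, `y`, `age`, `sex`, and `subgroup`; attribute
#'   `decomposition` records realized variance shares and the rescaled
#'   effect vectors.
#' @export
simulate_phenotype <- function(cohort, panel = cohort$panel, h2_direct,
                               parental_share = NULL, binary = FALSE,
                               prevalence = NULL, seed, subgroup = NULL) {
  stopifnot(inherits(cohort, "family_cohort"))
  if (h2_direct < 0 || h2_direct > 1) stop("h2_direct must be in [0, 1]")
  if (!is.null(parental_share) && h2_direct + parental_share > 1) {
    stop("infeasible variance targets: h2_direct + parental_share > 1")
  }
  ped <- cohort$ped
  offspring <- ped$role %in% c("proband", "sibling")
  has_parents <- any(offspring)
  who <- if (has_parents) which(offspring) else seq_len(nrow(ped))
  all_rows <- length(who) == nrow(ped) && !is.unsorted(who)
  x <- if (all_rows) cohort$dosage else cohort$dosage[who, , drop = FALSE]
  g0 <- drop(x %*% panel$gamma)
  if (!is.null(cohort$parental_sum)) {
    ps <- if (all_rows) cohort$parental_sum else {
      cohort$parental_sum[match(ped$individual_id[who],
                                rownames(cohort$dosage)), , drop = FALSE]
    }
    gp0 <- drop(ps %*% panel$theta)
  } else if (has_parents && !all(is.na(ped$father_id[who]))) {
    xp <- cohort$dosage[ped$father_id[who], , drop = FALSE] +
      cohort$dosage[ped$mother_id[who], , drop = FALSE]
    gp0 <- drop(xp %*% panel$theta)
  } else {
    gp0 <- rep(0, length(g0))
  }
  vg <- stats::var(g0)
  if (h2_direct > 0 && vg == 0) stop("direct genetic variance is zero")
  a <- if (h2_direct > 0) sqrt(h2_direct / vg) else 0
  vgp <- stats::var(gp0)
  b <- if (!is.null(parental_share)) {
    if (parental_share > 0 && vgp == 0) stop("parental genetic variance is zero")
    if (parental_share > 0) sqrt(parental_share / vgp) else 0
  } else a
  gl <- a * g0
  gpl <- b * gp0
  var_eps <- 1 - stats::var(gl + gpl)
  if (var_eps <= 0) {
    stop("infeasible variance targets: genetic components exceed unit variance")
  }
  n <- length(gl)
  withr::with_seed(seed, {
    eps <- stats::rnorm(n, sd = sqrt(var_eps))
    age <- round(stats::runif(n, 30, 70))
    m <- if (!is.null(subgroup)) {
      stats::rbinom(n, 1L, subgroup$frac %||% 0.5)
    } else rep(0L, n)
  })
  if (!is.null(subgroup)) {
    k <- subgroup$scale %||% 1
    # scale direct effects in group 1; rescale its noise so Var(y) stays 1
    ve1 <- 1 - stats::var(k * gl + gpl)
    if (ve1 <= 0) stop("subgroup scaling makes variance targets infeasible")
    y <- ifelse(m == 1L, k * gl + gpl + eps * sqrt(ve1 / var_eps),
                gl + gpl + eps)
  } else {
    y <- gl + gpl + eps
  }
  if (binary) {
    if (is.null(prevalence)) stop("prevalence required for binary phenotypes")
    thr <- mean(y) + stats::qnorm(1 - prevalence) * stats::sd(y)
    y <- as.integer(y > thr)
  }
  out <- data.frame(
    individual_id = ped$individual_id[who],
    family_id = ped$family_id[who],
    y = y,
    age = age,
    sex = ped$sex[who],
    subgroup = m,
    stringsAsFactors = FALSE
  )
  attr(out, "decomposition") <- list(
    var_direct = stats::var(gl), var_parental = stats::var(gpl),
    var_eps = var_eps, cov_direct_parental = stats::cov(gl, gpl),
    h2_realized = stats::var(gl) / stats::var(y),
    gamma_scaled = a * panel$gamma, theta_scaled = b * panel$theta
  )
  out
}

#' Check Mendelian consistency of a family cohort
#'
#' Counts trio genotype configurations that are impossible under Mendelian
#' transmission (e.g. child 2 with a homozygous-other parent).
#'
#' @param cohort a `family_cohort`.
#' @return integer count of violating (individual, SNP) cells.
#' @export
count_mendel_violations <- function(cohort) {
  ped <- cohort$ped
  kids <- which(!is.na(ped$father_id))
  if (!length(kids)) return(0L)
  gc <- cohort$dosage[kids, , drop = FALSE]
  gf <- cohort$dosage[ped$father_id[kids], , drop = FALSE]
  gm <- cohort$dosage[ped$mother_id[kids], , drop = FALSE]
  # a parent with dosage g can transmit at most (g >= 1) and at least (g == 2)
  bad <- (gc > (gf >= 1) + (gm >= 1)) | (gc < (gf == 2) + (gm == 2))
  sum(bad)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
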