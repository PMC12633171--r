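# Mendelian transmission likelihood tables, built once per session by exact
# enumeration over parental haplotype choices. Unphased parents: a dosage-1
# parent carries haplotype alleles {0, 1}; children pick one of the two
# haplotypes per parent uniformly. Sibling IBD at a parent means both
# children picked the same haplotype index there.
.mendel_tables <- new.env(parent = emptyenv())

hap_alleles <- function(g) switch(g + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))

# P(child = c | gm, gf), array [c+1, gm+1, gf+1]
child_lik_table <- function() {
  L <- array(0, c(3, 3, 3))
  for (gm in 0:2) for (gf in 0:2) {
    hm <- hap_alleles(gm); hf <- hap_alleles(gf)
    for (im in 1:2) for (jf in 1:2) {
      c_ <- hm[im] + hf[jf]
      L[c_ + 1, gm + 1, gf + 1] <- L[c_ + 1, gm + 1, gf + 1] + 0.25
    }
  }
  L
}

# P(c1, c2 | ibd, gm, gf), array [c1+1, c2+1, ibd+1, gm+1, gf+1]
sib_lik_table <- function() {
  L <- array(0, c(3, 3, 3, 3, 3))
  for (gm in 0:2) for (gf in 0:2) {
    hm <- hap_alleles(gm); hf <- hap_alleles(gf)
    add <- function(share_m, share_f, wt, ibd) {
      for (im1 in 1:2) for (if1 in 1:2) {
        im2s <- if (share_m) im1 else (3L - im1)
        if2s <- if (share_f) if1 else (3L - if1)
        c1 <- hm[im1] + hf[if1]
        c2 <- hm[im2s] + hf[if2s]
        L[c1 + 1, c2 + 1, ibd + 1, gm + 1, gf + 1] <<-
          L[c1 + 1, c2 + 1, ibd + 1, gm + 1, gf + 1] + wt * 0.25
      }
    }
    add(FALSE, FALSE, 1, 0L)
    add(TRUE, FALSE, 0.5, 1L); add(FALSE, TRUE, 0.5, 1L)
    add(TRUE, TRUE, 1, 2L)
  }
  L
}

get_mendel_tables <- function() {
  if (is.null(.mendel_tables$L1)) {
    .mendel_tables$L1 <- child_lik_table()
    .mendel_tables$L2 <- sib_lik_table()
  }
  .mendel_tables
}

hwe_prior <- function(maf) c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)

#' Posterior mean of the summed parental genotype at one SNP
#'
#' Exact Bayesian enumeration: all parental genotype pairs `(g_m, g_f)` in
#' `{0,1,2}^2` receive Hardy-Weinberg priors at the given allele frequency,
#' are weighted by the Mendelian transmission likelihood of the observed
#' children (joint likelihood under the sibling IBD state for two
#' children), conditioned on an observed parent where available, and the
#' posterior expectation of `g_m + g_f` is returned.
#'
#' @param child_dosages integer vector (length 1 or 2) of child allele
#'   counts in `{0,1,2}`.
#' @param observed_parent observed parent dosage, or `NULL` when neither
#'   parent is genotyped.
#' @param ibd sibling IBD state in `{0,1,2}` (required for two children).
#' @param maf effect-allele frequency in (0, 1).
#' @return Expected parental dosage sum, in `[0, 4]`.
#' @export
parental_posterior_mean <- function(child_dosages, observed_parent = NULL,
                                    ibd = NULL, maf) {
  stopifnot(length(child_dosages) %in% 1:2,
            all(child_dosages %in% 0:2),
            maf > 0, maf < 1)
  if (length(child_dosages) == 2 && is.null(ibd)) {
    stop("ibd state required for two children")
  }
  tb <- get_mendel_tables()
  lik <- function(gm, gf) {
    if (length(child_dosages) == 1) {
      tb$L1[child_dosages[1] + 1, gm + 1, gf + 1]
    } else {
      tb$L2[child_dosages[1] + 1, child_dosages[2] + 1, ibd + 1,
            gm + 1, gf + 1]
    }
  }
  pr <- hwe_prior(maf)
  if (!is.null(observed_parent)) {
    stopifnot(observed_parent %in% 0:2)
    num <- den <- 0
    for (g in 0:2) {
      w <- pr[g + 1] * lik(observed_parent, g)
      num <- num + w * g
      den <- den + w
    }
    if (den == 0) stop("Mendelian inconsistency between children and observed parent")
    return(observed_parent + num / den)
  }
  num <- den <- 0
  for (gm in 0:2) for (gf in 0:2) {
    w <- pr[gm + 1] * pr[gf + 1] * lik(gm, gf)
    num <- num + w * (gm + gf)
    den <- den + w
  }
  if (den == 0) stop("Mendelian inconsistency in observed child genotypes")
  num / den
}

# classify family designs from the parent-observed mask and offspring counts
family_designs <- function(cohort) {
  ped <- cohort$ped
  po <- cohort$parent_observed
  fams <- unique(ped$family_id[ped$role %in% c("proband", "sibling")])
  nkids <- table(ped$family_id[ped$role %in% c("proband", "sibling")])
  fo <- po$father[match(fams, po$family_id)]
  mo <- po$mother[match(fams, po$family_id)]
  fo[is.na(fo)] <- FALSE; mo[is.na(mo)] <- FALSE
  design <- ifelse(fo & mo, "trio",
            ifelse(fo | mo, "one_parent",
            ifelse(nkids[fams] == 2, "sib_pair", "singleton")))
  data.frame(family_id = fams, design = design,
             father_observed = fo, mother_observed = mo,
             stringsAsFactors = FALSE)
}

#' Mask parental genotypes in a family cohort
#'
#' Flags the father's and/or mother's genotypes of the given families as
#' unobserved so that downstream imputation must reconstruct them. The
#' underlying simulated dosages are retained for truth comparisons but are
#' never read by [impute_parental_pgi()] for masked parents.
#'
#' @param cohort a `family_cohort`.
#' @param families family ids to mask (default all).
#' @param father,mother logical: mask that parent.
#' @return The modified cohort.
#' @export
mask_parent_genotypes <- function(cohort, families = NULL,
                                  father = TRUE, mother = TRUE) {
  po <- cohort$parent_observed
  if (is.null(families)) families <- po$family_id
  i <- po$family_id %in% families
  if (father) po$father[i] <- FALSE
  if (mother) po$mother[i] <- FALSE
  cohort$parent_observed <- po
  cohort
}

#' Impute parental PGIs by exact posterior-mean enumeration
#'
#' For every family, the expected parental genotype sum at each SNP is
#' computed by the enumeration of [parental_posterior_mean()] (vectorized
#' over families and SNPs via precomputed likelihood tables), combined
#' through the aligned weight vector, and reported next to the proband PGI
#' computed on the same SNP set. Families with both parents genotyped pass
#' their observed parental PGIs through; families with one genotyped parent
#' get that parent observed and the other imputed; sibling pairs and
#' singletons (no genotyped parent) get a single combined parental PGI,
#' since separate maternal/paternal imputation is not identified there.
#'
#' @param cohort a `family_cohort` (parent-observed mask respected).
#' @param weights a `weight_set`.
#' @param maf per-SNP allele frequencies for the Hardy-Weinberg prior;
#'   default: frequencies estimated from the genotyped (observed) rows.
#' @return A `pgi_table` with one row per offspring: `pgi_proband`, then
#'   `pgi_father`/`pgi_mother` and/or `pgi_parental_combined` (NA where not
#'   applicable), `source_*` flags (`"observed"`/`"imputed"`), and `design`;
#'   attribute `design_counts` logs families per design.
#' @export
impute_parental_pgi <- function(cohort, weights, maf = NULL) {
  ped <- cohort$ped
  panel <- cohort$panel
  al <- align_weights(panel, weights)
  keep <- which(!is.na(al$w))
  if (!length(keep)) stop("zero SNP overlap between dosage and weights")
  w <- al$w[keep]
  des <- family_designs(cohort)
  if (!nrow(des)) stop("no usable families (no genotyped offspring)")
  off <- ped[ped$role %in% c("proband", "sibling"), ]
  # allele frequency from rows whose genotypes are observed
  obs_parent_ids <- c(
    ped$individual_id[ped$role == "father" &
      ped$family_id %in% des$family_id[des$father_observed]],
    ped$individual_id[ped$role == "mother" &
      ped$family_id %in% des$family_id[des$mother_observed]])
  obs_rows <- c(off$individual_id, obs_parent_ids)
  if (is.null(maf)) {
    maf <- colMeans(cohort$dosage[obs_rows, keep, drop = FALSE]) / 2
    maf <- pmin(pmax(maf, 1e-6), 1 - 1e-6)
  } else {
    maf <- maf[keep]
  }
  j <- length(keep)
  tb <- get_mendel_tables()
  pr <- rbind((1 - maf)^2, 2 * maf * (1 - maf), maf^2)  # 3 x J

  nfam <- nrow(des)
  exp_father <- matrix(NA_real_, nfam, j)
  exp_mother <- matrix(NA_real_, nfam, j)
  exp_sum <- matrix(NA_real_, nfam, j)
  rownames(exp_father) <- rownames(exp_mother) <- rownames(exp_sum) <-
    des$family_id

  # helper: offspring dosage matrices per family set, first and second child
  kids_of <- function(fams) {
    sub <- off[off$family_id %in% fams, ]
    first <- sub[!duplicated(sub$family_id), ]
    second <- sub[duplicated(sub$family_id), ]
    idx2 <- match(fams, second$family_id)
    list(
      c1 = cohort$dosage[first$individual_id[match(fams, first$family_id)],
                         keep, drop = FALSE],
      c2 = if (nrow(second) && all(!is.na(idx2))) {
        cohort$dosage[second$individual_id[idx2], keep, drop = FALSE]
      } else NULL
    )
  }
  parent_dosage <- function(fams, role) {
    ids <- ped$individual_id[ped$role == role & ped$family_id %in% fams]
    fid <- ped$family_id[ped$role == role & ped$family_id %in% fams]
    cohort$dosage[ids[match(fams, fid)], keep, drop = FALSE]
  }
  ibd_states <- function(fams) {
    if (is.null(cohort$ibd)) stop("sibling IBD states missing from cohort")
    cohort$ibd$states[fams, keep, drop = FALSE]
  }

  # --- trio: both parents observed
  tf <- des$family_id[des$design == "trio"]
  if (length(tf)) {
    i <- match(tf, des$family_id)
    exp_father[i, ] <- parent_dosage(tf, "father")
    exp_mother[i, ] <- parent_dosage(tf, "mother")
    exp_sum[i, ] <- exp_father[i, , drop = FALSE] + exp_mother[i, , drop = FALSE]
  }

  # --- one parent observed: enumerate the missing parent's 3 genotypes
  opf <- des$family_id[des$design == "one_parent"]
  if (length(opf)) {
    i <- match(opf, des$family_id)
    obs_role <- ifelse(des$father_observed[i], "father", "mother")
    gobs <- matrix(NA_real_, length(opf), j)
    fo <- obs_role == "father"
    if (any(fo)) gobs[fo, ] <- parent_dosage(opf[fo], "father")
    if (any(!fo)) gobs[!fo, ] <- parent_dosage(opf[!fo], "mother")
    kd <- kids_of(opf)
    two <- !is.null(kd$c2)
    snp_idx <- rep(seq_len(j), each = length(opf))
    num <- den <- 0
    for (g in 0:2) {
      likg <- if (two) {
        ib <- ibd_states(opf)
        array_lik <- tb$L2[cbind(as.vector(kd$c1) + 1, as.vector(kd$c2) + 1,
                                 as.vector(ib) + 1, as.vector(gobs) + 1, g + 1)]
        array_lik
      } else {
        tb$L1[cbind(as.vector(kd$c1) + 1, as.vector(gobs) + 1, g + 1)]
      }
      wgt <- pr[g + 1, snp_idx] * likg
      num <- num + wgt * g
      den <- den + wgt
    }
    if (any(den == 0)) stop("Mendelian inconsistency in one-parent family")
    emiss <- matrix(num / den, length(opf), j)
    ef <- em <- matrix(NA_real_, length(opf), j)
    ef[fo, ] <- gobs[fo, , drop = FALSE]; em[fo, ] <- emiss[fo, , drop = FALSE]
    em[!fo, ] <- gobs[!fo, , drop = FALSE]; ef[!fo, ] <- emiss[!fo, , drop = FALSE]
    exp_father[i, ] <- ef
    exp_mother[i, ] <- em
    exp_sum[i, ] <- ef + em
  }

  # --- sibling pair, no genotyped parent: 27 (c1, c2, ibd) configurations
  spf <- des$family_id[des$design == "sib_pair"]
  if (length(spf)) {
    i <- match(spf, des$family_id)
    kd <- kids_of(spf)
    ib <- ibd_states(spf)
    cfg <- expand.grid(c1 = 0:2, c2 = 0:2, ibd = 0:2)
    gm <- rep(0:2, times = 3); gf <- rep(0:2, each = 3)     # 9 parental pairs
    L <- matrix(tb$L2[cbind(rep(cfg$c1 + 1, times = 9),
                            rep(cfg$c2 + 1, times = 9),
                            rep(cfg$ibd + 1, times = 9),
                            rep(gm + 1, each = 27),
                            rep(gf + 1, each = 27))], 27, 9)
    P <- pr[gm + 1, , drop = FALSE] * pr[gf + 1, , drop = FALSE]  # 9 x J
    numM <- (L %*% ((gm + gf) * P))                                # 27 x J
    denM <- L %*% P
    code <- kd$c1 + 3 * kd$c2 + 9 * ib + 1
    flat <- cbind(as.vector(code), rep(seq_len(j), each = length(spf)))
    den_v <- denM[flat]
    if (any(den_v == 0)) stop("Mendelian inconsistency in sibling-pair family")
    exp_sum[i, ] <- matrix(numM[flat] / den_v, length(spf), j)
  }

  # --- singleton: 3 child configurations
  sgf <- des$family_id[des$design == "singleton"]
  if (length(sgf)) {
    i <- match(sgf, des$family_id)
    kd <- kids_of(sgf)
    gm <- rep(0:2, times = 3); gf <- rep(0:2, each = 3)
    L <- matrix(tb$L1[cbind(rep(1:3, times = 9),
                            rep(gm + 1, each = 3),
                            rep(gf + 1, each = 3))], 3, 9)
    P <- pr[gm + 1, , drop = FALSE] * pr[gf + 1, , drop = FALSE]
    numM <- L %*% ((gm + gf) * P)
    denM <- L %*% P
    flat <- cbind(as.vector(kd$c1) + 1, rep(seq_len(j), each = length(sgf)))
    exp_sum[i, ] <- matrix(numM[flat] / denM[flat], length(sgf), j)
  }

  # --- scores: proband standardization scale, parental columns on same scale
  sc_off <- drop(cohort$dosage[off$individual_id, keep, drop = FALSE] %*% w)
  ctr <- mean(sc_off); s <- stats::sd(sc_off)
  if (s == 0) stop("zero proband score variance")
  sc_f <- drop(exp_father %*% w); sc_m <- drop(exp_mother %*% w)
  sc_sum <- drop(exp_sum %*% w)
  i_off <- match(off$family_id, des$family_id)
  sep <- des$design %in% c("trio", "one_parent")
  out <- data.frame(
    individual_id = off$individual_id,
    family_id = off$family_id,
    design = des$design[i_off],
    pgi_proband = (sc_off - ctr) / s,
    stringsAsFactors = FALSE
  )
  if (any(sep)) {
    mu_f <- mean(sc_f[sep]); mu_m <- mean(sc_m[sep])
    out$pgi_father <- ((sc_f - mu_f) / s)[i_off]
    out$pgi_mother <- ((sc_m - mu_m) / s)[i_off]
    out$source_father <- ifelse(des$father_observed, "observed", "imputed")[i_off]
    out$source_mother <- ifelse(des$mother_observed, "observed", "imputed")[i_off]
    out$pgi_father[!sep[i_off]] <- NA
    out$pgi_mother[!sep[i_off]] <- NA
    out$source_father[!sep[i_off]] <- NA
    out$source_mother[!sep[i_off]] <- NA
  }
  if (any(!sep)) {
    mu_s <- mean(sc_sum[!sep])
    out$pgi_parental_combined <- ((sc_sum - mu_s) / s)[i_off]
    out$pgi_parental_combined[sep[i_off]] <- NA
    out$source_parental <- ifelse(sep, NA, "imputed")[i_off]
  }
  attr(out, "design_counts") <- table(des$design)
  attr(out, "assortative_mating_adjustment") <- FALSE
  class(out) <- c("pgi_table", "data.frame")
  out
}
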