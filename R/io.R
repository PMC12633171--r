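# Canonical interchange dialect: tab-separated, header row, UTF-8, '.'
# decimal, numerics at 10 significant digits so identical runs are
# byte-identical.

fmt_num <- function(x) {
  if (is.double(x)) formatC(x, digits = 10, format = "g") else x
}

write_tsv10 <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_num), stringsAsFactors = FALSE,
                       check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a family cohort as TSV dosage + FAM pedigree + variant table
#'
#' Writes `<prefix>.dosage.tsv` (individual_id, family_id, role, one column
#' per SNP), `<prefix>.fam` (family, individual, father, mother, sex,
#' phenotype placeholder) and `<prefix>.bim.tsv` (snp_id, effect_allele,
#' other_allele, maf).
#'
#' @param cohort a `family_cohort`.
#' @param prefix output path prefix.
#' @return The prefix, invisibly.
#' @export
write_cohort <- function(cohort, prefix) {
  ped <- cohort$ped
  dos <- as.data.frame(cohort$dosage)
  names(dos) <- cohort$panel$snp_id
  write_tsv10(cbind(data.frame(individual_id = ped$individual_id,
                               family_id = ped$family_id, role = ped$role,
                               stringsAsFactors = FALSE), dos),
              paste0(prefix, ".dosage.tsv"))
  fam <- data.frame(family = ped$family_id, individual = ped$individual_id,
                    father = ifelse(is.na(ped$father_id), "0", ped$father_id),
                    mother = ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                    sex = ped$sex, phenotype = -9, stringsAsFactors = FALSE)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_tsv10(cohort$panel[c("snp_id", "effect_allele", "other_allele", "maf")],
              paste0(prefix, ".bim.tsv"))
  invisible(prefix)
}

#' Read a family cohort written by [write_cohort()]
#'
#' @param prefix path prefix used when writing.
#' @return A `family_cohort` (without effect truth, IBD states, or
#'   parent-observed masks, which live in the simulation objects).
#' @export
read_cohort <- function(prefix) {
  dos <- read_tsv(paste0(prefix, ".dosage.tsv"))
  bim <- read_tsv(paste0(prefix, ".bim.tsv"))
  fam <- utils::read.table(paste0(prefix, ".fam"), sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("family", "individual", "father",
                                         "mother", "sex", "phenotype"))
  panel <- snp_panel(maf = bim$maf, gamma = 0, theta = 0,
                     snp_id = bim$snp_id, effect_allele = bim$effect_allele,
                     other_allele = bim$other_allele)
  m <- as.matrix(dos[, panel$snp_id, drop = FALSE])
  storage.mode(m) <- "double"
  ped <- data.frame(
    individual_id = dos$individual_id, family_id = dos$family_id,
    father_id = ifelse(fam$father == "0", NA_character_, fam$father),
    mother_id = ifelse(fam$mother == "0", NA_character_, fam$mother),
    sex = fam$sex, role = dos$role, stringsAsFactors = FALSE)
  po <- unique(ped$family_id[ped$role %in% c("proband", "sibling")])
  parent_observed <- data.frame(
    family_id = po,
    father = po %in% ped$family_id[ped$role == "father"],
    mother = po %in% ped$family_id[ped$role == "mother"],
    stringsAsFactors = FALSE)
  new_family_cohort(m, ped, panel, parent_observed = parent_observed)
}

#' Write / read GWAS summary statistics
#'
#' Columns: snp_id, effect_allele, other_allele, maf, beta, se, n.
#' @param sumstats a `summary_stats` data frame.
#' @param path file path.
#' @export
write_sumstats <- function(sumstats, path) write_tsv10(sumstats, path)

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  out <- read_tsv(path)
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Write / read a SNP weight set
#'
#' Columns: snp_id, effect_allele, other_allele, weight.
#' @param weights a `weight_set`.
#' @param path file path.
#' @export
write_weights <- function(weights, path) write_tsv10(weights, path)

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  out <- read_tsv(path)
  class(out) <- c("weight_set", "data.frame")
  out
}

#' Write a PGI table
#' @param pgi a `pgi_table`.
#' @param path file path.
#' @export
write_pgi <- function(pgi, path) write_tsv10(as.data.frame(pgi), path)

#' @rdname write_pgi
#' @export
read_pgi <- function(path) {
  out <- read_tsv(path)
  class(out) <- c("pgi_table", "data.frame")
  out
}
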