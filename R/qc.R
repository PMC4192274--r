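# SNP and animal quality control: position filter, sire-progeny Mendelian
# consistency, minor allele frequency, call rate, and the adjusted-reliability
# animal filter. Filters are applied in that order by qc_pipeline().

.qc_stage <- function(filter, removed_snps = character(),
                      removed_animals = character(), detail = NULL) {
  list(filter = filter, removed_snps = removed_snps,
       removed_animals = removed_animals,
       n_removed = length(removed_snps) + length(removed_animals),
       detail = detail)
}

#' Remove SNPs with no usable map position
#'
#' Drops SNPs on excluded chromosomes (sex chromosome / unknown) or with a
#' non-positive position.
#'
#' @param gs genotype_set
#' @param excluded_chroms chromosome labels to drop
#' @return list(genotypes, report)
#' @export
filter_unmapped <- function(gs, excluded_chroms = c("X", "0", "unknown")) {
  bad <- gs$map$chrom %in% excluded_chroms | gs$map$pos <= 0L
  keep_ids <- gs$map$snp_id[!bad]
  out <- if (any(bad)) subset_genotypes(gs, keep_ids) else gs
  list(genotypes = out,
       report = .qc_stage("unmapped", removed_snps = gs$map$snp_id[bad]))
}

#' Count sire-progeny opposing-homozygote violations per SNP
#'
#' A violation is sire call 2 with progeny call 0 or sire 0 with progeny 2;
#' heterozygous or missing calls are never violations. Pairs with a missing
#' call are not counted as checkable.
#'
#' @param gs genotype_set
#' @param ped pedigree
#' @return data.table snp_id, violations, checkable
#' @export
mendel_check <- function(gs, ped) {
  ped <- as.data.table(ped)
  pairs <- ped[!is.na(sire) & sire %in% gs$animal_ids & animal %in% gs$animal_ids,
               .(animal, sire)]
  m <- length(gs$snp_ids)
  if (!nrow(pairs))
    return(data.table(snp_id = gs$snp_ids, violations = 0L, checkable = 0L))
  S <- gs$calls[match(pairs$sire, gs$animal_ids), , drop = FALSE]
  P <- gs$calls[match(pairs$animal, gs$animal_ids), , drop = FALSE]
  viol <- colSums((S == 2 & P == 0) | (S == 0 & P == 2), na.rm = TRUE)
  checkable <- colSums(!is.na(S) & !is.na(P))
  data.table(snp_id = gs$snp_ids, violations = as.integer(viol),
             checkable = as.integer(checkable))
}

#' Remove SNPs with inconsistent sire-to-progeny Mendelian inheritance
#'
#' A SNP is removed when its opposing-homozygote rate over checkable
#' sire-progeny pairs exceeds `max_error_rate`. The default 0 removes a SNP
#' on any violation (strictest reading); raise it to tolerate a known
#' genotyping-error rate.
#'
#' @param gs genotype_set
#' @param ped pedigree
#' @param max_error_rate tolerated violation rate in [0,1]
#' @return list(genotypes, report)
#' @export
filter_mendelian <- function(gs, ped, max_error_rate = 0) {
  chk <- mendel_check(gs, ped)
  rate <- ifelse(chk$checkable > 0L, chk$violations / chk$checkable, 0)
  bad <- rate > max_error_rate
  out <- if (any(bad)) subset_genotypes(gs, chk$snp_id[!bad]) else gs
  list(genotypes = out,
       report = .qc_stage("mendelian", removed_snps = chk$snp_id[bad],
                          detail = chk[bad]))
}

#' Minor allele frequency per SNP over non-missing calls
#' @param gs genotype_set
#' @return numeric vector (NA where all calls are missing)
#' @export
snp_maf <- function(gs) {
  nn <- colSums(!is.na(gs$calls))
  f <- colSums(gs$calls, na.rm = TRUE) / (2 * nn)
  maf <- pmin(f, 1 - f)
  maf[nn == 0L] <- NA_real_
  maf
}

#' Remove SNPs with a minor allele frequency below a threshold
#'
#' Removal is strict (`maf < min_maf`): a SNP exactly at the threshold is
#' retained. All-missing SNPs are removed and reported separately.
#'
#' @param gs genotype_set
#' @param min_maf threshold in [0, 0.5]
#' @return list(genotypes, report)
#' @export
filter_maf <- function(gs, min_maf = 0.05) {
  stopifnot(min_maf >= 0, min_maf <= 0.5)
  maf <- snp_maf(gs)
  all_missing <- is.na(maf)
  bad <- all_missing | maf < min_maf
  out <- if (any(bad)) subset_genotypes(gs, gs$snp_ids[!bad]) else gs
  list(genotypes = out,
       report = .qc_stage("maf", removed_snps = gs$snp_ids[bad],
                          detail = list(all_missing = gs$snp_ids[all_missing])))
}

#' Remove SNPs with too many missing calls
#'
#' Removal is strict (`missing fraction > max_missing`): a SNP exactly at the
#' threshold is retained.
#'
#' @param gs genotype_set
#' @param max_missing threshold in [0,1]
#' @return list(genotypes, report)
#' @export
filter_callrate <- function(gs, max_missing = 0.05) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  frac <- colMeans(is.na(gs$calls))
  bad <- frac > max_missing
  out <- if (any(bad)) subset_genotypes(gs, gs$snp_ids[!bad]) else gs
  list(genotypes = out,
       report = .qc_stage("callrate", removed_snps = gs$snp_ids[bad]))
}

#' Adjusted reliability: remove the parent-average contribution
#'
#' The parent-average reliability is \eqn{r^2_{PA} = (r^2_{sire} +
#' r^2_{dam})/4} (an unknown parent contributes 0); the adjusted reliability
#' is \eqn{\max(0, (r^2 - r^2_{PA}) / (1 - r^2_{PA}))}. With both parents
#' unknown the reliability is returned unchanged.
#'
#' @param rel_animal animal reliability in [0,1]
#' @param rel_sire,rel_dam parent reliabilities, `NA` if unknown
#' @return adjusted reliability (vectorized)
#' @export
adjusted_reliability <- function(rel_animal, rel_sire = NA, rel_dam = NA) {
  k <- pmax(length(rel_animal), length(rel_sire), length(rel_dam))
  r <- rep_len(rel_animal, k)
  rs <- rep_len(rel_sire, k); rd <- rep_len(rel_dam, k)
  if (any(c(r, rs[!is.na(rs)], rd[!is.na(rd)]) < 0 |
          c(r, rs[!is.na(rs)], rd[!is.na(rd)]) > 1))
    stop("reliabilities must lie in [0,1]")
  rs0 <- ifelse(is.na(rs), 0, rs); rd0 <- ifelse(is.na(rd), 0, rd)
  rpa <- (rs0 + rd0) / 4
  if (any(rpa >= 1)) stop("parent-average reliability of 1 is degenerate")
  out <- pmax(0, (r - rpa) / (1 - rpa))
  both_unknown <- is.na(rs) & is.na(rd)
  out[both_unknown] <- r[both_unknown]
  out
}

#' Remove animals with a low adjusted reliability, per trait
#'
#' Parent reliabilities for the same trait are looked up through the
#' pedigree; removal is strict (`adjusted < min_adj_rel`), so an animal at
#' exactly the threshold is retained.
#'
#' @param ph phenotype_table
#' @param ped pedigree
#' @param min_adj_rel threshold (default 0.70)
#' @return list(phenotypes, report); `phenotypes` gains column `adj_reliability`
#' @export
filter_animals <- function(ph, ped, min_adj_rel = 0.70) {
  stopifnot(min_adj_rel >= 0, min_adj_rel <= 1)
  ped <- as.data.table(ped)
  ph <- copy(as.data.table(ph))
  sire_of <- setNames(ped$sire, ped$animal)
  dam_of <- setNames(ped$dam, ped$animal)
  rel_of <- function(ids, trait_) {
    key <- paste(ph$animal, ph$trait)
    ph$reliability[match(paste(ids, trait_), key)]
  }
  ph[, adj_reliability := adjusted_reliability(
    reliability,
    rel_of(sire_of[animal], trait),
    rel_of(dam_of[animal], trait)), by = trait]
  bad <- ph$adj_reliability < min_adj_rel
  removed <- ph[bad]
  kept <- ph[!bad]
  warn <- kept[, .N, by = trait][, setdiff(unique(ph$trait), trait)]
  if (length(warn))
    warning("all animals removed for trait(s): ", paste(warn, collapse = ", "))
  list(phenotypes = phenotype_table(kept),
       report = .qc_stage("adjusted_reliability",
                          removed_animals = removed[, paste(animal, trait, sep = ":")],
                          detail = removed[, .(animal, trait, adj_reliability)]))
}

#' Full quality-control pipeline
#'
#' Applies the SNP filters in order (position, Mendelian, MAF, call rate),
#' then the animal adjusted-reliability filter, and collects a per-stage
#' report.
#'
#' @param gs genotype_set
#' @param ped pedigree
#' @param ph phenotype_table
#' @param excluded_chroms chromosomes dropped by the position filter
#' @param mendel_max tolerated Mendelian violation rate
#' @param min_maf MAF threshold
#' @param max_missing call-rate threshold
#' @param min_adj_rel adjusted-reliability threshold
#' @return list(genotypes, phenotypes, report) where report is a list of
#'   per-stage entries plus `n_snps_in`, `n_snps_out`
#' @export
qc_pipeline <- function(gs, ped, ph,
                        excluded_chroms = c("X", "0", "unknown"),
                        mendel_max = 0, min_maf = 0.05,
                        max_missing = 0.05, min_adj_rel = 0.70) {
  n_in <- length(gs$snp_ids)
  s1 <- filter_unmapped(gs, excluded_chroms)
  s2 <- filter_mendelian(s1$genotypes, ped, mendel_max)
  s3 <- filter_maf(s2$genotypes, min_maf)
  s4 <- filter_callrate(s3$genotypes, max_missing)
  s5 <- filter_animals(ph, ped, min_adj_rel)
  list(genotypes = s4$genotypes, phenotypes = s5$phenotypes,
       report = list(stages = list(s1$report, s2$report, s3$report,
                                   s4$report, s5$report),
                     n_snps_in = n_in,
                     n_snps_out = length(s4$genotypes$snp_ids)))
}
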