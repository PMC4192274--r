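#!/usr/bin/env Rscript

# Stage 2: quality control.
#
# Applies the SNP filters in the study's prescribed order — unmapped
# position, sire-progeny Mendelian consistency, MAF < 5%, call rate with
# > 5% missing — and then drops animals whose adjusted reliability (parental
# contribution removed) is below 70%.

library(pedgwas)

datadir <- "results/data"
gs <- read_genotypes(file.path(datadir, "study.ped"), file.path(datadir, "study.map"))
ped <- read_pedigree(file.path(datadir, "pedigree.csv"))
ph <- read_phenotypes(file.path(datadir, "phenotypes.tsv"))

qc <- qc_pipeline(gs, ped, ph, mendel_max = 0.02)

cat(sprintf("SNPs: %d in -> %d out\n", qc$report$n_snps_in, qc$report$n_snps_out))
for (s in qc$report$stages)
  cat(sprintf("  %-22s removed %d\n", s$filter, s$n_removed))

write_genotypes(qc$genotypes, file.path(datadir, "study_qc.ped"),
                file.path(datadir, "study_qc.map"))
write_phenotypes(qc$phenotypes, file.path(datadir, "phenotypes_qc.tsv"))

qc_tab <- data.frame(
  stage = vapply(qc$report$stages, `[[`, character(1), "filter"),
  n_removed = vapply(qc$report$stages, `[[`, integer(1), "n_removed"))
write.table(qc_tab, "results/qc_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("post-QC files written under", datadir, "\n")
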