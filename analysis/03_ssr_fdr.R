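#!/usr/bin/env Rscript

# Stage 3: single SNP regression with q-value FDR control.
#
# Builds the pedigree additive relationship matrix, estimates variance
# components once by REML on the null animal model, scans every SNP as a
# fixed allele-count covariate by GLS, converts p-values to
# Storey-Tibshirani q-values, and merges adjacent significant SNPs
# (q < 0.05) into SSR QTL. Also reports pSSR — the proportion of
# non-significant SNPs — which seeds the Bayesian prior grid in stage 4.

library(pedgwas)

datadir <- "results/data"
gs <- read_genotypes(file.path(datadir, "study_qc.ped"),
                     file.path(datadir, "study_qc.map"))
ped <- read_pedigree(file.path(datadir, "pedigree.csv"))
ph <- read_phenotypes(file.path(datadir, "phenotypes_qc.tsv"))
ph <- phenotype_table(ph[ph$animal %in% gs$animal_ids])

A <- build_amatrix(ped)
vc <- estimate_varcomp(ph, A)
cat(sprintf("REML: sigma2_a = %.3f, sigma2_e = %.3f, h2 = %.3f\n",
            vc$sigma2_a, vc$sigma2_e, vc$h2))

scan <- ssr_scan(gs, ph, A, vc)
qres <- qvalues(scan$p)
ssr_qtl <- call_ssr_qtl(qres, gs$map)

cat(sprintf("pi0 = %.3f; %d SNPs at q < 0.05 merging into %d SSR QTL; pSSR = %.4f\n",
            qres$pi0, sum(qres$q < 0.05), nrow(ssr_qtl), qres$p_ssr))

write_ssr(scan, "results/ssr_scan.tsv")
write_qvalues(qres, gs$map, "results/snp_qvalues.tsv")
write_qtl_bed(ssr_qtl, "results/ssr_qtl.bed")
writeLines(sprintf("%.6f", qres$p_ssr), "results/p_ssr.txt")
cat("scan written to results/ssr_scan.tsv (Manhattan-plot ready)\n")
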