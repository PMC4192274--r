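#!/usr/bin/env Rscript

# Stage 1: generate the synthetic carcass-trait study.
#
# Emulates the inputs of a SNP-chip association study in a pedigreed
# dairy-cattle population: a 4-generation pedigree (~500 animals), ~2,000
# mapped SNPs with local LD, 10 sparse QTL whose effect variances follow
# the scaled inverse chi-squared law (nu = 4.234, S = 0.0429), a pedigree
# polygenic background, de-regressed-proof-style phenotypes with
# reliabilities in [0.70, 0.99], plus gene annotations, a bovine-to-human
# ortholog map and pathway sets containing one QTL-spiked pathway.
# Everything is written as plain-text files under results/data/.

library(pedgwas)

seed <- 2025L
outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_founders = 125, n_generations = 3, offspring_per_mating = 2,
                  n_chromosomes = 4, snps_per_chromosome = 500, n_qtl = 10,
                  seed = seed)
st <- simulate_study(cfg)

write_genotypes(st$genotypes, file.path(outdir, "study.ped"),
                file.path(outdir, "study.map"), seed = seed)
write_pedigree(st$pedigree, file.path(outdir, "pedigree.csv"), seed = seed)
write_phenotypes(st$phenotypes, file.path(outdir, "phenotypes.tsv"), seed = seed)
write_genes_bed(st$annotations$genes, file.path(outdir, "genes.bed"), seed = seed)
write_orthologs(st$annotations$orthologs, file.path(outdir, "orthologs.tsv"),
                seed = seed)
write_gmt(st$annotations$pathways, file.path(outdir, "pathways.gmt"), seed = seed)

# ground truth, kept only for the final comparison step (synthetic data!)
truth <- data.frame(snp_id = st$effects$qtl_snp_ids,
                    chrom = st$genotypes$map$chrom[st$effects$qtl_idx],
                    pos = st$genotypes$map$pos[st$effects$qtl_idx],
                    effect = st$effects$effects[st$effects$qtl_idx])
write.table(truth, file.path(outdir, "true_qtl_synthetic.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d animals x %d SNPs on %d chromosomes (seed %d)\n",
            length(st$genotypes$animal_ids), length(st$genotypes$snp_ids),
            cfg$n_chromosomes, seed))
cat(sprintf("planted %d QTL; spiked pathway: %s\n",
            cfg$n_qtl, st$annotations$spiked_pathway))
cat("wrote PED/MAP, pedigree, phenotypes, genes, orthologs, GMT to", outdir, "\n")
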