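#!/usr/bin/env Rscript

# Stage 5: pathway over-representation.
#
# Collects bovine genes within 500 kb of any member SNP of the Bayesian
# QTL, maps them to human orthologs, and tests each pathway for
# over-representation against the background of orthologs within 500 kb of
# any analyzed SNP (hypergeometric upper tail, raw p < 0.05). Finally
# compares the called QTL with the synthetic ground truth.

library(pedgwas)
library(data.table)

datadir <- "results/data"
genes <- read_genes_bed(file.path(datadir, "genes.bed"))
om <- read_orthologs(file.path(datadir, "orthologs.tsv"))
db <- read_gmt(file.path(datadir, "pathways.gmt"))
gs_map <- fread(grep("^#", readLines(file.path(datadir, "study_qc.map")),
                     invert = TRUE, value = TRUE) |> paste(collapse = "\n"),
                header = FALSE, col.names = c("chrom", "snp_id", "cm", "pos"),
                colClasses = list(character = 1:2))
mem <- fread("results/bayesb_qtl_members.tsv",
             colClasses = list(character = "chrom"))

qtl <- pedgwas:::qtl_calls(mem[, .(start_bp = min(pos), end_bp = max(pos),
                                   n_snps = .N, snp_ids = list(snp_id),
                                   member_pos = list(pos), score = NA_real_,
                                   source = "bayesb"),
                               by = .(qtl, chrom)][, qtl := NULL])

hits <- build_gene_hit_set(qtl, genes, om, gs_map[, .(chrom, pos)],
                           flank_bp = 5e5, trait = "trait1")
cat(sprintf("%d bovine genes within 500 kb of QTL -> %d human orthologs (background %d)\n",
            length(hits$bovine_hits), length(hits$hits), length(hits$background)))

res <- enrichment_test(hits, db)
write_pathways(res, "results/pathways.tsv", trait = "trait1")
cat("top pathways:\n")
print(head(as.data.frame(res[, c("pathway", "overlap", "pathway_size", "p",
                                 "significant")]), 5))

truth <- fread(file.path(datadir, "true_qtl_synthetic.tsv"),
               colClasses = list(character = "chrom"))
near <- vapply(seq_len(nrow(truth)), function(i)
  any(qtl$chrom == truth$chrom[i] &
        qtl$start_bp - 5e5 <= truth$pos[i] &
        qtl$end_bp + 5e5 >= truth$pos[i]), logical(1))
cat(sprintf("%d of %d planted QTL lie within 500 kb of a called QTL\n",
            sum(near), nrow(truth)))
cat(sprintf("%d pathways significant at raw p < 0.05; spiked pathway rank %d\n",
            sum(res$significant), which(res$pathway == "pw_spiked")))
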