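# End-to-end driver: simulate (or load) -> QC -> kinship -> single-SNP
# regression -> q-values -> SSR QTL -> multi-prior BayesB ensemble ->
# convergence report -> pathway enrichment, writing every declared output.

#' Run the complete association pipeline on one trait
#'
#' Chains every stage of the analysis: quality control, additive
#' relationship matrix, REML variance components, single-SNP mixed-model
#' scan, Storey-Tibshirani q-values and SSR QTL calls, the eleven-prior
#' BayesB ensemble with sliding-window posterior probabilities and
#' occurrence-rate selection, a convergence report for the selected chain,
#' and hypergeometric pathway over-representation of genes near the
#' Bayesian QTL. When `outdir` is given, all standard output files are
#' written (scan TSV, q-value TSV, QTL BED/TSV, convergence traces,
#' pathway table, QC summary).
#'
#' @param study a study list as returned by [simulate_study()] (elements
#'   `genotypes`, `pedigree`, `phenotypes`, `annotations`)
#' @param bayes_iters,bayes_thin,bayes_mh iterations / thinning / inner MH
#'   proposals for each ensemble chain
#' @param pp_threshold window-PP threshold for high-PP QTL
#' @param window sliding-window size in SNPs
#' @param flank_bp enrichment flank around QTL member SNPs
#' @param min_maf,max_missing,mendel_max,min_adj_rel QC thresholds
#' @param seed seed for the Bayesian stage
#' @param outdir optional output directory
#' @return list of class `pipeline_result` with elements `qc`, `varcomp`,
#'   `ssr`, `qvalues`, `ssr_qtl`, `ensemble`, `convergence`, `hits`,
#'   `pathways`
#' @export
run_pipeline <- function(study,
                         bayes_iters = 20000L, bayes_thin = 100L,
                         bayes_mh = 10L, pp_threshold = 0.5, window = 5L,
                         flank_bp = 5e5, min_maf = 0.05, max_missing = 0.05,
                         mendel_max = 0, min_adj_rel = 0.70,
                         seed = 1L, outdir = NULL) {
  qc <- qc_pipeline(study$genotypes, study$pedigree, study$phenotypes,
                    mendel_max = mendel_max, min_maf = min_maf,
                    max_missing = max_missing, min_adj_rel = min_adj_rel)
  gs <- qc$genotypes
  ph <- qc$phenotypes
  keep <- intersect(ph$animal, gs$animal_ids)
  ph <- phenotype_table(as.data.table(ph)[animal %in% keep])
  A <- build_amatrix(study$pedigree)

  vc <- estimate_varcomp(ph, A)
  scan <- ssr_scan(gs, ph, A, vc)
  qres <- qvalues(scan$p)
  ssr_qtl <- call_ssr_qtl(qres, gs$map)

  base_cfg <- bayesb_config(one_minus_pi = 0.01, n_iterations = bayes_iters,
                            thin = bayes_thin, mh_inner = bayes_mh, seed = seed)
  ens <- run_ensemble(gs, ph, p_ssr = qres$p_ssr, base_cfg = base_cfg,
                      threshold = pp_threshold, window = window,
                      keep_chains = TRUE)
  conv <- if (!is.na(ens$selected))
    convergence_report(ens$chains[[ens$selected]], scan, pp_threshold) else NULL

  ann <- study$annotations
  hits <- build_gene_hit_set(ens$qtl, ann$genes, ann$orthologs, gs$map,
                             flank_bp = flank_bp,
                             trait = ph$trait[1L])
  pw <- enrichment_test(hits, ann$pathways)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(f) file.path(outdir, f)
    write_ssr(scan, fp("ssr_scan.tsv"))
    write_qvalues(qres, gs$map, fp("snp_qvalues.tsv"))
    write_qtl_bed(ssr_qtl, fp("ssr_qtl.bed"))
    write_qtl_bed(ens$qtl, fp("bayesb_qtl.bed"))
    qtl_tab <- as.data.table(ens$qtl)[, .(chrom, start_bp, end_bp, n_snps,
                                          score, occurrence_rate)]
    write.table(qtl_tab, fp("bayesb_qtl.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    ens_tab <- data.table(analysis = seq_along(ens$priors),
                          one_minus_pi = as.numeric(ens$priors),
                          n_qtl = vapply(ens$per_analysis_qtl, nrow, integer(1)),
                          avg_occurrence_rate = ens$avg_rates,
                          burn_in = ens$burn_ins,
                          selected = seq_along(ens$priors) == ens$selected)
    write.table(ens_tab, fp("ensemble_summary.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(conv)) {
      conv_tab <- data.table(record = seq_along(conv$loglik_trace),
                             loglik_abs = conv$loglik_trace,
                             n_high_pp = conv$high_pp_trace,
                             effect_distance = conv$distance_trace)
      write.table(conv_tab, fp("convergence_traces.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    write_pathways(pw, fp("pathways.tsv"), trait = hits$trait)
    qc_tab <- data.table(
      stage = vapply(qc$report$stages, `[[`, character(1), "filter"),
      n_removed = vapply(qc$report$stages, `[[`, integer(1), "n_removed"))
    write.table(qc_tab, fp("qc_summary.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  structure(list(qc = qc, varcomp = vc, ssr = scan, qvalues = qres,
                 ssr_qtl = ssr_qtl, ensemble = ens, convergence = conv,
                 hits = hits, pathways = pw),
            class = "pipeline_result")
}

#' Fraction of planted QTL recovered by a set of QTL calls
#'
#' A planted causal SNP counts as recovered when it lies within the span of
#' a called QTL extended by `slack_bp` on each side, on the same chromosome.
#'
#' @param qtl `qtl_calls`
#' @param effects `true_effects` from the simulator
#' @param map the SNP map the effects refer to
#' @param slack_bp span extension in bp (default 0)
#' @return list: `recovered` (logical per planted QTL), `n_true_positive`,
#'   `n_false_positive` (called QTL matching no planted SNP)
#' @export
qtl_recovery <- function(qtl, effects, map, slack_bp = 0) {
  map <- as.data.table(map)
  tru <- map[effects$qtl_idx]
  rec <- vapply(seq_len(nrow(tru)), function(i)
    any(qtl$chrom == tru$chrom[i] &
          qtl$start_bp - slack_bp <= tru$pos[i] &
          qtl$end_bp + slack_bp >= tru$pos[i]), logical(1))
  fp <- if (nrow(qtl)) vapply(seq_len(nrow(qtl)), function(k)
    !any(tru$chrom == qtl$chrom[k] &
           tru$pos >= qtl$start_bp[k] - slack_bp &
           tru$pos <= qtl$end_bp[k] + slack_bp), logical(1)) else logical(0)
  list(recovered = rec, n_true_positive = sum(rec), n_false_positive = sum(fp))
}
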