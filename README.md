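# pedgwas

Genome-wide association for pedigreed livestock populations evaluated on
de-regressed proofs (DRPs), built for quantitative geneticists who want the
complete inference stack — quality control through pathway biology — as
tested, scriptable R functions rather than a chain of external tools.

The package implements two complementary association tracks over the same
genotype panel and runs them end-to-end on synthetic data with the
statistical structure of a dairy-cattle carcass-trait study (SNP-chip
genotypes, multi-generation pedigree, reliability-weighted pseudo-phenotypes):

1. **Single-SNP mixed model (SSR).** Each SNP enters as an allele count
   $x_j$ in the animal model
   $y = 1\mu + x_j b_j + u + e$, $u \sim N(0, A\sigma^2_a)$, with the
   pedigree additive relationship matrix $A$ built by the tabular method.
   Variance components are estimated once by REML via the
   eigendecomposition of $A$; each SNP is then a generalized
   least-squares fit with a per-SNP residual scale and Wald p-value.
   P-values become Storey–Tibshirani q-values
   ($\hat\pi_0$ from the $\lambda$-grid + spline estimator), adjacent SNPs
   with $q < 0.05$ merge into SSR QTL, and the non-significant fraction
   $p_{SSR}$ seeds the Bayesian priors.
2. **BayesB with a multi-prior ensemble.** All SNPs jointly:
   $y = 1\mu + \sum_j x_j a_j + e$, where each $a_j$ is zero with prior
   probability $\pi$ and otherwise $N(0, \sigma^2_j)$,
   $\sigma^2_j \sim$ scaled inv-$\chi^2(\nu = 4.234, S = 0.0429)$.
   The sampler updates $(\delta_j, \sigma^2_j)$ by Metropolis–Hastings
   with the effect integrated out and everything else by Gibbs; chains
   are thinned (default every 500th iteration). Posterior probabilities
   (PPs) are computed per SNP and on 5-SNP sliding windows; windows with
   PP > 0.5 are high-PP QTL. Eleven analyses per trait — eight fixed
   priors from 0.05 to $6.25\times10^{-5}$ plus three derived from
   $p_{SSR}$ — are reconciled by QTL occurrence rates, and the analysis
   with the highest average occurrence rate is selected. Convergence is
   monitored by three traces (summed absolute log-likelihood with an
   automated burn-in rule, cumulative high-PP counts, Euclidean distance
   of BayesB vs SSR effects).
3. **Pathway over-representation.** Bovine genes within 500 kb of QTL
   member SNPs map to human orthologs and are tested per pathway by the
   hypergeometric upper tail against the background of orthologs near any
   analyzed SNP.

A full synthetic-data generator (gene dropping through simulated pedigrees
with LD and recombination, scaled inverse-chi-squared QTL effects,
polygenic background, reliability-governed DRP noise, annotated genes /
orthologs / spiked pathways) makes every stage testable with no external
data.

## Worked example

The `analysis/` directory holds the numbered workflow; each script is a
thin driver over package functions and writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # synthetic study -> results/data/
Rscript analysis/02_qc.R          # SNP + animal quality control
Rscript analysis/03_ssr_fdr.R     # mixed-model scan + q-values
Rscript analysis/04_bayesb_ensemble.R  # 11-prior BayesB ensemble
Rscript analysis/05_enrichment.R  # pathway over-representation
```

On the default seed the run prints, stage by stage:

```
simulated 497 animals x 2000 SNPs on 4 chromosomes (seed 2025)
SNPs: 2000 in -> 1979 out          # 1 Mendelian, 20 MAF, 168 animal-trait records
REML: sigma2_a = 0.171, sigma2_e = 0.010, h2 = 0.947
pi0 = 0.905; 16 SNPs at q < 0.05 merging into 11 SSR QTL; pSSR = 0.9919
selected analysis 8 (1 - pi = 0.0011) with 6 high-PP QTL
convergence: burn-in 0 records; diagnostics pass: loglik, high_pp, distance
10 bovine genes within 500 kb of QTL -> 12 human orthologs (background 232)
7 of 10 planted QTL lie within 500 kb of a called QTL
2 pathways significant at raw p < 0.05; spiked pathway rank 1
```

Reading this: the DRP trait is highly heritable on the evaluation scale
(h² ≈ 0.95 is typical for sire proofs, not for raw phenotypes); the scan
finds 11 QTL at FDR < 0.05; the ensemble settles on a sparse prior
(1 − π ≈ 0.001) whose six window-level QTL recur across essentially all
eleven priors (average occurrence rate 11); and the planted QTL-adjacent
pathway is recovered as the top-ranked enrichment
(p = 8.1 × 10⁻⁶). Per-SNP outputs (`results/ssr_scan.tsv`,
`results/snp_qvalues.tsv`) are Manhattan-plot-ready tables of effect,
standard error, p and q per marker.

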