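---
title: "Methods: pedigree mixed-model association and BayesB variable selection in pedgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree mixed-model association and BayesB variable selection in pedgwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

pedgwas implements a two-track genome-wide association workflow for
pedigreed livestock populations evaluated on de-regressed proofs: a
frequentist single-SNP mixed-model scan with q-value false-discovery
control, and a Bayesian whole-genome regression (BayesB) run as a
multi-prior ensemble with occurrence-rate consensus. This vignette explains
the models, the tunable parameters, the synthetic-data generator the tests
rely on, and the numerical and design choices that were genuinely open.

## Phenotypes: de-regressed proofs and reliability

The unit of analysis is an animal's de-regressed predicted transmitting
ability (DRP) for a trait, accompanied by a reliability $r^2 \in [0,1]$.
A DRP behaves like a noisy observation of the animal's genetic merit $g$,

$$y_i = g_i + \varepsilon_i, \qquad
  \varepsilon_i \sim N\!\left(0,\; \sigma^2_g \frac{1-r^2_i}{r^2_i}\right),$$

the standard de-regressed-proof weighting: an animal evaluated with
$r^2 = 0.99$ is almost noise-free, one at $r^2 = 0.70$ carries
$\approx 43\%$ of the genetic variance as extra noise. Before analysis,
animals are filtered on *adjusted* reliability, which removes the
parent-average contribution $r^2_{PA} = (r^2_{sire} + r^2_{dam})/4$
(unknown parents contribute 0):

$$r^2_{adj} = \max\!\left(0,\; \frac{r^2 - r^2_{PA}}{1 - r^2_{PA}}\right),$$

with the default cutoff $r^2_{adj} < 0.70$ discarding the animal. The exact
formula behind the cutoff is not fully standardized in the literature; the
parent-average removal above is the conventional choice and is documented
as such.

## Quality control

SNP filters run in a fixed order, each with its boundary convention stated:

1. **Position** — SNPs on excluded chromosomes (default `X`, `0`,
   `unknown`) or with non-positive position are dropped.
2. **Mendelian consistency** — for every genotyped sire-progeny pair, a
   SNP accrues a violation when the two calls are opposing homozygotes.
   The default removes a SNP on *any* violation (`max_error_rate = 0`),
   the strictest reading; with injected genotyping error a tolerance such
   as 0.02 is appropriate.
3. **Minor allele frequency** — computed over non-missing calls; removal
   is strict (`maf < min_maf`, default 0.05), so a SNP exactly at 5% is
   retained.
4. **Call rate** — removal is strict (`missing > max_missing`, default
   0.05), so exactly 5% missing is retained.

Counts are conserved at every stage and the filters are idempotent; both
properties are tested.

## Single-SNP mixed model

Each SNP enters separately as a continuous allele count $x_j \in \{0,1,2\}$
in the animal model

$$y = 1\mu + x_j b_j + u + e, \qquad
  u \sim N(0, A\sigma^2_a), \quad e \sim N(0, I\sigma^2_e),$$

where $A$ is the pedigree additive (numerator) relationship matrix built by
the tabular recursion ($A_{kk} = 1 + \tfrac12 A_{sd}$,
$A_{jk} = \tfrac12 (A_{js} + A_{jd})$) over the topologically sorted
pedigree. Inbreeding is handled implicitly by the recursion; storage is
dense, adequate to a few thousand animals.

Two deliberate approximations, both tested:

* **Variance components are estimated once** on the null model by REML
  (profiling the ratio $\gamma = \sigma^2_a/\sigma^2_e$ through the
  eigendecomposition of $A$, maximized with one-dimensional search) and
  held fixed across SNPs, in the style of the fast mixed-model association
  methods. Refitting per SNP is orders of magnitude slower and changes
  p-values negligibly; the type-I-error test (empirical
  $\Pr(p<0.05) \in 0.05 \pm 0.02$ under a pure-polygenic null with
  $h^2 = 0.3$, $n \approx 500$, 2,000 SNPs) covers the approximation's
  adequacy.
* **Per-SNP residual scale.** The correlation structure
  $V \propto \sigma^2_a A + \sigma^2_e I$ is fixed, but the overall scale
  is re-estimated for every SNP from the weighted residual sum of squares
  on $n-2$ degrees of freedom. This makes the scan reduce *exactly* to
  ordinary least squares when $A = I$ and $\sigma^2_a = 0$ — a sharp oracle
  the test suite asserts to $10^{-8}$ on $\log_{10} p$ — and improves
  calibration. Wald p-values use the standard normal reference;
  at the intended sample sizes the difference from a t reference is
  negligible. Missing genotypes are mean-imputed per SNP; SNPs left
  without variation are flagged degenerate with $p = 1$.

## q-values and SSR QTL

The q-value machinery follows the cited estimator: $\hat\pi_0(\lambda) =
\#\{p > \lambda\}/(m(1-\lambda))$ on the grid $\lambda = 0, 0.05, \dots,
0.90$, smoothed by a natural cubic smoothing spline (df = 3) and evaluated
at $\lambda = 0.90$, clamped to $(0,1]$; with $m < 100$ the smoother is
unreliable and $\hat\pi_0 = 1$ is returned. q-values then follow the
step-up recursion; with $\pi_0 = 1$ they coincide exactly with the
Benjamini–Hochberg adjustment, which the tests use as an independent
oracle. Map-adjacent SNPs with $q < 0.05$ merge into one QTL; adjacency
means consecutive rows of the sorted map on the same chromosome with no
bp-distance cap (none is prescribed, so none is imposed). The proportion
of non-significant SNPs, $p_{SSR} = \#\{q \ge 0.05\}/m$, feeds the Bayesian
prior grid.

## BayesB

The Bayesian track fits all SNPs simultaneously:

$$y = 1\mu + \textstyle\sum_j x_j a_j + e,$$

where each $a_j$ is exactly zero with prior probability $\pi$ and otherwise
$N(0, \sigma^2_j)$ with $\sigma^2_j \sim$ scaled inverse
$\chi^2(\nu = 4.234,\, S = 0.0429)$. The scaled parameterization
($E[\sigma^2] = \nu S/(\nu-2) \approx 0.081$) is the genomic-prediction
convention and is adopted here; note it presumes a trait on a standardized
(unit-variance-like) scale, a point that matters for the benchmarks below.

Because $\sigma^2_j = 0$ has no conjugate update, $(\delta_j, \sigma^2_j)$
is sampled jointly by Metropolis–Hastings with $a_j$ integrated out of the
likelihood: proposals come from the prior mixture (zero with probability
$\pi$, else a fresh scaled inverse-$\chi^2$ draw), so the prior cancels and
the acceptance ratio is a rank-one marginal-likelihood ratio computable
from $x_j^\top e$ and $x_j^\top x_j$ alone. Ten proposals per locus per
sweep (`mh_inner`) are the default. Included effects, the intercept, and
the residual variance (flat prior, conjugate scaled inverse-$\chi^2$
posterior on $n-2$ df) have Gibbs updates. Chains are stored thinned
(default: every 500th iteration). The recorded "log-likelihood" is the
summed absolute per-observation Gaussian log-density, matching the
diagnostic the workflow plots.

Two implementation guarantees are worth stating:

* **Determinism and exchangeability.** Every locus owns a private
  counter-seeded xoshiro256++ stream keyed by its SNP id, loci are
  processed in a canonical order (sorted SNP id), and the sampler never
  touches R's global RNG. Identical inputs and seed give a bit-identical
  chain, and permuting genotype columns permutes the output exactly —
  both are asserted in the tests.
* **Divergence guard.** A non-finite residual variance aborts with the
  iteration number rather than silently poisoning the chain.

### Posterior probabilities and windows

The per-SNP posterior probability (PP) is the fraction of post-burn-in
records with $\delta_j = 1$. Because LD smears a QTL's evidence across
neighbours, PPs are also computed on sliding windows of 5 map-adjacent
SNPs (sliding by one SNP, never crossing chromosomes; a chromosome with
fewer SNPs than the window yields a single all-SNP window): a window's PP
is the fraction of records in which *at least one* member is included, so
window PP $\ge$ the maximum member PP by construction. Windows with
PP > 0.5 (strict) are high-PP QTL; overlapping significant windows merge.

### The eleven-prior ensemble

Eleven analyses per trait differ only in the prior association probability
$1-\pi$: eight fixed values log-uniformly spaced from 0.05 down to
$6.25\times10^{-5}$ (the printed endpoints; the intermediate values are not
published, so log-uniform spacing is the natural reconstruction and is
configurable), plus $(1-p_{SSR})/2$, $(1-p_{SSR})$ and
$\min(2(1-p_{SSR}), 0.5)$ — the doubling is capped so the prior remains a
probability, resolving an ambiguity in how the doubled value should be
read. Value collisions are perturbed downward by half a geometric grid
step with a warning. QTL are matched across analyses by member-SNP overlap
with transitive closure; a QTL's occurrence rate is the number of analyses
containing a match. Each analysis is scored by the mean occurrence rate of
its QTL and the argmax is selected; exact ties break toward the larger
$1-\pi$ (no rule is prescribed; the larger prior is the less aggressive
claim) with a warning.

### Convergence diagnostics

Three traces are computed per chain: the summed absolute log-likelihood;
the count of SNPs whose *cumulative* PP exceeds 0.5 at each record (a
plateau indicates all high-PP QTL have been found); and the Euclidean
distance between the cumulative posterior-mean effects and the SSR
estimates on the high-PP set (threshold 0.5 assumed; the source workflow
does not state it). Where the original workflow inspected these traces by
eye, CI needs a decision rule: the reference is the mean and SD of the
final 50% of the log-likelihood trace, and burn-in is the first record
from which every later value stays within mean $\pm\,4$ SD; if none
exists the whole trace is flagged failed. All traces are pure functions of
the stored chain and recompute bit-identically.

## Pathway over-representation

Genes whose span overlaps a 500 kb flank around any member SNP of a
significant QTL form the hit set; their human orthologs are tested per
pathway against the background of orthologs of genes within 500 kb of
*any* analyzed SNP, with pathway membership restricted to that background.
With no gene-length bias correction the sampling model collapses to the
classical hypergeometric, so the upper tail $P(X \ge k)$ is computed
directly — the Wallenius machinery a bias-corrected test would need is
never exercised. Raw $p < 0.05$ flags significance, mirroring the
uncorrected reporting convention of this analysis family; a
Benjamini–Hochberg column is available behind a flag. One-to-many and
missing orthologs are handled by set union and an unmapped count.

## The synthetic-data generator

The generator produces every input the pipeline touches, so the whole
stack is testable offline:

* **Pedigree** — founders with alternating sexes; each later generation
  pairs random males and females (with replacement, so paternal half-sib
  families arise as in cattle breeding), `offspring_per_mating` children
  each.
* **Genotypes** — founder haplotypes are first-order Markov chains along
  each chromosome with allele frequencies uniform in
  `[maf_low, maf_high]` and adjacent-allele correlation `ld_rho`
  (default 0.6, in the range of adjacent-marker correlation on a 50k
  cattle chip); descendants receive gametes by gene dropping with
  per-interval crossover probability proportional to bp span, one
  expected crossover per chromosome (a standard cattle-scale
  approximation). Uncorrupted data are exactly Mendelian-consistent —
  asserted as an invariant. Afterwards genotypes are corrupted: set to
  missing at `missing_rate` (default 0.01, typical chip missingness) and
  randomized at `mendel_error_rate` (default 0.001, typical array error).
* **QTL effects** — `n_qtl` SNPs drawn uniformly; effect variances from
  the scaled inverse $\chi^2(\nu, S)$ law above, effects zero-mean normal.
* **Phenotypes** — $g = Xa + u$ with $u \sim N(0, A\sigma^2_{poly})$,
  $\sigma^2_{poly}$ set so the polygenic share of genetic variance equals
  `h2_polygenic`; reliabilities uniform on `[0.70, 0.99]` (the realistic
  post-filter range); DRP noise as in the weighting formula, using the
  realized variance of $g$ (falling back to unit scale when there is no
  genetic variance at all, so a no-genetics configuration still yields a
  pure-noise trait). The true $g$ is stored for oracles only and never
  read by analysis code.
* **Annotations** — non-overlapping gene intervals (one per chromosome
  slot), 0/1/2 human orthologs per gene with configurable proportions,
  random pathways of 10–200 genes, and one *spiked* pathway whose members
  are drawn from orthologs of genes within 500 kb of a true QTL with
  probability `spike_fraction`; when that pool is exhausted the pathway is
  simply smaller — members are never back-filled — so a spike fraction of
  1 puts every member near a QTL by construction.

Everything is bit-reproducible given the configuration and seed.

What the generator does *not* emulate: realistic cattle demography or
effective population size, sequence-level variation, the X chromosome,
genotype intensity clusters (hence the cluster-separation filter of chip
pipelines is out of scope), and the actual national-evaluation
de-regression machinery — the reliability-weighted noise model is a
stand-in, not a reconstruction. Passing tests therefore demonstrate
correctness of the inference stack under this statistical structure, not
performance on any real cattle dataset.

## Benchmark constructions and problem sizes

The test suite runs everything at desk scale; the sizes below are the
package's own choices, chosen to make the statistical assertions sharp:

* A-matrix: 20 random pedigrees of up to 30 animals against an independent
  memoized path-counting kinship oracle, agreement to $10^{-12}$.
* Scan reduction: $n = 200$, 50 SNPs against `lm()`.
* Scan calibration: $\approx 500$ animals in a 4-generation pedigree,
  2,000 SNPs, pure-polygenic trait with $h^2 = 0.3$.
* BayesB recovery: 400 unrelated genotyped animals, 2,000 SNPs, 10 planted
  QTL of *equal* effect variance at the prior mean $\nu S/(\nu-2)$,
  jointly half the genetic variance (the other half iid polygenic),
  200,000 iterations thinned at 500, $1-\pi = 0.005$. Two aspects of this
  design deserve comment. First, the trait is simulated on the scale the
  effect-variance prior is calibrated for; planting effects far outside
  the prior's bulk makes the marginal-likelihood proposals systematically
  too small and recovery borderline regardless of sampler quality.
  Second, equal variance shares make every planted locus individually
  detectable; drawing the ten shares from the heavy-tailed inverse-$\chi^2$
  instead typically leaves two or three loci below 1% of the QTL variance,
  which no method recovers at this sample size. False positives are
  counted on merged high-PP QTL — the pipeline's calling unit — because
  under LD several overlapping windows flank one causal SNP.
* Null specificity: ten studies of 300 unrelated animals and 1,000 SNPs
  with the phenotype standardized and permuted, 60,000 iterations thinned
  at 200. A caveat this package reports honestly: across 1,000
  LD-correlated markers the largest chance association occasionally
  (a sub-percent tail event per dataset) reaches a Bayes factor that
  correctly overwhelms the 1/99 prior odds, so a zero-false-window
  expectation fails in a small fraction of replicates *because the
  posterior is right*, not because the sampler errs.
* Enrichment: the spiked pathway must rank first with $p < 0.05$ in at
  least 9 of 10 seeded studies.
* End-to-end: one full pipeline on $\approx 500$ animals $\times$ 2,000
  SNPs with the eleven-prior ensemble at reduced chain length (10,000
  iterations thinned at 100), checking that every declared output file is
  emitted.

## Known limitations

* A deep pedigree with a strong polygenic background induces chance
  correlations between the polygene and individual genotype columns;
  in such datasets BayesB (which carries no explicit polygenic term)
  can both mask true QTL and call family-tagging SNPs. The mixed-model
  track is the guard against this; the two tracks are complementary, which
  is precisely why the workflow runs both.
* The effect-variance prior is not scale-free; applying it to a trait
  whose variance is far from the scale it was calibrated for shifts the
  effective inclusion threshold. Standardizing the trait before the
  Bayesian stage is recommended and is what the benchmarks do.
* Occurrence-rate matching by member-set intersection with transitive
  closure can chain distinct nearby QTL into one cluster under strong LD;
  the merged span makes this visible in the output.
* `estimate_pi0`'s spline fit needs a reasonable number of tests; below
  100 p-values it deliberately returns 1 (pure Benjamini–Hochberg
  behavior).
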