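# Synthetic study generator: pedigree, genotypes with LD and gene dropping,
# QTL effects from a scaled inverse chi-squared law, reliability-weighted
# pseudo-phenotypes, and gene/ortholog/pathway annotations.

#' Configuration for the synthetic study generator
#'
#' Defaults emulate a SNP-chip association study in a pedigreed dairy-cattle
#' population: a multi-generation pedigree, ~thousands of markers with a
#' realistic MAF spectrum and local LD, a sparse set of QTL whose effect
#' variances follow a scaled inverse chi-squared law with \eqn{\nu = 4.234}
#' and \eqn{S = 0.0429}, a polygenic background transmitted through the
#' pedigree, and de-regressed-proof-style pseudo-phenotypes whose noise is
#' governed by a reliability drawn between 0.70 and 0.99.
#'
#' @param n_founders founder animals (generation 0)
#' @param n_generations generations bred below the founders
#' @param offspring_per_mating offspring produced by each mating
#' @param n_chromosomes autosomes simulated
#' @param snps_per_chromosome markers per chromosome
#' @param chromosome_length_bp chromosome length in bp (1 expected crossover)
#' @param maf_low,maf_high founder allele-frequency bounds, in (0, 0.5]
#' @param ld_rho adjacent-marker haplotype allele correlation, in [0, 1)
#' @param n_qtl number of causal SNPs
#' @param qtl_nu,qtl_s scaled inverse chi-squared df and scale for the
#'   per-QTL effect variance
#' @param h2_polygenic share of genetic variance from the pedigree polygene
#' @param rel_low,rel_high reliability bounds for the pseudo-phenotypes
#' @param mendel_error_rate per-genotype probability of corruption to a
#'   random call
#' @param missing_rate per-genotype missing probability
#' @param genes_per_chromosome annotated genes placed per chromosome
#' @param ortholog_props probabilities a bovine gene has 0/1/2 human orthologs
#' @param n_pathways random pathways (one extra spiked pathway is added)
#' @param pathway_size_range min/max pathway size (genes)
#' @param spike_fraction probability a spiked-pathway member is drawn from
#'   genes within `spike_flank_bp` of a true QTL
#' @param spike_flank_bp flank defining "near a QTL" for the spiked pathway
#' @param seed integer master seed
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_founders = 60, n_generations = 3,
                       offspring_per_mating = 2,
                       n_chromosomes = 5, snps_per_chromosome = 400,
                       chromosome_length_bp = 1e8L,
                       maf_low = 0.05, maf_high = 0.5, ld_rho = 0.6,
                       n_qtl = 10, qtl_nu = 4.234, qtl_s = 0.0429,
                       h2_polygenic = 0.3,
                       rel_low = 0.70, rel_high = 0.99,
                       mendel_error_rate = 0.001, missing_rate = 0.01,
                       genes_per_chromosome = 60,
                       ortholog_props = c(0.15, 0.70, 0.15),
                       n_pathways = 50, pathway_size_range = c(10L, 200L),
                       spike_fraction = 0.9, spike_flank_bp = 5e5,
                       seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(maf_low > 0, maf_high <= 0.5, maf_low <= maf_high,
              rel_low <= rel_high, rel_low >= 0, rel_high <= 1,
              ld_rho >= 0, ld_rho < 1,
              mendel_error_rate >= 0, mendel_error_rate <= 1,
              missing_rate >= 0, missing_rate <= 1,
              h2_polygenic >= 0, h2_polygenic < 1,
              n_generations >= 0, qtl_nu > 0, qtl_s > 0,
              length(ortholog_props) == 3, abs(sum(ortholog_props) - 1) < 1e-8)
  })
  if (cfg$n_qtl > cfg$n_chromosomes * cfg$snps_per_chromosome)
    stop("n_qtl exceeds the total SNP count")
  structure(cfg, class = "sim_config")
}

#' Draw from the scaled inverse chi-squared distribution
#'
#' \eqn{X = \nu S / \chi^2_\nu}, with mean \eqn{\nu S / (\nu - 2)} for
#' \eqn{\nu > 2}.
#' @param n draws
#' @param nu degrees of freedom
#' @param s scale
#' @export
rscaled_invchisq <- function(n, nu, s) nu * s / rchisq(n, df = nu)

#' Simulate a multi-generation pedigree
#'
#' Founders (generation 0) are assigned alternating sexes. In every later
#' generation `floor(previous/2)` matings are formed by pairing a random male
#' and a random female from the previous generation (with replacement, so
#' half-sib families occur as in cattle breeding), each producing
#' `offspring_per_mating` offspring of random sex.
#'
#' @param cfg [sim_config()]
#' @param seed overrides `cfg$seed`
#' @return a [pedigree()] with extra columns `generation` and `sex`
#' @export
simulate_pedigree <- function(cfg, seed = cfg$seed) {
  if (cfg$n_founders < 2) stop("need at least 2 founders to form a mating")
  set.seed(seed)
  gen <- list(data.table(animal = sprintf("F%03d", seq_len(cfg$n_founders)),
                         sire = NA_character_, dam = NA_character_,
                         generation = 0L,
                         sex = rep_len(c("M", "F"), cfg$n_founders)))
  for (g in seq_len(cfg$n_generations)) {
    prev <- gen[[g]]
    males <- prev[sex == "M", animal]; females <- prev[sex == "F", animal]
    if (!length(males) || !length(females))
      stop("generation ", g - 1L, " has a single sex; no mating possible")
    n_matings <- max(1L, nrow(prev) %/% 2L)
    sires <- sample(males, n_matings, replace = TRUE)
    dams <- sample(females, n_matings, replace = TRUE)
    kid_sire <- rep(sires, each = cfg$offspring_per_mating)
    kid_dam <- rep(dams, each = cfg$offspring_per_mating)
    n_kids <- length(kid_sire)
    gen[[g + 1L]] <- data.table(
      animal = sprintf("G%d_%04d", g, seq_len(n_kids)),
      sire = kid_sire, dam = kid_dam, generation = g,
      sex = sample(c("M", "F"), n_kids, replace = TRUE))
  }
  ped <- rbindlist(gen)
  out <- pedigree(ped[, .(animal, sire, dam)])
  out[, generation := ped$generation[match(animal, ped$animal)]]
  out[, sex := ped$sex[match(animal, ped$animal)]]
  out[]
}

# Founder haplotypes: first-order Markov chain along each chromosome with
# marginal allele frequency p_j and adjacent-allele correlation ld_rho.
.founder_haplotypes <- function(n_hap, freqs, rho) {
  m <- length(freqs)
  H <- matrix(0L, n_hap, m)
  H[, 1L] <- rbinom(n_hap, 1L, freqs[1L])
  if (m > 1L) for (j in 2:m) {
    p0 <- freqs[j - 1L]; p1 <- freqs[j]
    pcond <- p1 + rho * sqrt(p1 * (1 - p1) / (p0 * (1 - p0))) * (H[, j - 1L] - p0)
    H[, j] <- rbinom(n_hap, 1L, pmin(1, pmax(0, pcond)))
  }
  H
}

# One gamete from a parent's two chromosome haplotypes, with crossover
# probability per adjacent interval = interval bp / chromosome bp.
.gamete <- function(h1, h2, xover_prob) {
  m <- length(h1)
  cross <- c(rbinom(1L, 1L, 0.5), rbinom(m - 1L, 1L, xover_prob))
  sel <- cumsum(cross) %% 2L
  ifelse(sel == 0L, h1, h2)
}

#' Simulate genotypes by gene dropping through a pedigree
#'
#' Founder haplotypes are drawn per chromosome with allele frequencies
#' uniform in `[maf_low, maf_high]` and first-order Markov LD (`ld_rho`);
#' descendants receive recombined gametes (one expected crossover per
#' chromosome), so uncorrupted data are Mendelian-consistent. Genotypes are
#' then set to missing at `missing_rate` and randomized at
#' `mendel_error_rate`.
#'
#' @param ped a [pedigree()]
#' @param cfg [sim_config()]
#' @param seed overrides `cfg$seed`
#' @return genotype_set; the uncorrupted calls are attached as attribute
#'   `clean_calls` for simulation oracles only
#' @export
simulate_genotypes <- function(ped, cfg, seed = cfg$seed) {
  set.seed(seed + 1L)
  n <- nrow(ped)
  m_chr <- cfg$snps_per_chromosome
  m <- cfg$n_chromosomes * m_chr
  idx <- setNames(seq_len(n), ped$animal)
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])

  map <- data.table(
    chrom = rep(as.character(seq_len(cfg$n_chromosomes)), each = m_chr),
    snp_id = sprintf("snp_%d_%04d", rep(seq_len(cfg$n_chromosomes), each = m_chr),
                     rep(seq_len(m_chr), cfg$n_chromosomes)),
    pos = integer(m))
  H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
  for (cc in seq_len(cfg$n_chromosomes)) {
    cols <- (cc - 1L) * m_chr + seq_len(m_chr)
    pos <- sort(sample.int(cfg$chromosome_length_bp - 1L, m_chr)) + 0L
    map$pos[cols] <- pos
    freqs <- runif(m_chr, cfg$maf_low, cfg$maf_high)
    xover <- diff(pos) / cfg$chromosome_length_bp
    founders <- which(is.na(si) & is.na(di))
    FH <- .founder_haplotypes(2L * length(founders), freqs, cfg$ld_rho)
    H1[founders, cols] <- FH[seq_along(founders) * 2L - 1L, ]
    H2[founders, cols] <- FH[seq_along(founders) * 2L, ]
    for (k in seq_len(n)) {
      if (is.na(si[k]) && is.na(di[k])) next
      H1[k, cols] <- .gamete(H1[si[k], cols], H2[si[k], cols], xover)
      H2[k, cols] <- .gamete(H1[di[k], cols], H2[di[k], cols], xover)
    }
  }
  clean <- H1 + H2
  calls <- clean
  if (cfg$mendel_error_rate > 0) {
    err <- matrix(runif(n * m) < cfg$mendel_error_rate, n, m)
    calls[err] <- sample(0:2, sum(err), replace = TRUE)
  }
  if (cfg$missing_rate > 0) {
    mis <- matrix(runif(n * m) < cfg$missing_rate, n, m)
    calls[mis] <- NA
  }
  rownames(calls) <- ped$animal
  gs <- genotype_set(calls, map, ped$animal)
  rownames(clean) <- ped$animal
  colnames(clean) <- map$snp_id
  attr(gs, "clean_calls") <- clean[, gs$map$snp_id, drop = FALSE]
  gs
}

#' Simulate sparse QTL effects
#'
#' `n_qtl` SNPs are chosen uniformly without replacement; each receives an
#' effect drawn from a zero-mean normal whose variance comes from the scaled
#' inverse chi-squared(`qtl_nu`, `qtl_s`) law. All other effects are exactly
#' zero.
#'
#' @param gs genotype_set
#' @param cfg [sim_config()]
#' @param seed overrides `cfg$seed`
#' @return list of class `true_effects` with `qtl_idx`, `qtl_snp_ids`,
#'   `effects` (length = n SNPs), `variances`
#' @export
simulate_qtl_effects <- function(gs, cfg, seed = cfg$seed) {
  m <- length(gs$snp_ids)
  if (cfg$n_qtl > m) stop("n_qtl exceeds SNP count")
  set.seed(seed + 2L)
  effects <- numeric(m)
  qtl_idx <- sort(sample.int(m, cfg$n_qtl))
  variances <- rscaled_invchisq(cfg$n_qtl, cfg$qtl_nu, cfg$qtl_s)
  effects[qtl_idx] <- rnorm(cfg$n_qtl, 0, sqrt(variances))
  structure(list(qtl_idx = qtl_idx, qtl_snp_ids = gs$snp_ids[qtl_idx],
                 effects = effects, variances = variances),
            class = "true_effects")
}

#' Simulate de-regressed-proof-style pseudo-phenotypes
#'
#' The genetic value is \eqn{g_i = \sum_j x_{ij} a_j + u_i} with polygenic
#' \eqn{u \sim MVN(0, A \sigma^2_{poly})}, where \eqn{\sigma^2_{poly}} is set
#' so the polygenic share of genetic variance equals `h2_polygenic`.
#' Reliabilities are uniform on `[rel_low, rel_high]` and the observed value
#' is \eqn{y_i = g_i + \epsilon_i} with
#' \eqn{\epsilon_i \sim N(0, \sigma^2_g (1 - r^2_i)/r^2_i)} — the standard
#' de-regressed-proof weighting, where \eqn{\sigma^2_g} is the realized
#' variance of g. The true g is stored for test oracles only.
#'
#' @param gs genotype_set (missing calls are mean-imputed for g)
#' @param effects `true_effects`
#' @param amatrix `amatrix` covering the genotyped animals
#' @param cfg [sim_config()]
#' @param seed overrides `cfg$seed`
#' @param trait trait label
#' @return phenotype_table with columns animal, trait, drp, reliability, true_g
#' @export
simulate_phenotypes <- function(gs, effects, amatrix, cfg, seed = cfg$seed,
                                trait = "trait1") {
  ids <- gs$animal_ids
  A <- subset_amatrix(amatrix, ids)
  set.seed(seed + 3L)
  X <- mean_impute(gs$calls)
  g_qtl <- drop(X %*% effects$effects)
  n <- length(ids)
  var_qtl <- var(g_qtl)
  h2 <- cfg$h2_polygenic
  sigma2_poly <- if (var_qtl > 0) h2 / (1 - h2) * var_qtl else h2
  u <- numeric(n)
  if (sigma2_poly > 0) {
    R <- tryCatch(chol(A + diag(1e-10, n)),
                  error = function(e) stop("A-matrix is singular"))
    u <- drop(crossprod(R, rnorm(n))) * sqrt(sigma2_poly)
  }
  g <- g_qtl + u
  sigma2_g <- var(g)
  rel <- runif(n, cfg$rel_low, cfg$rel_high)
  noise_sd <- if (sigma2_g > 0) sqrt(sigma2_g * (1 - rel) / rel) else sqrt((1 - rel) / rel)
  y <- g + rnorm(n, 0, noise_sd)
  phenotype_table(data.table(animal = ids, trait = trait, drp = y,
                             reliability = rel, true_g = g))
}

#' Simulate gene annotations, ortholog map and pathway sets
#'
#' Genes are placed as non-overlapping intervals along the simulated
#' chromosomes; each bovine gene receives 0, 1 or 2 human orthologs with the
#' configured probabilities; pathways are random ortholog sets of the
#' configured size range, plus one spiked pathway whose members are drawn
#' preferentially (probability `spike_fraction`) from orthologs of genes
#' within `spike_flank_bp` of a true QTL.
#'
#' @param gs genotype_set (for chromosome layout and QTL positions)
#' @param effects `true_effects`
#' @param cfg [sim_config()]
#' @param seed overrides `cfg$seed`
#' @return list with `genes` (gene_set), `orthologs` (ortholog_map),
#'   `pathways` (pathway_db), `spiked_pathway` (its id)
#' @export
simulate_annotations <- function(gs, effects, cfg, seed = cfg$seed) {
  set.seed(seed + 4L)
  n_genes <- cfg$genes_per_chromosome
  if (n_genes == 0L) {
    return(list(genes = gene_set(data.table(gene_id = character(), chrom = character(),
                                            start = integer(), end = integer())),
                orthologs = ortholog_map(data.table(bovine = character(), human = character())),
                pathways = NULL, spiked_pathway = NA_character_))
  }
  chroms <- as.character(seq_len(cfg$n_chromosomes))
  genes <- rbindlist(lapply(chroms, function(cc) {
    len <- pmin(5e4, pmax(5e3, round(rnorm(n_genes, 2e4, 1e4))))
    # non-overlapping: partition the chromosome into n slots, one gene each
    slot <- cfg$chromosome_length_bp %/% n_genes
    start <- (seq_len(n_genes) - 1L) * slot +
      sample.int(pmax(1L, slot - max(len) - 1L), n_genes, replace = TRUE)
    data.table(gene_id = sprintf("bgene_%s_%03d", cc, seq_len(n_genes)),
               chrom = cc, start = as.integer(start),
               end = as.integer(start + len))
  }))
  genes <- gene_set(genes)

  mult <- sample(0:2, nrow(genes), replace = TRUE, prob = cfg$ortholog_props)
  om <- rbindlist(lapply(which(mult > 0L), function(i)
    data.table(bovine = genes$gene_id[i],
               human = sprintf("hgene_%s_%d", genes$gene_id[i], seq_len(mult[i])))))
  if (!nrow(om)) om <- data.table(bovine = character(), human = character())
  om <- ortholog_map(om)
  all_orth <- unique(om$human)

  qtl_map <- gs$map[effects$qtl_idx]
  near <- genes[, {
    hit <- vapply(seq_len(.N), function(i) {
      any(qtl_map$chrom == chrom[i] &
            qtl_map$pos >= start[i] - cfg$spike_flank_bp &
            qtl_map$pos <= end[i] + cfg$spike_flank_bp)
    }, logical(1))
    .(gene_id = gene_id[hit])
  }]
  near_orth <- unique(om[bovine %in% near$gene_id, human])

  sets <- list()
  for (k in seq_len(cfg$n_pathways)) {
    sz <- sample(cfg$pathway_size_range[1L]:cfg$pathway_size_range[2L], 1L)
    sz <- min(sz, length(all_orth))
    sets[[sprintf("pw_%03d", k)]] <- sample(all_orth, sz)
  }
  # spiked pathway: each intended member comes from the near-QTL ortholog
  # pool with probability spike_fraction; if the near pool is exhausted the
  # pathway simply ends up smaller (members are never back-filled from the
  # genome-wide pool, so spike_fraction = 1 puts every member near a QTL)
  spike_id <- "pw_spiked"
  sz <- min(sample(cfg$pathway_size_range[1L]:cfg$pathway_size_range[2L], 1L),
            length(all_orth))
  n_near_target <- sum(runif(sz) < cfg$spike_fraction & length(near_orth) > 0)
  n_near <- min(n_near_target, length(near_orth))
  n_rest <- sz - n_near_target
  spiked <- unique(c(sample(near_orth, n_near),
                     sample(setdiff(all_orth, near_orth), min(n_rest, length(setdiff(all_orth, near_orth))))))
  if (!length(spiked)) spiked <- sample(all_orth, min(sz, length(all_orth)))
  sets[[spike_id]] <- spiked
  list(genes = genes, orthologs = om,
       pathways = pathway_db(sets), spiked_pathway = spike_id)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper chaining [simulate_pedigree()], [simulate_genotypes()],
#' [simulate_qtl_effects()], [build_amatrix()], [simulate_phenotypes()] and
#' [simulate_annotations()].
#'
#' @param cfg [sim_config()]
#' @param seed overrides `cfg$seed`
#' @return list with elements `pedigree`, `genotypes`, `effects`, `amatrix`,
#'   `phenotypes`, `annotations`, `cfg`
#' @export
simulate_study <- function(cfg = sim_config(), seed = cfg$seed) {
  ped <- simulate_pedigree(cfg, seed)
  gs <- simulate_genotypes(ped, cfg, seed)
  eff <- simulate_qtl_effects(gs, cfg, seed)
  A <- build_amatrix(ped)
  ph <- simulate_phenotypes(gs, eff, A, cfg, seed)
  ann <- simulate_annotations(gs, eff, cfg, seed)
  list(pedigree = ped, genotypes = gs, effects = eff, amatrix = A,
       phenotypes = ph, annotations = ann, cfg = cfg)
}

#' Mean-impute missing genotype calls, column-wise
#' @param X calls matrix with NAs
#' @return numeric matrix without NAs (all-missing columns become 0)
#' @export
mean_impute <- function(X) {
  X <- as.matrix(X) * 1.0
  nas <- which(colSums(is.na(X)) > 0L)
  for (j in nas) {
    mu <- mean(X[, j], na.rm = TRUE)
    if (is.nan(mu)) mu <- 0
    X[is.na(X[, j]), j] <- mu
  }
  X
}
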