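# R-side interface to the BayesB sampler and posterior-probability
# computation (per SNP and per sliding window of adjacent SNPs).

#' BayesB sampler configuration
#'
#' @param one_minus_pi prior probability that a SNP has a non-zero effect,
#'   in (0,1)
#' @param nu,s effect-variance prior: scaled inverse chi-squared degrees of
#'   freedom (default 4.234) and scale (default 0.0429)
#' @param n_iterations total MCMC iterations
#' @param thin record every `thin`-th iteration (default 500)
#' @param mh_inner Metropolis-Hastings proposals per locus per sweep
#' @param seed integer seed (< 2^31)
#' @return list of class `bayesb_config`
#' @export
bayesb_config <- function(one_minus_pi, nu = 4.234, s = 0.0429,
                          n_iterations = 200000L, thin = 500L,
                          mh_inner = 10L, seed = 1L) {
  stopifnot(one_minus_pi > 0, one_minus_pi < 1, thin >= 1,
            n_iterations >= thin, mh_inner >= 1, nu > 0, s > 0)
  structure(list(one_minus_pi = one_minus_pi, nu = nu, s = s,
                 n_iterations = as.integer(n_iterations),
                 thin = as.integer(thin), mh_inner = as.integer(mh_inner),
                 seed = as.integer(seed)),
            class = "bayesb_config")
}

#' Run the BayesB MCMC sampler
#'
#' Fits `y = 1*mu + sum_j x_j a_j + e` where each SNP effect is exactly zero
#' with prior probability `pi` and otherwise normal with a locus-specific
#' variance drawn from the scaled inverse chi-squared(`nu`, `s`) prior.
#' Locus indicators and variances are updated jointly by
#' Metropolis-Hastings with the effect integrated out; effects, intercept
#' and residual variance (flat prior) by Gibbs. The chain is stored thinned.
#' Identical inputs and seed give a bit-identical chain; the sampler uses
#' its own per-locus RNG streams, so results do not depend on (or disturb)
#' R's global RNG state.
#'
#' @param gs genotype_set (missing calls are mean-imputed)
#' @param y phenotype_table (single trait) or numeric vector named by animal
#' @param cfg [bayesb_config()]
#' @return object of class `chain_samples`: thinned records of `effects`
#'   (records x SNPs), `delta` indicators, `sigma2_e`, `mu`, `loglik_abs`
#'   (summed absolute per-observation Gaussian log-density), plus the SNP
#'   map, animal ids and config
#' @export
run_bayesb <- function(gs, y, cfg) {
  stopifnot(inherits(cfg, "bayesb_config"))
  yv <- .pheno_vector(y)
  ids <- intersect(names(yv), gs$animal_ids)
  if (length(ids) < 2L) stop("need at least 2 animals with genotype and phenotype")
  X <- mean_impute(gs$calls[match(ids, gs$animal_ids), , drop = FALSE])
  ord0 <- order(gs$snp_ids) - 1L  # canonical processing order (sorted id)
  raw <- bayesb_mcmc_cpp(X, unname(yv[ids]), gs$snp_ids, ord0,
                         cfg$one_minus_pi, cfg$nu, cfg$s,
                         cfg$n_iterations, cfg$thin, cfg$mh_inner,
                         as.double(cfg$seed))
  colnames(raw$effects) <- gs$snp_ids
  colnames(raw$delta) <- gs$snp_ids
  structure(list(effects = raw$effects, delta = raw$delta,
                 sigma2_e = raw$sigma2_e, mu = raw$mu,
                 loglik_abs = raw$loglik_abs,
                 n_records = nrow(raw$delta),
                 snp_ids = gs$snp_ids, map = copy(gs$map),
                 animal_ids = ids, config = cfg),
            class = "chain_samples")
}

#' @export
print.chain_samples <- function(x, ...) {
  cat(sprintf("chain_samples: %d records x %d SNPs (1-pi = %g, %d iterations, thin %d)\n",
              x$n_records, length(x$snp_ids), x$config$one_minus_pi,
              x$config$n_iterations, x$config$thin))
  invisible(x)
}

#' Per-SNP and sliding-window posterior probabilities
#'
#' The per-SNP posterior probability (PP) is the fraction of post-burn-in
#' records in which the SNP has a non-zero effect. Window PPs are computed
#' over runs of `window` map-adjacent SNPs (sliding by one SNP, never
#' crossing chromosomes): the fraction of records in which at least one
#' member SNP is included. A chromosome with fewer SNPs than `window`
#' contributes a single window covering all of them.
#'
#' @param chain `chain_samples`
#' @param burn_in number of initial records discarded (0 = keep all)
#' @param window window size in SNPs (default 5)
#' @return object of class `posterior_prob` with elements `snp`
#'   (snp_id, chrom, pos, pp), `windows` (chrom, start_bp, end_bp, snp_ids,
#'   member_pos, pp), `burn_in`, `window`
#' @export
compute_pp <- function(chain, burn_in = 0L, window = 5L) {
  stopifnot(inherits(chain, "chain_samples"), window >= 1L)
  TT <- chain$n_records
  if (burn_in >= TT) stop("burn_in (", burn_in, ") >= record count (", TT, ")")
  D <- chain$delta[(burn_in + 1L):TT, , drop = FALSE]
  pp_snp <- colMeans(D)
  map <- chain$map
  snp <- data.table(snp_id = chain$snp_ids, chrom = map$chrom,
                    pos = map$pos, pp = pp_snp)
  wins <- rbindlist(lapply(split(seq_len(nrow(map)), map$chrom), function(rows) {
    mc <- length(rows)
    starts <- if (mc <= window) 1L else seq_len(mc - window + 1L)
    rbindlist(lapply(starts, function(s0) {
      mem <- rows[s0:min(s0 + window - 1L, mc)]
      hit <- if (length(mem) == 1L) D[, mem] else rowSums(D[, mem, drop = FALSE]) > 0
      data.table(chrom = map$chrom[mem[1L]],
                 start_bp = map$pos[mem[1L]],
                 end_bp = map$pos[mem[length(mem)]],
                 snp_ids = list(map$snp_id[mem]),
                 member_pos = list(map$pos[mem]),
                 pp = mean(hit > 0))
    }))
  }), use.names = TRUE)
  structure(list(snp = snp, windows = wins, burn_in = as.integer(burn_in),
                 window = as.integer(window)),
            class = "posterior_prob")
}
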