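# Independent oracles and small fixture builders shared across tests.

# Kinship by top-down memoized recursion on animal pairs (Wright's
# coefficients); an independent route to the additive relationship matrix:
# A_ij = 2 * phi(i, j). Animals must be given in topological order.
kinship_oracle <- function(ped) {
  ped <- as.data.frame(ped)
  n <- nrow(ped)
  pos <- setNames(seq_len(n), ped$animal)
  si <- pos[ped$sire]; di <- pos[ped$dam]
  memo <- new.env(hash = TRUE)
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(min(i, j), max(i, j))
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (i == j) {
      0.5 * (1 + phi(si[i], di[i]))
    } else {
      # recurse on the animal later in topological order
      if (i < j) 0.5 * (phi(i, si[j]) + phi(i, di[j]))
      else 0.5 * (phi(j, si[i]) + phi(j, di[i]))
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) for (j in i:n) A[i, j] <- A[j, i] <- 2 * phi(i, j)
  A
}

# Random acyclic pedigree: each animal after the first few picks earlier
# animals (or unknown) as parents.
random_pedigree <- function(n, seed) {
  set.seed(seed)
  animal <- sprintf("A%02d", seq_len(n))
  sire <- dam <- rep(NA_character_, n)
  for (k in 3:n) {
    if (runif(1) < 0.8) sire[k] <- animal[sample.int(k - 1L, 1L)]
    if (runif(1) < 0.8) {
      cand <- setdiff(animal[seq_len(k - 1L)], sire[k])
      if (length(cand)) dam[k] <- cand[sample.int(length(cand), 1L)]
    }
  }
  pedigree(data.frame(animal = animal, sire = sire, dam = dam))
}

# Quick genotype_set from a call matrix on one or more chromosomes.
make_gs <- function(X, chrom = NULL, pos = NULL, snp_ids = NULL) {
  m <- ncol(X)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- ave(seq_len(m), chrom, FUN = function(i) seq_along(i) * 1000L)
  if (is.null(snp_ids)) snp_ids <- sprintf("s%03d", seq_len(m))
  if (is.null(rownames(X))) rownames(X) <- sprintf("an%03d", seq_len(nrow(X)))
  genotype_set(X, data.frame(chrom = chrom, snp_id = snp_ids, pos = pos))
}

# Hand-built chain_samples for posterior-probability and convergence units.
make_chain <- function(delta, effects = NULL, map = NULL, loglik = NULL,
                       thin = 1L, one_minus_pi = 0.05) {
  delta <- as.matrix(delta)
  TT <- nrow(delta); m <- ncol(delta)
  if (is.null(effects)) effects <- delta * 1.0
  if (is.null(map)) map <- data.table::data.table(
    chrom = rep("1", m), snp_id = sprintf("s%03d", seq_len(m)),
    pos = seq_len(m) * 1000L)
  if (is.null(loglik)) loglik <- rep(-10, TT)
  structure(list(effects = as.matrix(effects), delta = delta,
                 sigma2_e = rep(1, TT), mu = rep(0, TT),
                 loglik_abs = loglik, n_records = TT,
                 snp_ids = map$snp_id, map = map,
                 animal_ids = character(),
                 config = bayesb_config(one_minus_pi, n_iterations = TT * thin,
                                        thin = thin)),
            class = "chain_samples")
}

# Hand-built QTL-call tables for occurrence-rate and selection algebra.
.toy_qtl <- function(sets, chrom = "1") {
  if (!length(sets)) return(pedgwas:::qtl_calls(NULL))
  pedgwas:::qtl_calls(data.table::rbindlist(lapply(sets, function(s) {
    pos <- as.integer(sub("s", "", s)) * 1000L
    data.table::data.table(chrom = chrom, start_bp = min(pos),
                           end_bp = max(pos), n_snps = length(s),
                           snp_ids = list(s), member_pos = list(pos),
                           score = 0.9, source = "bayesb")
  })))
}

# Exact hypergeometric upper tail by direct enumeration with choose().
hyper_tail_enum <- function(k, N, K, nn) {
  if (k <= 0) return(1)
  top <- min(K, nn)
  if (k > top) return(0)
  sum(vapply(k:top, function(i)
    choose(K, i) * choose(N - K, nn - i), numeric(1))) / choose(N, nn)
}

# Small synthetic study used by several suites (cheap but full-featured).
small_study <- function(seed = 11, mendel_error_rate = 0, missing_rate = 0, ...) {
  cfg <- sim_config(n_founders = 30, n_generations = 2, offspring_per_mating = 2,
                    n_chromosomes = 3, snps_per_chromosome = 60, n_qtl = 4,
                    mendel_error_rate = mendel_error_rate,
                    missing_rate = missing_rate, seed = seed, ...)
  simulate_study(cfg)
}
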