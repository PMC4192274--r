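# Convergence diagnostics for a BayesB chain: the summed-absolute
# log-likelihood trace with an automated burn-in rule, the trace of the
# number of SNPs with cumulative PP > 0.5, and the Euclidean distance
# between the cumulative posterior-mean effects and the single-SNP
# regression estimates on the high-PP SNP set.

#' Automated burn-in detection on a log-likelihood trace
#'
#' The final 50% of the trace defines a reference mean and SD; burn-in is
#' the first record index from which every subsequent value lies within
#' mean +/- 4 SD. If no such index exists the trace length is returned and
#' the failure flag is set.
#'
#' @param loglik_trace numeric trace, one value per stored record
#' @return list: `burn_in` (records to discard; 0 = none), `pass` flag,
#'   `ref_mean`, `ref_sd`
#' @export
detect_burn_in <- function(loglik_trace) {
  TT <- length(loglik_trace)
  if (TT < 10L) stop("trace must have at least 10 records")
  if (any(!is.finite(loglik_trace))) stop("non-finite trace values")
  tail_idx <- (floor(TT / 2) + 1L):TT
  ref_mean <- mean(loglik_trace[tail_idx])
  ref_sd <- sd(loglik_trace[tail_idx])
  inside <- abs(loglik_trace - ref_mean) <= 4 * ref_sd
  # first index from which everything onwards is inside the band
  ok_from <- rev(cumprod(rev(inside))) > 0
  first <- which(ok_from)[1L]
  if (is.na(first))
    return(list(burn_in = TT, pass = FALSE, ref_mean = ref_mean, ref_sd = ref_sd))
  list(burn_in = first - 1L, pass = TRUE, ref_mean = ref_mean, ref_sd = ref_sd)
}

#' Trace of the number of SNPs with cumulative PP > 0.5
#'
#' At record t the PP of each SNP is computed over records 1..t; the trace
#' reports how many SNPs exceed 0.5. A plateau indicates all high-PP QTL
#' have been found.
#'
#' @param chain `chain_samples`
#' @return integer vector, one count per record
#' @export
high_pp_count_trace <- function(chain) {
  D <- chain$delta
  TT <- nrow(D)
  cs <- apply(D, 2L, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = TT)
  ppc <- cs / seq_len(TT)
  as.integer(rowSums(ppc > 0.5))
}

#' Trace of the Euclidean distance between BayesB and SSR effects
#'
#' At each record, the set S holds SNPs whose cumulative PP exceeds
#' `pp_threshold`; the trace value is
#' \eqn{\sqrt{\sum_{j \in S} (\bar a_j - \hat b_j)^2}} where
#' \eqn{\bar a_j} is the cumulative posterior-mean BayesB effect (zeros
#' included) and \eqn{\hat b_j} the SSR estimate. Empty S gives 0.
#'
#' @param chain `chain_samples`
#' @param ssr_result `ssr_result` covering all chain SNPs
#' @param pp_threshold PP cut defining S (default 0.5)
#' @return numeric vector, one distance per record
#' @export
effect_distance_trace <- function(chain, ssr_result, pp_threshold = 0.5) {
  if (!all(chain$snp_ids %in% ssr_result$snp_id))
    stop("SSR results do not cover all chain SNPs")
  bhat <- ssr_result$effect[match(chain$snp_ids, ssr_result$snp_id)]
  D <- chain$delta
  A <- chain$effects
  TT <- nrow(D)
  csD <- apply(D, 2L, cumsum); csA <- apply(A, 2L, cumsum)
  if (is.null(dim(csD))) { csD <- matrix(csD, nrow = TT); csA <- matrix(csA, nrow = TT) }
  vapply(seq_len(TT), function(t) {
    S <- csD[t, ] / t > pp_threshold
    if (!any(S)) return(0)
    abar <- csA[t, S] / t
    sqrt(sum((abar - bhat[S])^2))
  }, numeric(1))
}

#' Full convergence report for a chain
#'
#' Computes all three diagnostic traces, applies the burn-in rule to the
#' log-likelihood trace, and flags each diagnostic. The PP-count and
#' distance diagnostics pass when the final fifth of the trace has
#' stabilized (its range is within one count, resp. within 10% of the trace
#' scale).
#'
#' @param chain `chain_samples`
#' @param ssr_result `ssr_result`
#' @param pp_threshold PP threshold for the distance diagnostic
#' @return list of class `convergence_report`: `burn_in`, `pass` flags,
#'   `loglik_trace`, `high_pp_trace`, `distance_trace`
#' @export
convergence_report <- function(chain, ssr_result, pp_threshold = 0.5) {
  bi <- detect_burn_in(chain$loglik_abs)
  hp <- high_pp_count_trace(chain)
  dist <- effect_distance_trace(chain, ssr_result, pp_threshold)
  TT <- length(hp)
  last5 <- (max(1L, TT - floor(TT / 5) + 1L)):TT
  hp_pass <- diff(range(hp[last5])) <= 1L
  scale <- max(abs(dist), 1e-12)
  dist_pass <- diff(range(dist[last5])) <= 0.1 * scale
  structure(list(burn_in = bi$burn_in,
                 pass = c(loglik = bi$pass, high_pp = hp_pass, distance = dist_pass),
                 ref_mean = bi$ref_mean, ref_sd = bi$ref_sd,
                 loglik_trace = chain$loglik_abs,
                 high_pp_trace = hp, distance_trace = dist),
            class = "convergence_report")
}
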