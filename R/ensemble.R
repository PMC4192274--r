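# Multi-prior BayesB ensemble: eleven prior association probabilities per
# trait, high-PP QTL per analysis, occurrence rates across analyses, and
# selection of the analysis with the highest average occurrence rate.

#' Build the eleven-value prior grid
#'
#' Eight fixed values log-uniformly spaced from 0.05 down to 6.25e-5, plus
#' three derived from the SSR scan: the associated proportion `1 - p_ssr`
#' (where `p_ssr` is the proportion of SNPs with q >= 0.05), its half, and
#' its double capped at 0.5 so the prior remains a probability. Collisions
#' with the fixed grid are perturbed by half a (geometric) grid step with a
#' warning.
#'
#' @param p_ssr proportion of non-significant SNPs from the SSR analysis,
#'   in (0,1)
#' @param fixed optional override of the eight fixed values
#' @return numeric vector of 11 prior association probabilities, sorted
#'   descending, with a `source` attribute
#' @export
build_prior_grid <- function(p_ssr, fixed = NULL) {
  if (p_ssr <= 0 || p_ssr >= 1) stop("p_ssr must lie in (0,1)")
  if (is.null(fixed))
    fixed <- exp(seq(log(0.05), log(6.25e-5), length.out = 8))
  assoc <- 1 - p_ssr
  derived <- c(assoc / 2, assoc, min(2 * assoc, 0.5))
  step <- sqrt(fixed[1] / fixed[2])  # half a geometric grid step
  for (i in seq_along(derived)) {
    while (any(abs(log(derived[i]) - log(c(fixed, derived[-i]))) < 1e-12)) {
      warning("prior value collision at ", signif(derived[i], 6),
              "; perturbing by half a grid step")
      derived[i] <- derived[i] / step  # downward keeps the value in (0, 0.5]
    }
  }
  grid <- c(fixed, derived)
  src <- c(rep("fixed", 8), "pssr_half", "pssr", "pssr_double")
  ord <- order(grid, decreasing = TRUE)
  structure(grid[ord], source = src[ord])
}

#' Call high-PP QTL from window posterior probabilities
#'
#' Windows with PP strictly above `threshold` are significant; overlapping
#' significant windows on the same chromosome (sharing at least one SNP)
#' are merged into one QTL spanning their union.
#'
#' @param pp `posterior_prob` from [compute_pp()]
#' @param threshold PP threshold (default 0.5, strict `>`)
#' @return `qtl_calls` with source `"bayesb"` and score = max window PP
#' @export
call_high_pp_qtl <- function(pp, threshold = 0.5) {
  w <- pp$windows
  w <- w[which(w$pp > threshold)]
  if (!nrow(w)) return(qtl_calls(NULL))
  qtl_calls(rbindlist(lapply(split(seq_len(nrow(w)), w$chrom), function(rows) {
    ww <- w[rows]
    setorder(ww, start_bp)
    groups <- list(); cur <- 1L
    grp <- integer(nrow(ww)); grp[1L] <- 1L
    if (nrow(ww) > 1L) for (i in 2:nrow(ww)) {
      prev_members <- unlist(ww$snp_ids[grp == grp[i - 1L]])
      grp[i] <- if (length(intersect(ww$snp_ids[[i]], prev_members))) grp[i - 1L]
                else grp[i - 1L] + 1L
    }
    rbindlist(lapply(split(seq_len(nrow(ww)), grp), function(g) {
      ids <- unique(unlist(ww$snp_ids[g]))
      posv <- unique(unlist(ww$member_pos[g]))
      o <- order(posv)
      data.table(chrom = ww$chrom[1L],
                 start_bp = min(posv), end_bp = max(posv),
                 n_snps = length(ids),
                 snp_ids = list(ids[o]), member_pos = list(posv[o]),
                 score = max(ww$pp[g]), source = "bayesb")
    }))
  }), use.names = TRUE))
}

#' Match QTL across analyses and assign occurrence rates
#'
#' QTL from different analyses belong to the same underlying QTL when their
#' member-SNP sets intersect; matching is closed transitively (union-find).
#' A QTL's occurrence rate is the number of analyses containing at least
#' one member of its cluster.
#'
#' @param per_analysis_qtl list of `qtl_calls`, one per analysis
#' @return the input list with columns `occurrence_rate` and `cluster` added
#' @export
occurrence_rates <- function(per_analysis_qtl) {
  stopifnot(length(per_analysis_qtl) >= 1L)
  all_qtl <- rbindlist(lapply(seq_along(per_analysis_qtl), function(k) {
    q <- per_analysis_qtl[[k]]
    if (!nrow(q)) return(NULL)
    data.table(analysis = k, qtl_row = seq_len(nrow(q)), snp_ids = q$snp_ids)
  }), use.names = TRUE)
  if (is.null(all_qtl) || !nrow(all_qtl)) {
    return(lapply(per_analysis_qtl, function(q) {
      q[, `:=`(occurrence_rate = integer(0), cluster = integer(0))][]
    }))
  }
  nq <- nrow(all_qtl)
  parent <- seq_len(nq)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  snp2q <- split(rep(seq_len(nq), lengths(all_qtl$snp_ids)), unlist(all_qtl$snp_ids))
  for (qs in snp2q) if (length(qs) > 1L) {
    r0 <- find(qs[1L])
    for (i in qs[-1L]) { ri <- find(i); if (ri != r0) parent[ri] <- r0 }
  }
  cluster <- vapply(seq_len(nq), find, integer(1))
  cluster <- as.integer(factor(cluster))
  rate_of_cluster <- tapply(all_qtl$analysis, cluster, function(a) length(unique(a)))
  all_qtl[, cluster_id := cluster]
  all_qtl[, occurrence_rate := as.integer(rate_of_cluster[as.character(cluster_id)])]
  lapply(seq_along(per_analysis_qtl), function(k) {
    q <- copy(per_analysis_qtl[[k]])
    rows <- all_qtl[analysis == k]
    q[, occurrence_rate := NA_integer_]
    q[, cluster := NA_integer_]
    if (nrow(rows)) {
      q[rows$qtl_row, occurrence_rate := rows$occurrence_rate]
      q[rows$qtl_row, cluster := rows$cluster_id]
    }
    qtl_calls(q)
  })
}

#' Select the analysis with the highest average occurrence rate
#'
#' Each analysis's average occurrence rate is the sum of its QTL occurrence
#' rates divided by its QTL count (0 when it called no QTL). Ties are
#' broken toward the larger prior association probability, with a warning.
#'
#' @param per_analysis_qtl list of `qtl_calls` with occurrence rates (from
#'   [occurrence_rates()])
#' @param priors the prior association probability of each analysis
#' @return list: `selected` (index), `avg_rates`, `priors`
#' @export
select_analysis <- function(per_analysis_qtl, priors) {
  stopifnot(length(per_analysis_qtl) == length(priors))
  avg <- vapply(per_analysis_qtl, function(q)
    if (nrow(q)) mean(q$occurrence_rate) else 0, numeric(1))
  if (all(avg == 0) && all(vapply(per_analysis_qtl, nrow, integer(1)) == 0L))
    stop("no high PP QTL in any analysis")
  best <- which(avg == max(avg))
  if (length(best) > 1L) {
    warning("tie on average occurrence rate; choosing the larger prior")
    best <- best[which.max(priors[best])]
  }
  list(selected = best, avg_rates = avg, priors = priors)
}

#' Run the full eleven-prior BayesB ensemble for one trait
#'
#' Builds the prior grid from `p_ssr`, runs one chain per prior (seeds are
#' derived from `base_cfg$seed` plus the analysis index), determines
#' burn-in per chain from the log-likelihood trace, computes sliding-window
#' posterior probabilities, calls high-PP QTL, assigns occurrence rates and
#' selects the analysis with the highest average occurrence rate.
#'
#' @param gs genotype_set (post-QC)
#' @param y phenotype_table (one trait) or named numeric vector
#' @param p_ssr proportion of non-significant SNPs from the SSR q-values
#' @param base_cfg `bayesb_config` template (its `one_minus_pi` is replaced
#'   by each grid value)
#' @param threshold window-PP threshold for high-PP QTL
#' @param window sliding-window size in SNPs
#' @param keep_chains keep the full chains in the result (memory!)
#' @return list of class `ensemble_result`: `priors`, `per_analysis_qtl`,
#'   `avg_rates`, `selected`, `qtl` (calls of the selected analysis),
#'   `burn_ins`, and optionally `chains`
#' @export
run_ensemble <- function(gs, y, p_ssr, base_cfg, threshold = 0.5,
                         window = 5L, keep_chains = FALSE) {
  priors <- build_prior_grid(p_ssr)
  chains <- vector("list", length(priors))
  per_qtl <- vector("list", length(priors))
  burn_ins <- integer(length(priors))
  for (k in seq_along(priors)) {
    cfg_k <- bayesb_config(one_minus_pi = priors[k], nu = base_cfg$nu,
                           s = base_cfg$s, n_iterations = base_cfg$n_iterations,
                           thin = base_cfg$thin, mh_inner = base_cfg$mh_inner,
                           seed = base_cfg$seed + k)
    ch <- run_bayesb(gs, y, cfg_k)
    bi <- detect_burn_in(ch$loglik_abs)
    burn_ins[k] <- min(bi$burn_in, ch$n_records - 1L)
    pp <- compute_pp(ch, burn_in = burn_ins[k], window = window)
    per_qtl[[k]] <- call_high_pp_qtl(pp, threshold)
    if (keep_chains) chains[[k]] <- ch
  }
  per_qtl <- occurrence_rates(per_qtl)
  sel <- tryCatch(select_analysis(per_qtl, priors), error = function(e) NULL)
  structure(list(priors = priors, per_analysis_qtl = per_qtl,
                 avg_rates = if (is.null(sel)) rep(0, length(priors)) else sel$avg_rates,
                 selected = if (is.null(sel)) NA_integer_ else sel$selected,
                 qtl = if (is.null(sel)) qtl_calls(NULL) else per_qtl[[sel$selected]],
                 burn_ins = burn_ins,
                 chains = if (keep_chains) chains else NULL),
            class = "ensemble_result")
}
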