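# Storey-Tibshirani q-values and QTL calling by merging adjacent
# significant SNPs.

#' Estimate the null proportion pi0 from a vector of p-values
#'
#' Computes \eqn{\hat\pi_0(\lambda) = \#\{p > \lambda\} / (m (1 - \lambda))}
#' over the grid \eqn{\lambda = 0, 0.05, \dots, 0.90}, fits a natural cubic
#' smoothing spline (df = 3) to the points, and evaluates it at
#' \eqn{\lambda = 0.90}, clamped to \eqn{(\epsilon, 1]}. With fewer than 100
#' p-values the smoother is unreliable and 1 is returned.
#'
#' @param pvalues numeric vector in [0,1]
#' @param lambda evaluation grid
#' @return pi0 estimate in (0, 1]
#' @export
estimate_pi0 <- function(pvalues, lambda = seq(0, 0.90, by = 0.05)) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE) || anyNA(pvalues))
    stop("p-values must lie in [0,1] and be non-missing")
  m <- length(pvalues)
  if (m < 1L) stop("need at least one p-value")
  if (m < 100L) return(1)
  pi0_hat <- vapply(lambda, function(l) mean(pvalues > l) / (1 - l), numeric(1))
  fit <- smooth.spline(lambda, pi0_hat, df = 3)
  pi0 <- predict(fit, x = max(lambda))$y
  min(1, max(1e-8, pi0))
}

#' Storey-Tibshirani q-values
#'
#' Step-up over the order statistics: \eqn{q_{(m)} = \min(1, \pi_0 p_{(m)})}
#' and \eqn{q_{(i)} = \min(\pi_0 m p_{(i)} / i, q_{(i+1)})}. With
#' `pi0 = 1` this reduces exactly to the Benjamini-Hochberg adjustment.
#' Also reports `p_ssr`, the proportion of SNPs with `q >= 0.05`, which
#' seeds the Bayesian prior ensemble.
#'
#' @param pvalues numeric vector in [0,1]
#' @param pi0 null proportion; default estimated by [estimate_pi0()]
#' @return list of class `qvalue_result`: `p`, `q`, `pi0`, `p_ssr`
#' @export
qvalues <- function(pvalues, pi0 = estimate_pi0(pvalues)) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE) || anyNA(pvalues))
    stop("p-values must lie in [0,1] and be non-missing")
  stopifnot(pi0 > 0, pi0 <= 1)
  m <- length(pvalues)
  ord <- order(pvalues)
  ps <- pvalues[ord]
  qs <- numeric(m)
  qs[m] <- min(1, pi0 * ps[m])
  if (m > 1L) for (i in (m - 1L):1L) qs[i] <- min(pi0 * m * ps[i] / i, qs[i + 1L])
  q <- numeric(m)
  q[ord] <- qs
  structure(list(p = pvalues, q = q, pi0 = pi0, p_ssr = mean(q >= 0.05)),
            class = "qvalue_result")
}

#' Call SSR QTL by merging adjacent significant SNPs
#'
#' Maximal runs of map-adjacent SNPs with `q < alpha` are merged into one
#' QTL spanning the first to last member position; runs never cross
#' chromosome boundaries. Singleton significant SNPs form single-SNP QTL.
#'
#' @param qres `qvalue_result` aligned to the rows of `map`
#' @param map data.table with snp_id, chrom, pos sorted by (chrom, pos)
#' @param alpha significance threshold on q (default 0.05, strict `<`)
#' @return `qtl_calls` data.table: chrom, start_bp, end_bp, n_snps, snp_ids
#'   (list), member_pos (list), score (min q), source
#' @export
call_ssr_qtl <- function(qres, map, alpha = 0.05) {
  map <- as.data.table(map)
  stopifnot(length(qres$q) == nrow(map))
  sig <- qres$q < alpha
  qtl_calls(rbindlist(lapply(split(seq_len(nrow(map)), map$chrom), function(rows) {
    s <- sig[rows]
    if (!any(s)) return(NULL)
    r <- rle(s)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    rbindlist(lapply(runs, function(k) {
      mem <- rows[starts[k]:ends[k]]
      data.table(chrom = map$chrom[mem[1L]],
                 start_bp = map$pos[mem[1L]], end_bp = map$pos[mem[length(mem)]],
                 n_snps = length(mem),
                 snp_ids = list(map$snp_id[mem]),
                 member_pos = list(map$pos[mem]),
                 score = min(qres$q[mem]), source = "ssr")
    }))
  }), use.names = TRUE))
}

# Shared QTL-call container used by the SSR and Bayesian paths.
qtl_calls <- function(dt) {
  if (is.null(dt) || !nrow(dt))
    dt <- data.table(chrom = character(), start_bp = integer(),
                     end_bp = integer(), n_snps = integer(),
                     snp_ids = list(), member_pos = list(),
                     score = numeric(), source = character())
  setattr(dt, "class", c("qtl_calls", class(data.table())))
  dt[]
}

#' Write QTL calls as BED (0-based half-open)
#' @param qtl `qtl_calls`
#' @param path file path
#' @export
write_qtl_bed <- function(qtl, path) {
  lines <- if (nrow(qtl)) {
    sprintf("%s\t%d\t%d\t%s_qtl_%d\t%g", qtl$chrom, qtl$start_bp - 1L,
            qtl$end_bp, qtl$source, seq_len(nrow(qtl)), qtl$score)
  } else character()
  writeLines(lines, path)
  invisible(NULL)
}

#' Write the per-SNP p/q table
#' @param qres `qvalue_result`
#' @param map SNP map aligned with the p-values
#' @param path file path
#' @export
write_qvalues <- function(qres, map, path) {
  dt <- data.table(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
                   p = qres$p, q = qres$q)
  write.table(dt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
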