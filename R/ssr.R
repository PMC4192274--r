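# Single SNP regression: per-SNP fixed allele-count effect in an animal
# mixed model y = 1*mu + x_j*b_j + u + e, u ~ N(0, A*sigma2_a). Variance
# components are estimated once on the null model by REML through the
# eigendecomposition of A and held fixed across SNPs; each SNP is then a
# generalized least-squares fit in the rotated (diagonal-covariance) basis,
# with the residual scale re-estimated per SNP from the weighted RSS.

#' REML variance components for the null animal model
#'
#' Fits `y = 1*mu + u + e`, `u ~ N(0, A*sigma2_a)`, `e ~ N(0, I*sigma2_e)`
#' by restricted maximum likelihood. The likelihood is profiled over the
#' variance ratio `gamma = sigma2_a / sigma2_e` using the eigendecomposition
#' of A, and maximized by one-dimensional search on log(gamma).
#'
#' @param y phenotype_table (one trait) or numeric vector named by animal
#' @param amatrix `amatrix` covering the phenotyped animals
#' @return list of class `varcomp`: `sigma2_a`, `sigma2_e`, `h2`, `gamma`,
#'   plus the cached eigendecomposition and animal order used by [ssr_scan()]
#' @export
estimate_varcomp <- function(y, amatrix) {
  yv <- .pheno_vector(y)
  ids <- names(yv)
  if (length(yv) < 10L) stop("need at least 10 phenotyped animals")
  if (var(yv) == 0) stop("phenotype has zero variance")
  A <- subset_amatrix(amatrix, ids)
  eg <- eigen(A, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  if (min(eg$values) < -1e-6) stop("A-matrix is not positive semi-definite")
  U <- eg$vectors
  n <- length(yv)
  ystar <- drop(crossprod(U, yv))
  onestar <- drop(crossprod(U, rep(1, n)))
  reml_ll <- function(lg) {
    w <- exp(lg) * d + 1
    xtwx <- sum(onestar^2 / w)
    beta <- sum(onestar * ystar / w) / xtwx
    r <- ystar - onestar * beta
    rss <- sum(r^2 / w)
    s2 <- rss / (n - 1)
    -0.5 * ((n - 1) * log(s2) + sum(log(w)) + log(xtwx))
  }
  opt <- optimize(reml_ll, interval = c(-12, 12), maximum = TRUE, tol = 1e-8)
  gamma <- exp(opt$maximum)
  w <- gamma * d + 1
  beta <- sum(onestar * ystar / w) / sum(onestar^2 / w)
  sigma2_e <- sum((ystar - onestar * beta)^2 / w) / (n - 1)
  sigma2_a <- gamma * sigma2_e
  structure(list(sigma2_a = sigma2_a, sigma2_e = sigma2_e,
                 h2 = sigma2_a / (sigma2_a + sigma2_e), gamma = gamma,
                 reml_loglik = opt$objective,
                 eigen = list(U = U, d = d), animal_ids = ids),
            class = "varcomp")
}

.pheno_vector <- function(y) {
  if (inherits(y, "phenotype_table") || is.data.frame(y)) {
    y <- as.data.table(y)
    if (length(unique(y$trait)) > 1L)
      stop("phenotype table holds multiple traits; subset to one first")
    setNames(y$drp, y$animal)
  } else {
    if (is.null(names(y))) stop("numeric phenotype vector must be named by animal")
    y
  }
}

#' Genome scan by single-SNP generalized least squares
#'
#' For each SNP, fits `y = 1*mu + x_j*b_j` by GLS with covariance structure
#' `V = sigma2_a*A + sigma2_e*I` held fixed from `vc`; the residual scale is
#' re-estimated per SNP from the weighted residual sum of squares on
#' `n - 2` degrees of freedom, and a two-sided Wald p-value is taken against
#' the standard normal reference. Missing genotypes are mean-imputed per SNP.
#' SNPs with zero genotype variance are flagged degenerate with p = 1.
#'
#' @param gs genotype_set
#' @param y phenotype_table (one trait) or named numeric vector
#' @param amatrix `amatrix` (used only if `vc` carries no cached
#'   eigendecomposition for these animals)
#' @param vc `varcomp` from [estimate_varcomp()]
#' @return data.table of class `ssr_result`: snp_id, chrom, pos, effect, se,
#'   p, n, degenerate
#' @export
ssr_scan <- function(gs, y, amatrix, vc) {
  stopifnot(inherits(vc, "varcomp"))
  yv <- .pheno_vector(y)
  ids <- intersect(names(yv), gs$animal_ids)
  if (length(ids) < 3L) stop("fewer than 3 animals shared between genotypes and phenotypes")
  yv <- yv[ids]
  n <- length(ids)
  if (!is.null(vc$eigen) && identical(vc$animal_ids, ids)) {
    U <- vc$eigen$U; d <- vc$eigen$d
  } else {
    eg <- eigen(subset_amatrix(amatrix, ids), symmetric = TRUE)
    U <- eg$vectors; d <- pmax(eg$values, 0)
  }
  X <- mean_impute(gs$calls[match(ids, gs$animal_ids), , drop = FALSE])
  w <- vc$sigma2_a * d + vc$sigma2_e
  ystar <- drop(crossprod(U, yv))
  onestar <- drop(crossprod(U, rep(1, n)))
  Xstar <- crossprod(U, X)
  iw <- 1 / w
  a11 <- sum(onestar^2 * iw)
  a12 <- colSums(Xstar * (onestar * iw))
  a22 <- colSums(Xstar^2 * iw)
  b1 <- sum(onestar * ystar * iw)
  b2 <- colSums(Xstar * (ystar * iw))
  yy <- sum(ystar^2 * iw)
  det <- a11 * a22 - a12^2
  # degenerate: no genotype variation after imputation
  xvar <- a22 - a12^2 / a11
  degen <- xvar <= 1e-10 * pmax(a22, 1e-300)
  det[degen] <- NA_real_
  beta2 <- (a11 * b2 - a12 * b1) / det
  beta1 <- (b1 - a12 * beta2) / a11
  rss <- pmax(yy - beta1 * b1 - beta2 * b2, 0)
  scale <- rss / (n - 2)
  se <- sqrt(scale * a11 / det)
  z <- beta2 / se
  p <- 2 * pnorm(-abs(z))
  effect <- beta2; effect[degen] <- 0
  se[degen] <- NA_real_
  p[degen] <- 1
  out <- data.table(snp_id = gs$snp_ids, chrom = gs$map$chrom,
                    pos = gs$map$pos, effect = effect, se = se, p = p,
                    n = n, degenerate = degen)
  setattr(out, "class", c("ssr_result", class(data.table())))
  out[]
}

#' Write a genome-scan table (Manhattan-plot ready)
#' @param res `ssr_result`
#' @param path file path
#' @export
write_ssr <- function(res, path) {
  write.table(as.data.frame(res), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
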