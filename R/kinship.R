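# Pedigree additive (numerator) relationship matrix.

#' Build the additive relationship matrix from a pedigree
#'
#' Tabular (recursive) method over the topologically sorted pedigree:
#' the diagonal is \eqn{A_{kk} = 1 + 0.5 A_{sd}} (inbreeding enters through
#' the parents' relationship; 0 if either parent unknown) and off-diagonals
#' are \eqn{A_{jk} = 0.5 (A_{js} + A_{jd})} for animals j ordered before k.
#' Founders have diagonal exactly 1. The result is symmetric and positive
#' semi-definite. Dense storage; intended for pedigrees up to a few thousand
#' animals.
#'
#' @param ped a [pedigree()]
#' @return matrix of class `amatrix` with animal ids as dimnames
#' @export
build_amatrix <- function(ped) {
  ped <- if (inherits(ped, "pedigree")) ped else pedigree(ped)
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$animal)
  si <- unname(idx[ped$sire]); di <- unname(idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (k in seq_len(n)) {
    s <- si[k]; d <- di[k]
    if (k > 1L) {
      prev <- seq_len(k - 1L)
      row <- numeric(k - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[prev, s]
      if (!is.na(d)) row <- row + 0.5 * A[prev, d]
      A[prev, k] <- row
      A[k, prev] <- row
    }
    A[k, k] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  class(A) <- c("amatrix", "matrix", "array")
  A
}

#' Principal submatrix of an A-matrix in a requested animal order
#' @param amatrix an `amatrix` from [build_amatrix()]
#' @param animal_ids ids to keep, in the desired order
#' @return `amatrix` restricted to those animals
#' @export
subset_amatrix <- function(amatrix, animal_ids) {
  missing_ids <- setdiff(animal_ids, rownames(amatrix))
  if (length(missing_ids))
    stop("animals not in A-matrix: ", paste(head(missing_ids, 3), collapse = ", "))
  out <- amatrix[animal_ids, animal_ids, drop = FALSE]
  class(out) <- c("amatrix", "matrix", "array")
  out
}

#' Write an A-matrix as a square TSV with an id header
#' @param amatrix an `amatrix`
#' @param path file path
#' @export
write_amatrix <- function(amatrix, path) {
  df <- data.frame(id = rownames(amatrix), amatrix, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
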