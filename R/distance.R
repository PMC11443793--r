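#' Pairwise instance distances on genotype data
#'
#' The metric behind all nearest-neighbor logic: the number of features at
#' which two instances carry different genotypes (a per-feature difference of
#' 0 if equal and 1 otherwise -- Hamming, equivalent to Manhattan on this
#' encoding). Computed as three indicator-matrix crossproducts, so it is a
#' few BLAS calls rather than an m^2 n loop.
#'
#' @param x A `genotype_dataset` or an integer genotype matrix in `{0,1,2}`.
#' @return A symmetric `m x m` numeric matrix of mismatch counts with zero
#'   diagonal.
#' @examples
#' pairwise_distance(rbind(c(0, 1, 2), c(0, 2, 2)))
#' @export
pairwise_distance <- function(x) {
  X <- if (inherits(x, "genotype_dataset")) x$genotypes else x
  if (!is.matrix(X)) abort_invalid("`x` must be a matrix or genotype_dataset")
  if (nrow(X) < 2L) abort_invalid("need at least 2 instances")
  same <- matrix(0, nrow(X), nrow(X))
  for (v in 0:2) same <- same + tcrossprod((X == v) * 1)
  ncol(X) - same
}

# For each target t (row of W) sum the per-feature genotype mismatches to the
# instances flagged in W[t, ]: D[t, f] = |S_t| - #{j in S_t : X[j,f] == X[t,f]}.
# The match counts come from W %*% I_v for the three genotype indicators.
neighbor_diff_sums <- function(X, W) {
  counts <- rowSums(W)
  match <- matrix(0, nrow(X), ncol(X))
  for (v in 0:2) {
    Iv <- (X == v) * 1
    match <- match + Iv * (W %*% Iv)
  }
  counts - match
}

scorer_checks <- function(dataset, min_m = 2L) {
  if (!inherits(dataset, "genotype_dataset")) {
    abort_invalid("`dataset` must be a genotype_dataset")
  }
  m <- nrow(dataset$genotypes)
  if (m < min_m) abort_invalid(sprintf("need at least %d instances", min_m))
  cls <- tabulate(dataset$labels + 1L, 2L)
  if (any(cls < 2L)) {
    abort_degenerate("each class needs at least 2 instances for neighbor scoring")
  }
  invisible(m)
}

new_rba_scores <- function(scores, algorithm, dataset, nn = NULL) {
  names(scores) <- colnames(dataset$genotypes)
  structure(
    list(scores = scores, algorithm = algorithm, nn = nn,
         config_id = dataset$config_id,
         replicate_seed = dataset$replicate_seed),
    class = "rba_scores"
  )
}

#' @export
print.rba_scores <- function(x, ...) {
  cat(sprintf("%s scores%s for '%s': %d features, range [%.4g, %.4g]\n",
              x$algorithm, if (!is.null(x$nn)) sprintf(" (NN=%d)", x$nn) else "",
              x$config_id, length(x$scores), min(x$scores), max(x$scores)))
  invisible(x)
}

# Extract a plain named numeric score vector.
score_values <- function(scores) {
  if (inherits(scores, "rba_scores")) scores$scores
  else if (is.numeric(scores)) scores
  else abort_invalid("scores must be numeric or an rba_scores object")
}
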