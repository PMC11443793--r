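#' ReliefF feature scores
#'
#' Every instance serves once as the target. For each target the `nn` nearest
#' same-class instances (hits) and `nn` nearest opposite-class instances
#' (misses) are found under the genotype mismatch distance (ties broken by
#' ascending instance index), and each feature's weight accumulates the miss
#' differences minus the hit differences. The total is normalized by
#' `m * nn`, bounding scores to `[-1, 1]`.
#'
#' If a target has fewer than `nn` hits or misses available, all available
#' ones are used and one warning is emitted per dataset.
#'
#' @param dataset A `genotype_dataset`.
#' @param nn Number of nearest hits/misses per target (the run parameter NN).
#' @param dist Optional precomputed [pairwise_distance()] matrix.
#' @return An `rba_scores` object.
#' @examples
#' d <- make_xor_dataset(2, 20, 200, seed = 1)
#' s <- relieff_scores(d, nn = 10)
#' order(-abs(s$scores))[1:2]
#' @export
relieff_scores <- function(dataset, nn, dist = NULL) {
  m <- scorer_checks(dataset)
  if (!is.numeric(nn) || length(nn) != 1L || nn < 1 || nn >= m - 1) {
    abort_invalid("`nn` must be an integer in [1, m - 2]")
  }
  nn <- as.integer(nn)
  X <- dataset$genotypes
  y <- dataset$labels
  if (is.null(dist)) dist <- pairwise_distance(X)
  Wh <- matrix(0, m, m)
  Wm <- matrix(0, m, m)
  clamped <- FALSE
  idx <- seq_len(m)
  for (t in idx) {
    ord <- order(dist[t, ], idx)
    ord <- ord[ord != t]
    hit <- y[ord] == y[t]
    hits <- ord[hit]
    miss <- ord[!hit]
    kh <- min(nn, length(hits))
    km <- min(nn, length(miss))
    if (kh < nn || km < nn) clamped <- TRUE
    Wh[t, hits[seq_len(kh)]] <- 1
    Wm[t, miss[seq_len(km)]] <- 1
  }
  if (clamped) {
    warning(sprintf("fewer than nn = %d hits or misses for some targets; using all available", nn))
  }
  scores <- colSums(neighbor_diff_sums(X, Wm) - neighbor_diff_sums(X, Wh)) / (m * nn)
  new_rba_scores(scores, "relieff", dataset, nn = nn)
}
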