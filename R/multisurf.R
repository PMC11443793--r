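# MultiSURF and MultiSURF*: instead of a fixed neighbor count, each target
# defines "near" and "far" instances adaptively from its own distance
# distribution -- mean pairwise distance T_i, with a dead-band of
# deadband_multiplier * SD excluding ambiguous instances.

surf_geometry <- function(dist, deadband_multiplier) {
  if (deadband_multiplier < 0) abort_invalid("`deadband_multiplier` must be >= 0")
  m <- nrow(dist)
  thr <- rowSums(dist) / (m - 1)
  msq <- rowSums(dist^2) / (m - 1)
  dead <- deadband_multiplier * sqrt(pmax(msq - thr^2, 0))
  near <- dist < (thr - dead)
  far <- dist > (thr + dead)
  diag(near) <- FALSE
  diag(far) <- FALSE
  list(threshold = thr, deadband = dead, near = near, far = far)
}

#' Near/far partition of instances around one target
#'
#' The target's threshold is its mean mismatch distance to all other
#' instances and the dead-band is `deadband_multiplier` times the (population)
#' standard deviation of those distances. Instances strictly below
#' `threshold - deadband` are near; strictly above `threshold + deadband` are
#' far; the rest are ambiguous and excluded.
#'
#' @param dataset A `genotype_dataset` with at least 3 instances.
#' @param target Target instance index.
#' @param deadband_multiplier Dead-band width in SD units (default 0.5).
#' @param dist Optional precomputed distance matrix.
#' @return List with `target`, `threshold`, `deadband`, `near_set`, `far_set`
#'   (sorted instance indices, never containing the target).
#' @examples
#' d <- make_xor_dataset(2, 10, 30, seed = 1)
#' multisurf_partition(d, target = 1)$threshold
#' @export
multisurf_partition <- function(dataset, target, deadband_multiplier = 0.5,
                                dist = NULL) {
  m <- scorer_checks(dataset, min_m = 3L)
  if (target < 1L || target > m) abort_invalid("`target` out of range")
  if (is.null(dist)) dist <- pairwise_distance(dataset$genotypes)
  geo <- surf_geometry(dist, deadband_multiplier)
  list(target = as.integer(target),
       threshold = geo$threshold[target],
       deadband = geo$deadband[target],
       near_set = which(geo$near[target, ]),
       far_set = which(geo$far[target, ]))
}

surf_engine <- function(dataset, deadband_multiplier, dist, far_scoring) {
  m <- scorer_checks(dataset, min_m = 3L)
  X <- dataset$genotypes
  y <- dataset$labels
  if (is.null(dist)) dist <- pairwise_distance(X)
  geo <- surf_geometry(dist, deadband_multiplier)
  hit_mask <- outer(y, y, `==`)

  # Per-target side term: count-normalized mean feature difference to the
  # instances in W's rows; rows with an empty side contribute zero.
  side <- function(W) {
    cnt <- rowSums(W)
    D <- neighbor_diff_sums(X, W)
    D[cnt > 0, ] <- D[cnt > 0, , drop = FALSE] / cnt[cnt > 0]
    D
  }

  near_term <- side(geo$near & !hit_mask) - side(geo$near & hit_mask)
  if (!far_scoring) return(colSums(near_term) / m)
  # far instances score with inverted sign; near and far halves are averaged
  # so the total stays within [-1, 1]
  far_term <- side(geo$far & hit_mask) - side(geo$far & !hit_mask)
  colSums(near_term + far_term) / (2 * m)
}

#' MultiSURF feature scores
#'
#' Near-only scoring: for each target, near hits and near misses (see
#' [multisurf_partition()]) update each feature's weight by the miss
#' differences minus the hit differences, each side normalized by its own
#' member count for that target; targets with an empty side contribute
#' nothing from that side. The sum over targets is divided by `m`.
#'
#' @inheritParams multisurf_partition
#' @return An `rba_scores` object.
#' @export
multisurf_scores <- function(dataset, deadband_multiplier = 0.5, dist = NULL) {
  s <- surf_engine(dataset, deadband_multiplier, dist, far_scoring = FALSE)
  new_rba_scores(s, "multisurf", dataset)
}

#' MultiSURF* feature scores
#'
#' As [multisurf_scores()], plus inverse scoring of far instances: beyond the
#' far threshold, hit differences add to and miss differences subtract from a
#' feature's weight (count-normalized per side). Far scoring boosts power for
#' pure pairwise interactions but suppresses univariate effects. The near and
#' far contributions are averaged per target, keeping scores in `[-1, 1]`.
#'
#' @inheritParams multisurf_partition
#' @return An `rba_scores` object.
#' @export
multisurfstar_scores <- function(dataset, deadband_multiplier = 0.5, dist = NULL) {
  s <- surf_engine(dataset, deadband_multiplier, dist, far_scoring = TRUE)
  new_rba_scores(s, "multisurfstar", dataset)
}
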