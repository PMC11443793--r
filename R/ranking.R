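# Ranking schemes and the weakest-link statistic.

#' Order features by score under a ranking scheme
#'
#' Standard ranking sorts raw scores in descending order (most positive
#' first); absolute-value ranking sorts `|score|` in descending order so that
#' strongly negative weights are prioritized alongside strongly positive
#' ones. Ties are broken by ascending feature index.
#'
#' @param scores An `rba_scores` object or numeric vector.
#' @param scheme `"standard"` or `"absolute"`.
#' @return Integer vector of feature indices, best rank first (a permutation
#'   of `seq_along(scores)`).
#' @examples
#' rank_features(c(0.5, -0.9, 0.1), "standard")  # 1 3 2
#' rank_features(c(0.5, -0.9, 0.1), "absolute")  # 2 1 3
#' @export
rank_features <- function(scores, scheme = c("standard", "absolute")) {
  scheme <- match.arg(scheme)
  s <- score_values(scores)
  if (any(!is.finite(s))) abort_invalid("scores must be finite")
  key <- if (scheme == "absolute") abs(s) else s
  order(-key, seq_along(key))
}

#' Weakest-link rank of the predictive features
#'
#' The worst (largest) 1-based position among the known predictive features
#' in an ordering: e.g. predictive features ranked 1st and 5th give 5.
#' Missing even one predictive feature breaks feature selection for
#' interactions, so only this worst position is evaluated.
#'
#' @param ordering Feature indices best-first, as from [rank_features()] or a
#'   [shuffle_ranking()] `$ordering`.
#' @param predictive_idx Indices of the known predictive features.
#' @return Integer weakest-link position.
#' @examples
#' weakest_link_rank(c(3, 1, 4, 2, 5), predictive_idx = c(1, 2))  # 4
#' @export
weakest_link_rank <- function(ordering, predictive_idx) {
  pos <- match(predictive_idx, ordering)
  if (anyNA(pos)) abort_integrity("a predictive feature is absent from the ordering")
  max(pos)
}

#' Weakest link directly from scores
#'
#' Convenience wrapper combining [rank_features()] and [weakest_link_rank()],
#' with an optional pessimistic tie mode for sensitivity analysis: under
#' `ties = "pessimistic"` every predictive feature is placed after all
#' features tied with it (the worst outcome any tie-breaking could produce).
#'
#' @inheritParams rank_features
#' @param predictive_idx Indices of the known predictive features.
#' @param ties `"index"` (deterministic ascending-index tie-break) or
#'   `"pessimistic"`.
#' @return Integer weakest-link position.
#' @export
weakest_link <- function(scores, predictive_idx,
                         scheme = c("standard", "absolute"),
                         ties = c("index", "pessimistic")) {
  scheme <- match.arg(scheme)
  ties <- match.arg(ties)
  s <- score_values(scores)
  if (ties == "index") {
    return(weakest_link_rank(rank_features(s, scheme), predictive_idx))
  }
  key <- if (scheme == "absolute") abs(s) else s
  if (any(predictive_idx < 1L | predictive_idx > length(key))) {
    abort_integrity("a predictive feature is absent from the ordering")
  }
  as.integer(max(vapply(predictive_idx, function(i) {
    sum(key > key[i]) + sum(key == key[i])
  }, numeric(1))))
}

#' Power curve over ranking positions
#'
#' For each of the `n` possible ranking positions, the percentage of
#' replicates whose weakest link is at or better than that position. Curves
#' are non-decreasing and reach 100 at position `n`.
#'
#' @param weakest_links Integer vector of weakest-link positions (one per
#'   replicate), each in `[1, n]`.
#' @param n Number of features (ranking positions).
#' @return Numeric vector of length `n` with percentages in `[0, 100]`.
#' @examples
#' power_curve(c(2, 4), n = 5)  # 0 50 50 100 100
#' @export
power_curve <- function(weakest_links, n) {
  if (length(weakest_links) < 1L) abort_invalid("need at least one replicate")
  if (any(weakest_links < 1L | weakest_links > n)) {
    abort_invalid("weakest links must lie in [1, n]")
  }
  vapply(seq_len(n), function(p) 100 * mean(weakest_links <= p), numeric(1))
}

#' Analytic power curve of the random-shuffle control
#'
#' Under a uniform random permutation of `n` features, the weakest link of
#' `k` predictive features is the maximum of `k` draws without replacement
#' from `1..n`, with CDF `P(max <= p) = choose(p, k) / choose(n, k)`.
#'
#' @param n Number of features.
#' @param n_predictive Number of predictive features `k`.
#' @return Numeric vector of length `n`: the exact expected power curve (in
#'   percent) of the shuffle control.
#' @examples
#' shuffle_power_curve(5, 2)
#' @export
shuffle_power_curve <- function(n, n_predictive) {
  if (n_predictive < 1L || n_predictive > n) {
    abort_invalid("`n_predictive` must lie in [1, n]")
  }
  100 * choose(seq_len(n), n_predictive) / choose(n, n_predictive)
}
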