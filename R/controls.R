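# Negative-control ranking methods: plug-in mutual information (univariate
# benchmark) and a random shuffle of the feature order.

#' Mutual information feature scores
#'
#' Exact plug-in estimator of the mutual information between each discrete
#' genotype (3 levels) and the binary class, in nats:
#' `I = sum p(g, y) * log(p(g, y) / (p(g) p(y)))`, empty cells contributing
#' zero. Plug-in MI is nonnegative; as a guard for alternative estimators the
#' result is clipped at zero.
#'
#' @param dataset A `genotype_dataset`.
#' @return An `rba_scores` object with algorithm `"mutual_information"`.
#' @examples
#' d <- make_xor_dataset(2, 10, 200, seed = 1)
#' mutual_info_scores(d)$scores[1:3]
#' @export
mutual_info_scores <- function(dataset) {
  if (!inherits(dataset, "genotype_dataset")) {
    abort_invalid("`dataset` must be a genotype_dataset")
  }
  y <- dataset$labels
  if (length(unique(y)) < 2L) abort_degenerate("mutual information requires both classes")
  m <- length(y)
  py <- tabulate(y + 1L, 2L) / m
  scores <- apply(dataset$genotypes, 2L, function(g) {
    joint <- table(factor(g, levels = 0:2), factor(y, levels = 0:1)) / m
    pg <- rowSums(joint)
    mi <- 0
    for (i in 1:3) for (j in 1:2) {
      if (joint[i, j] > 0) {
        mi <- mi + joint[i, j] * log(joint[i, j] / (pg[i] * py[j]))
      }
    }
    mi
  })
  new_rba_scores(pmax(as.numeric(scores), 0), "mutual_information", dataset)
}

#' Random-shuffle feature ranking
#'
#' The no-information negative control: a uniform random permutation of the
#' feature indices, reproducible from the seed.
#'
#' @param dataset A `genotype_dataset` (or a single integer, the number of
#'   features).
#' @param seed Optional integer seed.
#' @return A list of class `control_ranking` with `method`, `ordering` (a
#'   permutation of the feature indices, best rank first) and `seed`.
#' @examples
#' shuffle_ranking(make_xor_dataset(2, 5, 20, seed = 1), seed = 3)$ordering
#' @export
shuffle_ranking <- function(dataset, seed = NULL) {
  n <- if (inherits(dataset, "genotype_dataset")) ncol(dataset$genotypes)
       else as.integer(dataset)
  if (is.na(n) || n < 1L) abort_invalid("need at least one feature")
  ordering <- with_seed(seed, sample.int(n))
  structure(list(method = "random_shuffle", ordering = ordering, seed = seed),
            class = "control_ranking")
}
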