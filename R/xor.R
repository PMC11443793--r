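# Clean k-way XOR interaction models.
#
# Each predictive locus is drawn at MAF 0.5 and binarized by heterozygosity
# (P(heterozygous) = 0.5 under HWE), and the class is the parity (XOR) of
# those bits. The implied penetrance table takes only the values 0 and 1
# (full penetrance, heritability 1), and because the parity of any nonempty
# set of fair bits is itself a fair bit, every proper-subset marginal equals
# 0.5 exactly: the model is pure, strict and clean for every order.

#' Penetrance model implied by the k-way XOR construction
#'
#' @param order Interaction order (2 to 5).
#' @return A `penetrance_model` whose table over `{0,1,2}^k` is 1 where the
#'   number of heterozygous loci is odd and 0 elsewhere, with MAF 0.5 at each
#'   locus, prevalence 0.5 and heritability 1.
#' @examples
#' verify_pure_strict(xor_penetrance_model(2))
#' @export
xor_penetrance_model <- function(order) {
  if (!order %in% 2:5) abort_invalid("XOR `order` must be 2, 3, 4 or 5")
  G <- genotype_grid(order)
  f <- as.numeric(rowSums(G == 1L) %% 2 == 1)
  new_penetrance_model(order, f, rep(0.5, order), prevalence = 0.5,
                       heritability = 1, difficulty = "na")
}

#' Generate a clean k-way XOR dataset
#'
#' The first `order` columns are the predictive loci; the class label is the
#' parity of their heterozygosity indicators, so the phenotype is a
#' deterministic, non-linearly separable function of the predictive genotypes
#' (full penetrance). The remaining columns are independent non-predictive
#' loci, all at MAF 0.5.
#'
#' @param order Interaction order (2 to 5).
#' @param n_total Total number of features (>= `order`).
#' @param m Number of instances.
#' @param seed Optional integer seed.
#' @param config_id Configuration key stored in the dataset (defaults to
#'   `"xor_k<order>_n<n_total>"`).
#' @return A `genotype_dataset`.
#' @examples
#' d <- make_xor_dataset(2, n_total = 20, m = 200, seed = 1)
#' mean(d$labels)
#' @export
make_xor_dataset <- function(order, n_total, m, seed = NULL, config_id = NULL) {
  if (!order %in% 2:5) abort_invalid("XOR `order` must be 2, 3, 4 or 5")
  if (n_total < order) abort_invalid("`n_total` must be at least `order`")
  if (m < 1) abort_invalid("`m` must be positive")
  if (is.null(config_id)) config_id <- sprintf("xor_k%d_n%d", order, n_total)
  with_seed(seed, {
    X <- sample_genotypes(rep(0.5, n_total), m)
    y <- as.integer(rowSums(X[, seq_len(order), drop = FALSE] == 1L) %% 2)
    colnames(X) <- c(sprintf("M0P%d", seq_len(order) - 1L),
                     if (n_total > order) sprintf("N%d", seq_len(n_total - order) - 1L))
    new_genotype_dataset(X, y, predictive_idx = seq_len(order),
                         config_id = config_id, replicate_seed = seed)
  })
}
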