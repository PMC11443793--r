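# Pure/strict k-locus penetrance models under Hardy-Weinberg weights.
#
# A table f over {0,1,2}^k is "pure and strict" when the penetrance
# marginalized onto any nonempty proper subset of its loci is constant:
# no univariate effects, no lower-order interactions. In the HWE-weighted
# functional-ANOVA decomposition of f this means only the grand mean and
# the full k-way interaction component are nonzero, so valid tables are
# built by projecting random candidates onto that top-order component and
# rescaling to the requested prevalence and heritability.

# Enumerate {0,1,2}^k, one genotype combination per row (3^k rows).
genotype_grid <- function(order) {
  # locus 1 varies fastest: row index = 1 + sum_j g_j * 3^(j-1)
  G <- as.matrix(expand.grid(rep(list(0:2), order), KEEP.OUT.ATTRS = FALSE))
  dimnames(G) <- NULL
  G
}

# HWE probability of each genotype combination (rows of genotype_grid).
genotype_cell_probs <- function(mafs) {
  G <- genotype_grid(length(mafs))
  pl <- lapply(mafs, hwe_probs)
  Reduce(`*`, lapply(seq_along(mafs), function(j) pl[[j]][G[, j] + 1L]))
}

# Integer key identifying the genotype restricted to loci S (0 when S empty).
subset_key <- function(G, S) {
  if (length(S) == 0L) return(rep(0, nrow(G)))
  as.vector(G[, S, drop = FALSE] %*% 3^(seq_along(S) - 1))
}

# Marginal penetrance over loci S: expectation of f over the complementary
# loci under their HWE weights, one value per genotype of S.
subset_marginal <- function(f, mafs, S) {
  k <- length(mafs)
  G <- genotype_grid(k)
  Cc <- setdiff(seq_len(k), S)
  wC <- if (length(Cc) == 0L) rep(1, length(f)) else {
    pl <- lapply(mafs, hwe_probs)
    Reduce(`*`, lapply(Cc, function(j) pl[[j]][G[, j] + 1L]))
  }
  key <- subset_key(G, S)
  tapply(f * wC, key, sum)[as.character(sort(unique(key)))]
}

# Full k-way interaction component: successively center over each locus
# (weighted by its HWE distribution). Every proper-subset marginal of the
# result is exactly zero.
interaction_component <- function(f, mafs) {
  k <- length(mafs)
  G <- genotype_grid(k)
  pl <- lapply(mafs, hwe_probs)
  d <- f
  for (j in seq_len(k)) {
    key <- subset_key(G, setdiff(seq_len(k), j))
    w <- pl[[j]][G[, j] + 1L]
    mns <- tapply(d * w, key, sum)
    d <- d - as.vector(mns[as.character(key)])
  }
  d
}

new_penetrance_model <- function(order, table, mafs, prevalence, heritability,
                                 difficulty = "na") {
  structure(
    list(order = as.integer(order), table = as.numeric(table),
         mafs = as.numeric(mafs), prevalence = prevalence,
         heritability = heritability, difficulty = difficulty),
    class = "penetrance_model"
  )
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat(sprintf(
    "penetrance model: %d-locus, K = %.4f, h2 = %.4f, MAFs = %s, difficulty = %s\n",
    x$order, x$prevalence, x$heritability,
    paste(format(x$mafs), collapse = "/"), x$difficulty))
  invisible(x)
}

#' Recompute prevalence from a penetrance table
#'
#' @param model A `penetrance_model`.
#' @return The population prevalence K: the HWE-weighted mean of the table.
#' @export
model_prevalence <- function(model) {
  sum(genotype_cell_probs(model$mafs) * model$table)
}

#' Recompute broad-sense heritability from a penetrance table
#'
#' @param model A `penetrance_model`.
#' @return `Var(f) / (K (1 - K))` with variance taken under HWE genotype
#'   probabilities.
#' @export
model_heritability <- function(model) {
  P <- genotype_cell_probs(model$mafs)
  K <- sum(P * model$table)
  sum(P * (model$table - K)^2) / (K * (1 - K))
}

# Detectability proxy used to grade model difficulty: weighted mean absolute
# penetrance deviation over weighted SD. High values mean the signal sits in
# common genotype cells (easy to detect from finite samples); low values mean
# it is spiked into rare cells (hard).
model_detectability <- function(model) {
  P <- genotype_cell_probs(model$mafs)
  K <- sum(P * model$table)
  d <- model$table - K
  sum(P * abs(d)) / sqrt(sum(P * d^2))
}

#' Generate a random pure/strict penetrance model
#'
#' Searches for a k-locus penetrance table with the requested heritability by
#' constrained random search: a uniform random candidate table is projected
#' onto the subspace in which every marginal over a proper subset of loci is
#' constant (so the model carries no univariate or lower-order effects), the
#' deviations are rescaled to hit the target heritability at the candidate
#' prevalence, and the table is accepted if all penetrances stay in [0, 1].
#' For `order = 1` the pure/strict constraint is vacuous and only the
#' heritability is matched.
#'
#' Some (heritability, MAF, prevalence) combinations admit no valid table --
#' notably high heritability at low MAF for 3-way models -- in which case a
#' feasibility error reporting the number of attempts is raised.
#'
#' @param order Number of interacting loci (1, 2 or 3).
#' @param heritability Target broad-sense heritability in `(0, 1)`.
#' @param mafs Minor-allele frequencies of the loci (recycled to `order`);
#'   default 0.2.
#' @param prevalence Population prevalence K, or `NULL` (default) to sample a
#'   feasible K uniformly from (0.05, 0.5) per candidate, as penetrance-table
#'   simulators conventionally let K float.
#' @param difficulty `"na"` (first valid model), `"easy"` or `"hard"`:
#'   generate `pop_size` valid models, rank them by a detectability score,
#'   and draw from the top or bottom decile respectively.
#' @param pop_size Population size used for difficulty selection.
#' @param max_tries Candidate budget before declaring infeasibility.
#' @param seed Optional integer seed.
#' @return A `penetrance_model` with fields `order`, `table` (length `3^order`,
#'   ordered as `genotype_grid(order)` rows), `mafs`, `prevalence`,
#'   `heritability`, `difficulty`.
#' @examples
#' m <- make_penetrance_model(2, heritability = 0.4, seed = 7)
#' model_heritability(m)
#' @export
make_penetrance_model <- function(order, heritability, mafs = 0.2,
                                  prevalence = NULL,
                                  difficulty = c("na", "easy", "hard"),
                                  pop_size = 50, max_tries = 20000,
                                  seed = NULL) {
  difficulty <- match.arg(difficulty)
  if (!order %in% 1:3) abort_invalid("`order` must be 1, 2 or 3")
  if (!is.numeric(heritability) || heritability <= 0 || heritability >= 1) {
    abort_invalid("`heritability` must lie in (0, 1)")
  }
  mafs <- rep_len(mafs, order)
  check_maf(mafs)
  if (!is.null(prevalence) &&
      (prevalence <= 0 || prevalence >= 1)) {
    abort_invalid("`prevalence` must lie in (0, 1)")
  }

  with_seed(seed, {
    n_needed <- if (difficulty == "na") 1L else as.integer(pop_size)
    found <- vector("list", n_needed)
    n_found <- 0L
    tries <- 0L
    P <- genotype_cell_probs(mafs)
    while (n_found < n_needed && tries < max_tries) {
      tries <- tries + 1L
      d <- interaction_component(stats::runif(3^order), mafs)
      v <- sum(P * d^2)
      if (v < 1e-12) next
      K <- if (is.null(prevalence)) stats::runif(1, 0.05, 0.5) else prevalence
      tab <- K + sqrt(heritability * K * (1 - K) / v) * d
      if (all(tab >= 0 & tab <= 1)) {
        n_found <- n_found + 1L
        found[[n_found]] <- new_penetrance_model(order, tab, mafs, K,
                                                 heritability, difficulty)
      }
    }
    if (n_found < n_needed) {
      abort_feasibility(sprintf(
        paste0("no valid pure/strict table found for order=%d, h2=%g, ",
               "mafs=%s%s after %d attempts (%d found, %d required)"),
        order, heritability, paste(format(mafs), collapse = "/"),
        if (is.null(prevalence)) "" else sprintf(", K=%g", prevalence),
        tries, n_found, n_needed))
    }
    if (difficulty == "na") return(found[[1L]])
    det <- vapply(found, model_detectability, numeric(1))
    n_dec <- max(1L, ceiling(n_needed / 10))
    pool <- if (difficulty == "easy") order(det, decreasing = TRUE)[seq_len(n_dec)]
            else order(det)[seq_len(n_dec)]
    found[[pool[sample.int(length(pool), 1L)]]]
  })
}

#' Verify that a penetrance model is pure and strict
#'
#' Brute-force check: marginalizes the penetrance table onto every nonempty
#' proper subset of its loci (weighting the complementary loci by their HWE
#' genotype probabilities) and tests whether each marginal is constant.
#'
#' @param model A `penetrance_model` of order >= 2.
#' @param tol Maximum allowed deviation (max - min) of any subset marginal.
#' @return A list with `pure_strict` (logical) and `max_deviation` (largest
#'   marginal deviation found over all proper subsets).
#' @examples
#' verify_pure_strict(xor_penetrance_model(3))
#' @export
verify_pure_strict <- function(model, tol = 1e-9) {
  k <- model$order
  if (k < 2) abort_invalid("pure/strict verification requires order >= 2")
  max_dev <- 0
  for (sz in seq_len(k - 1)) {
    for (S in utils::combn(k, sz, simplify = FALSE)) {
      marg <- subset_marginal(model$table, model$mafs, S)
      max_dev <- max(max_dev, max(marg) - min(marg))
    }
  }
  list(pure_strict = max_dev <= tol, max_deviation = max_dev)
}

# Penetrance values for observed genotypes at the model's loci.
penetrance_lookup <- function(model, geno) {
  geno <- as.matrix(geno)
  if (ncol(geno) != model$order) {
    abort_invalid("genotype matrix must have one column per model locus")
  }
  idx <- 1 + as.vector(geno %*% 3^(seq_len(model$order) - 1))
  model$table[idx]
}
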