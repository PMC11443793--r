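#' Hardy-Weinberg genotype probabilities
#'
#' @param maf Minor-allele frequency in `(0, 0.5]`.
#' @return Probabilities of genotypes (0, 1, 2) = (homozygous major,
#'   heterozygous, homozygous minor): `((1-p)^2, 2p(1-p), p^2)`.
#' @export
hwe_probs <- function(maf) {
  check_maf(maf)
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

check_maf <- function(maf) {
  if (!is.numeric(maf) || any(!is.finite(maf)) || any(maf <= 0) || any(maf > 0.5)) {
    abort_invalid("minor-allele frequencies must lie in (0, 0.5]")
  }
  invisible(maf)
}

#' Sample a genotype matrix under Hardy-Weinberg equilibrium
#'
#' Each column (locus) is drawn i.i.d. from the HWE genotype distribution at
#' its own minor-allele frequency; loci are independent (no linkage
#' disequilibrium).
#'
#' @param maf Vector of minor-allele frequencies, one per locus, each in
#'   `(0, 0.5]`.
#' @param m Number of instances (rows) to draw.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return An `m x length(maf)` integer matrix with entries in `{0, 1, 2}`.
#' @examples
#' g <- sample_genotypes(c(0.2, 0.5), m = 100, seed = 1)
#' table(g[, 1])
#' @export
sample_genotypes <- function(maf, m, seed = NULL) {
  check_maf(maf)
  if (!is.numeric(m) || length(m) != 1L || m < 1) {
    abort_invalid("`m` must be a positive integer")
  }
  m <- as.integer(m)
  with_seed(seed, {
    g <- vapply(maf, function(p) {
      sample.int(3L, m, replace = TRUE, prob = hwe_probs(p)) - 1L
    }, integer(m))
    matrix(as.integer(g), nrow = m)
  })
}
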