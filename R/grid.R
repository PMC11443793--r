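# The simulation study grid: every dataset family with its configuration
# variations (predictive/total features, heritability, instances, model
# difficulty, subgroup or weight ratios), 30 replicates per configuration.

grid_row <- function(config_id, group, order, n_predictive, n_total,
                     heritability, m, difficulty = NA_character_,
                     ratio = NA_character_, replicates = 30L) {
  data.frame(config_id = config_id, group = group, order = order,
             n_predictive = n_predictive, n_total = n_total,
             heritability = heritability, m = m, difficulty = difficulty,
             ratio = ratio, replicates = replicates,
             stringsAsFactors = FALSE)
}

#' Enumerate the simulation study's experiment configurations
#'
#' Builds the full grid of dataset configurations, one row per configuration:
#' \describe{
#'   \item{xor}{clean full-penetrance XOR interactions, orders 2-5 at total
#'     feature counts 20, 40, 60, 80, 100; 1600 instances (20 configurations).}
#'   \item{core2way}{noisy pure/strict 2-way models, 2 of 100 features,
#'     difficulty easy/hard x heritability 0.05/0.1/0.2/0.4 x instances
#'     200/400/800/1600 (32 configurations).}
#'   \item{featurescale}{noisy 2-way at heritability 0.4, 1600 instances,
#'     total features 1000, 10000 and 100000 (the 100-feature point is the
#'     core group's); the 100000-feature configuration is listed at 10000
#'     features with reduced replicates unless `full_scale = TRUE`.}
#'   \item{hetero2way}{two independent 2-way models, each predictive for one
#'     instance subgroup, subgroup prevalences 50:50 and 75:25.}
#'   \item{epi3way}{noisy pure/strict 3-way model at heritability 0.2 (0.4 is
#'     infeasible for pure/strict 3-way tables at these MAFs).}
#'   \item{univariate}{single-locus models, difficulty easy/hard x
#'     heritability 0.05/0.1/0.2/0.4 (8 configurations).}
#'   \item{additive2, additive4}{2 and 4 single-locus models combined
#'     additively on the penetrance scale (weights 50:50 / 75:25 for the
#'     2-feature group, equal for the 4-feature group).}
#' }
#'
#' @param groups Which dataset families to include (default: all).
#' @param replicates Replicate datasets per configuration (default 30).
#' @param full_scale Include the 100000-feature configuration at full size.
#' @return A data.frame with one row per configuration: `config_id`, `group`,
#'   `order`, `n_predictive`, `n_total`, `heritability`, `m`, `difficulty`,
#'   `ratio`, `replicates`.
#' @examples
#' nrow(experiment_grid("xor"))
#' @export
experiment_grid <- function(groups = c("xor", "core2way", "featurescale",
                                       "hetero2way", "epi3way", "univariate",
                                       "additive2", "additive4"),
                            replicates = 30L, full_scale = FALSE) {
  groups <- match.arg(groups, several.ok = TRUE)
  if (replicates < 1L) abort_invalid("`replicates` must be >= 1")
  rows <- list()
  if ("xor" %in% groups) {
    for (k in 2:5) for (n in seq(20L, 100L, by = 20L)) {
      rows[[length(rows) + 1L]] <- grid_row(
        sprintf("xor_k%d_n%d", k, n), "xor", k, k, n,
        heritability = 1, m = 1600L, replicates = replicates)
    }
  }
  if ("core2way" %in% groups) {
    for (dif in c("easy", "hard")) for (h in c(0.05, 0.1, 0.2, 0.4)) {
      for (m in c(200L, 400L, 800L, 1600L)) {
        rows[[length(rows) + 1L]] <- grid_row(
          sprintf("core2way_%s_h%s_m%d", dif, format(h), m), "core2way",
          2L, 2L, 100L, h, m, difficulty = dif, replicates = replicates)
      }
    }
  }
  if ("featurescale" %in% groups) {
    for (n in c(1000L, 10000L, 100000L)) {
      n_eff <- if (n == 100000L && !full_scale) 10000L else n
      reps <- if (n == 100000L && !full_scale) max(1L, replicates %/% 3L) else replicates
      rows[[length(rows) + 1L]] <- grid_row(
        sprintf("featurescale_n%d%s", n,
                if (n_eff != n) "_scaled" else ""), "featurescale",
        2L, 2L, n_eff, 0.4, 1600L, difficulty = "easy", replicates = reps)
    }
  }
  if ("hetero2way" %in% groups) {
    for (r in c("50:50", "75:25")) {
      rows[[length(rows) + 1L]] <- grid_row(
        sprintf("hetero2way_r%s", gsub(":", "-", r)), "hetero2way",
        2L, 4L, 100L, 0.4, 1600L, difficulty = "easy", ratio = r,
        replicates = replicates)
    }
  }
  if ("epi3way" %in% groups) {
    rows[[length(rows) + 1L]] <- grid_row(
      "epi3way_h0.2", "epi3way", 3L, 3L, 100L, 0.2, 1600L,
      difficulty = "easy", replicates = replicates)
  }
  if ("univariate" %in% groups) {
    for (dif in c("easy", "hard")) for (h in c(0.05, 0.1, 0.2, 0.4)) {
      rows[[length(rows) + 1L]] <- grid_row(
        sprintf("univariate_%s_h%s", dif, format(h)), "univariate",
        1L, 1L, 100L, h, 1600L, difficulty = dif, replicates = replicates)
    }
  }
  if ("additive2" %in% groups) {
    for (r in c("50:50", "75:25")) {
      rows[[length(rows) + 1L]] <- grid_row(
        sprintf("additive2_w%s", gsub(":", "-", r)), "additive2",
        1L, 2L, 100L, 0.4, 1600L, difficulty = "easy", ratio = r,
        replicates = replicates)
    }
  }
  if ("additive4" %in% groups) {
    rows[[length(rows) + 1L]] <- grid_row(
      "additive4", "additive4", 1L, 4L, 100L, 0.4, 1600L,
      difficulty = "easy", replicates = replicates)
  }
  do.call(rbind, rows)
}

#' The clean XOR configuration grid
#'
#' @param replicates Replicates per configuration.
#' @return The 20 XOR configurations (orders 2-5 x feature counts
#'   20, 40, 60, 80, 100).
#' @export
xor_grid <- function(replicates = 30L) {
  experiment_grid("xor", replicates = replicates)
}
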