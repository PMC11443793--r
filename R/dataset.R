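# The genotype_dataset container: an integer genotype matrix in {0,1,2}
# (rows = instances, columns = features, named), a binary label vector, and
# the indices of the known predictive features.

new_genotype_dataset <- function(genotypes, labels, predictive_idx,
                                 config_id = NA_character_,
                                 replicate_seed = NULL) {
  ds <- structure(
    list(genotypes = genotypes, labels = as.integer(labels),
         predictive_idx = as.integer(predictive_idx),
         config_id = config_id,
         replicate_seed = if (is.null(replicate_seed)) NA_integer_
                          else as.integer(replicate_seed)),
    class = "genotype_dataset"
  )
  validate_dataset(ds)
}

#' Validate a genotype dataset
#'
#' Checks the container invariants: genotypes integer in `{0,1,2}`, labels in
#' `{0,1}`, predictive indices nonempty and within the feature range.
#'
#' @param ds A `genotype_dataset`.
#' @return `ds`, invisibly, or an invalid-parameter error.
#' @export
validate_dataset <- function(ds) {
  X <- ds$genotypes
  if (!is.matrix(X) || !all(X %in% 0:2)) {
    abort_invalid("genotypes must be a matrix with entries in {0, 1, 2}")
  }
  if (length(ds$labels) != nrow(X) || !all(ds$labels %in% 0:1)) {
    abort_invalid("labels must be {0, 1} with one entry per instance")
  }
  p <- ds$predictive_idx
  if (length(p) == 0L || any(p < 1L) || any(p > ncol(X)) || anyDuplicated(p)) {
    abort_invalid("predictive_idx must be a nonempty set of feature columns")
  }
  invisible(ds)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf(
    "genotype dataset '%s': %d instances x %d features, %d predictive, %.1f%% cases\n",
    x$config_id, nrow(x$genotypes), ncol(x$genotypes),
    length(x$predictive_idx), 100 * mean(x$labels)))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$genotypes)

parse_ratio <- function(ratio) {
  parts <- suppressWarnings(as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1L]]))
  if (length(parts) < 2L || any(!is.finite(parts)) ||
      abs(sum(parts) - 100) > 1e-9) {
    abort_invalid(sprintf("subgroup ratio '%s' must be percentages summing to 100", ratio))
  }
  parts / 100
}

# Draw `n_cases` cases and `n_controls` controls by rejection sampling:
# genotypes for all loci are sampled HWE, the penetrance function maps the
# full genotype row to P(case), and labels are Bernoulli draws. This is the
# balanced case/control sampling scheme of penetrance-table simulators.
sample_case_control <- function(mafs, penet_fun, n_cases, n_controls,
                                batch = 4096L, max_batches = 5000L) {
  cases <- matrix(0L, 0L, length(mafs))
  controls <- matrix(0L, 0L, length(mafs))
  for (b in seq_len(max_batches)) {
    if (nrow(cases) >= n_cases && nrow(controls) >= n_controls) break
    X <- sample_genotypes(mafs, batch)
    y <- stats::rbinom(batch, 1L, penet_fun(X))
    if (nrow(cases) < n_cases) cases <- rbind(cases, X[y == 1L, , drop = FALSE])
    if (nrow(controls) < n_controls) controls <- rbind(controls, X[y == 0L, , drop = FALSE])
  }
  if (nrow(cases) < n_cases || nrow(controls) < n_controls) {
    abort_orchestration("case/control rejection sampling failed to fill quotas")
  }
  list(genotypes = rbind(cases[seq_len(n_cases), , drop = FALSE],
                         controls[seq_len(n_controls), , drop = FALSE]),
       labels = rep(1:0, c(n_cases, n_controls)))
}

# Generate the penetrance model(s) a configuration requires (NULL for XOR).
config_models <- function(config, seed = NULL) {
  group <- config$group
  if (group == "xor") return(NULL)
  with_seed(seed, {
    n_models <- switch(group,
      core2way = , featurescale = , epi3way = , univariate = 1L,
      hetero2way = , additive2 = 2L,
      additive4 = 4L,
      abort_invalid(sprintf("unknown dataset group '%s'", group)))
    order <- switch(group,
      core2way = , featurescale = , hetero2way = 2L,
      epi3way = 3L,
      univariate = , additive2 = , additive4 = 1L)
    lapply(seq_len(n_models), function(i) {
      make_penetrance_model(order, heritability = config$heritability,
                            mafs = config$mafs %||% 0.2,
                            difficulty = config$difficulty %||% "na")
    })
  })
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || all(is.na(a))) b else a

#' Assemble a dataset for one experiment configuration
#'
#' Dispatches on the configuration's dataset group. Clean XOR configurations
#' delegate to [make_xor_dataset()]. For penetrance-table groups the
#' predictive loci of all models plus independent non-predictive loci (MAFs
#' uniform in (0.05, 0.5)) are sampled under HWE and labels are drawn
#' Bernoulli from the penetrance:
#' \itemize{
#'   \item homogeneous groups (noisy 2-way, feature scaling, 3-way,
#'     univariate): one model governs every instance;
#'   \item heterogeneous groups: instances are split by the subgroup ratio
#'     and each subgroup is labeled by its own model while the other model's
#'     loci are carried as non-predictive for that subgroup;
#'   \item additive groups: per-model penetrance deviations from each model's
#'     prevalence are combined as a weighted sum on the penetrance scale
#'     (weights from the ratio, equal if absent) and clipped to [0, 1].
#' }
#' With `balanced = TRUE` (the default, matching the balanced-class datasets
#' the evaluation assumes) cases and controls are rejection-sampled to equal
#' counts; with `balanced = FALSE` labels are plain Bernoulli draws so the
#' empirical prevalence converges to the model's K. Rows are shuffled.
#'
#' @param config One row of [experiment_grid()] (as list or data.frame row).
#' @param models Optional list of `penetrance_model`s covering the
#'   configuration's predictive loci; generated internally when `NULL`.
#' @param seed Optional integer seed (stored as the dataset's replicate seed).
#' @param balanced Sample equal numbers of cases and controls (default TRUE).
#' @return A `genotype_dataset` with predictive features in the leading
#'   columns, named `M<model>P<locus>`, non-predictive columns named `N<i>`.
#' @examples
#' cfg <- experiment_grid("xor")[1, ]
#' d <- assemble_dataset(cfg, seed = 1)
#' @export
assemble_dataset <- function(config, models = NULL, seed = NULL,
                             balanced = TRUE) {
  config <- as.list(config)
  if (config$group == "xor") {
    return(make_xor_dataset(config$order, config$n_total, config$m,
                            seed = seed, config_id = config$config_id))
  }
  if (is.null(models)) models <- config_models(config, seed = seed)
  k_pred <- sum(vapply(models, function(mo) mo$order, integer(1)))
  if (k_pred != config$n_predictive) {
    abort_invalid("models do not cover the configured predictive loci")
  }
  with_seed(seed, {
    n_noise <- config$n_total - k_pred
    noise_mafs <- stats::runif(n_noise, 0.05, 0.5)
    pred_mafs <- unlist(lapply(models, function(mo) mo$mafs))
    loci <- split(seq_len(k_pred),
                  rep(seq_along(models),
                      vapply(models, function(mo) mo$order, integer(1))))
    m <- config$m
    half <- function(q) c(ceiling(q / 2), floor(q / 2))
    all_mafs <- c(pred_mafs, noise_mafs)
    draw <- function(pf, q_total) {
      if (balanced) {
        q <- half(q_total)
        sample_case_control(all_mafs, pf, q[1L], q[2L])
      } else {
        X <- sample_genotypes(all_mafs, q_total)
        list(genotypes = X, labels = stats::rbinom(q_total, 1L, pf(X)))
      }
    }

    if (config$group == "hetero2way") {
      w <- parse_ratio(config$ratio)
      quota <- round(w * m)
      if (abs(sum(quota) - m) > 0) abort_invalid("subgroup ratio does not divide the instance count")
      parts <- lapply(seq_along(models), function(g) {
        pf <- function(X) penetrance_lookup(models[[g]], X[, loci[[g]], drop = FALSE])
        draw(pf, quota[g])
      })
      X <- do.call(rbind, lapply(parts, `[[`, "genotypes"))
      y <- unlist(lapply(parts, `[[`, "labels"))
    } else {
      pf <- if (length(models) == 1L) {
        function(X) penetrance_lookup(models[[1L]], X[, loci[[1L]], drop = FALSE])
      } else {
        w <- if (is.null(config$ratio) || is.na(config$ratio %||% NA)) {
          rep(1 / length(models), length(models))
        } else parse_ratio(config$ratio)
        Kbar <- sum(w * vapply(models, `[[`, numeric(1), "prevalence"))
        function(X) {
          dev <- Map(function(mo, lc, wt) {
            wt * (penetrance_lookup(mo, X[, lc, drop = FALSE]) - mo$prevalence)
          }, models, loci, w)
          pmin(pmax(Kbar + Reduce(`+`, dev), 0), 1)
        }
      }
      part <- draw(pf, m)
      X <- part$genotypes
      y <- part$labels
    }

    colnames(X) <- c(
      unlist(lapply(seq_along(models), function(g) {
        sprintf("M%dP%d", g - 1L, seq_len(models[[g]]$order) - 1L)
      })),
      if (n_noise > 0L) sprintf("N%d", seq_len(n_noise) - 1L))
    shuf <- sample.int(m)
    new_genotype_dataset(X[shuf, , drop = FALSE], y[shuf],
                         predictive_idx = seq_len(k_pred),
                         config_id = config$config_id, replicate_seed = seed)
  })
}
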