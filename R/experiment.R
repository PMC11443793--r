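# Orchestration of the full benchmark: for every configuration x replicate x
# method, generate the dataset, score it, and record the weakest-link rank.

#' The ten benchmark methods
#'
#' Standard and absolute-value rankings of the four Relief-based scorers
#' (ReliefF at two neighbor settings, MultiSURF, MultiSURF*), plus the two
#' controls, in the fixed reporting order.
#'
#' @param nn The two ReliefF neighbor settings (default 10 and 100).
#' @return A data.frame with columns `method`, `scorer`, `scheme`, `nn`.
#' @export
method_table <- function(nn = c(10L, 100L)) {
  rba <- data.frame(
    scorer = rep(c("relieff", "relieff", "multisurf", "multisurfstar"), 2L),
    nn = rep(c(nn[1L], nn[2L], NA, NA), 2L),
    scheme = rep(c("standard", "absolute"), each = 4L),
    stringsAsFactors = FALSE)
  rba$method <- paste0(
    rep(c(sprintf("ReliefF-%dNN", nn[1L]), sprintf("ReliefF-%dNN", nn[2L]),
          "MultiSURF", "MultiSURF*"), 2L),
    rep(c("", "_ABS"), each = 4L))
  ctl <- data.frame(scorer = c("shuffle", "mutual_information"),
                    nn = NA, scheme = c("standard", "standard"),
                    method = c("Shuffle", "MutualInformation"),
                    stringsAsFactors = FALSE)
  rbind(rba, ctl)[, c("method", "scorer", "scheme", "nn")]
}

#' Run the weakest-link evaluation over an experiment grid
#'
#' For each configuration row, the penetrance model(s) are generated once
#' (seeded from the configuration id), then each replicate dataset is
#' assembled, scored by every scorer a requested method needs (the distance
#' matrix and base scores are shared across methods), and the weakest-link
#' rank of the known predictive features is recorded per method.
#' All randomness derives from `base_seed` via [replicate_seed()], so reruns
#' are byte-identical.
#'
#' @param grid A configuration data.frame from [experiment_grid()].
#' @param methods Method labels to evaluate (default: all ten rows of
#'   [method_table()], in fixed order).
#' @param base_seed Integer base seed for the whole run.
#' @param replicates Override of the grid's per-configuration replicate
#'   counts (`NULL` keeps them).
#' @param nn ReliefF neighbor settings used by the method labels.
#' @param deadband_multiplier Dead-band width for MultiSURF/MultiSURF*.
#' @param ties Tie mode passed to [weakest_link()].
#' @param verbose Print per-configuration progress.
#' @return A data.frame with one row per configuration x replicate x method:
#'   `config_id`, `replicate`, `replicate_seed`, `method`, `scheme`,
#'   `weakest_link`, `n_features`.
#' @examples
#' g <- experiment_grid("xor")[1, ]
#' run_experiment_grid(g, methods = "Shuffle", replicates = 1, base_seed = 1)
#' @export
run_experiment_grid <- function(grid, methods = method_table(nn)$method,
                                base_seed = 42L, replicates = NULL,
                                nn = c(10L, 100L), deadband_multiplier = 0.5,
                                ties = c("index", "pessimistic"),
                                verbose = FALSE) {
  ties <- match.arg(ties)
  mt <- method_table(nn)
  unknown <- setdiff(methods, mt$method)
  if (length(methods) == 0L || length(unknown) > 0L) {
    abort_orchestration(sprintf(
      "no scorer is defined for method(s): %s",
      if (length(unknown)) paste(unknown, collapse = ", ") else "<none requested>"))
  }
  mt <- mt[match(methods, mt$method), , drop = FALSE]  # fixed reporting order
  out <- vector("list", nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    config <- as.list(grid[ci, ])
    reps <- if (is.null(replicates)) config$replicates else replicates
    models <- config_models(config,
                            seed = replicate_seed(config$config_id, 0L, base_seed))
    if (verbose) message(sprintf("[%d/%d] %s (%d replicates)",
                                 ci, nrow(grid), config$config_id, reps))
    rows <- vector("list", reps)
    for (r in seq_len(reps)) {
      seed_r <- replicate_seed(config$config_id, r, base_seed)
      ds <- assemble_dataset(config, models, seed = seed_r)
      need <- unique(mt$scorer[mt$scorer %in% c("relieff", "multisurf", "multisurfstar")])
      dist <- if (length(need)) pairwise_distance(ds$genotypes)
      cache <- new.env(parent = emptyenv())
      get_scores <- function(scorer, k) {
        key <- paste0(scorer, "_", k %||% "")
        if (!is.null(cache[[key]])) return(cache[[key]])
        cache[[key]] <- switch(scorer,
          relieff = relieff_scores(ds, nn = k, dist = dist),
          multisurf = multisurf_scores(ds, deadband_multiplier, dist = dist),
          multisurfstar = multisurfstar_scores(ds, deadband_multiplier, dist = dist),
          mutual_information = mutual_info_scores(ds))
        cache[[key]]
      }
      wl <- vapply(seq_len(nrow(mt)), function(mi) {
        scorer <- mt$scorer[mi]
        if (scorer == "shuffle") {
          sh <- shuffle_ranking(ds, seed = replicate_seed(
            paste0(config$config_id, "/shuffle"), r, base_seed))
          weakest_link_rank(sh$ordering, ds$predictive_idx)
        } else {
          weakest_link(get_scores(scorer, mt$nn[mi]), ds$predictive_idx,
                       scheme = mt$scheme[mi], ties = ties)
        }
      }, numeric(1))
      rows[[r]] <- data.frame(
        config_id = config$config_id, replicate = r, replicate_seed = seed_r,
        method = mt$method, scheme = mt$scheme, weakest_link = as.integer(wl),
        n_features = ncol(ds$genotypes), stringsAsFactors = FALSE)
    }
    out[[ci]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate weakest-link results into power curves
#'
#' @param results Results data.frame from [run_experiment_grid()].
#' @return A named list (one element per `config_id`) of matrices, methods in
#'   rows (run order preserved) and ranking positions in columns, holding
#'   [power_curve()] percentages.
#' @export
power_curves <- function(results) {
  lapply(split(results, factor(results$config_id, unique(results$config_id))),
         function(cfg) {
           n <- unique(cfg$n_features)
           if (length(n) != 1L) abort_shape("inconsistent feature counts within a configuration")
           meths <- unique(cfg$method)
           mat <- t(vapply(meths, function(me) {
             power_curve(cfg$weakest_link[cfg$method == me], n)
           }, numeric(n)))
           rownames(mat) <- meths
           colnames(mat) <- seq_len(n)
           mat
         })
}
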