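# Naive reference implementations, kept deliberately independent of the
# package's vectorized code paths: plain double loops, per-target means.

make_ds <- function(X, y, predictive_idx = 1L, config_id = "test") {
  reliefbench:::new_genotype_dataset(
    {
      if (is.null(colnames(X))) colnames(X) <- paste0("F", seq_len(ncol(X)))
      X
    },
    y, predictive_idx = predictive_idx, config_id = config_id)
}

random_dataset <- function(m, n, seed) {
  set.seed(seed)
  X <- matrix(sample(0:2, m * n, replace = TRUE), m, n)
  y <- c(0L, 0L, 1L, 1L, sample(0:1, m - 4L, replace = TRUE))
  make_ds(X, y)
}

naive_distance <- function(X) {
  m <- nrow(X)
  D <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) D[i, j] <- sum(X[i, ] != X[j, ])
  D
}

# sorted candidate neighbors of t within class `cls`, ties by ascending index
naive_sorted <- function(D, y, t, cls) {
  others <- setdiff(seq_along(y), t)
  cand <- others[y[others] == cls]
  cand[order(D[t, cand], cand)]
}

naive_relieff <- function(X, y, nn) {
  colnames(X) <- NULL
  m <- nrow(X)
  D <- naive_distance(X)
  sc <- numeric(ncol(X))
  for (t in seq_len(m)) {
    hits <- naive_sorted(D, y, t, y[t])
    miss <- naive_sorted(D, y, t, 1L - y[t])
    hits <- hits[seq_len(min(nn, length(hits)))]
    miss <- miss[seq_len(min(nn, length(miss)))]
    for (j in hits) sc <- sc - (X[j, ] != X[t, ])
    for (j in miss) sc <- sc + (X[j, ] != X[t, ])
  }
  sc / (m * nn)
}

naive_surf_partition <- function(D, t, db = 0.5) {
  others <- setdiff(seq_len(nrow(D)), t)
  d <- D[t, others]
  thr <- mean(d)
  dead <- db * sqrt(mean((d - thr)^2))
  list(threshold = thr, deadband = dead,
       near = others[D[t, others] < thr - dead],
       far = others[D[t, others] > thr + dead])
}

naive_surf <- function(X, y, db = 0.5, far_scoring = FALSE) {
  colnames(X) <- NULL
  m <- nrow(X)
  D <- naive_distance(X)
  sc <- numeric(ncol(X))
  side_mean <- function(t, set) {
    if (length(set) == 0L) return(numeric(ncol(X)))
    out <- numeric(ncol(X))
    for (j in set) out <- out + (X[j, ] != X[t, ])
    out / length(set)
  }
  for (t in seq_len(m)) {
    p <- naive_surf_partition(D, t, db)
    nh <- p$near[y[p$near] == y[t]]
    nm <- p$near[y[p$near] != y[t]]
    term <- side_mean(t, nm) - side_mean(t, nh)
    if (far_scoring) {
      fh <- p$far[y[p$far] == y[t]]
      fm <- p$far[y[p$far] != y[t]]
      term <- (term + side_mean(t, fh) - side_mean(t, fm)) / 2
    }
    sc <- sc + term
  }
  sc / m
}

# worst-case weakest link over every ordering consistent with the ranking key
enumerate_worst_weakest_link <- function(key, predictive_idx) {
  n <- length(key)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  worst <- 0L
  for (p in perms(seq_len(n))) {
    if (all(diff(key[p]) <= 0)) {  # valid descending ordering
      worst <- max(worst, max(match(predictive_idx, p)))
    }
  }
  worst
}
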