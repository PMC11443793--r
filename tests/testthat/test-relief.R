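test_that("pairwise distances count genotype mismatches exactly", {
  expect_equal(pairwise_distance(rbind(c(0, 1, 2), c(0, 1, 2)))[1, 2], 0)
  expect_equal(pairwise_distance(rbind(c(0, 1, 2), c(0, 2, 2)))[1, 2], 1)

  d <- random_dataset(10, 6, seed = 42)
  D <- pairwise_distance(d$genotypes)
  expect_equal(D, naive_distance(d$genotypes), tolerance = 0)
  expect_identical(D, t(D))
  expect_true(all(diag(D) == 0))
})

test_that("ReliefF matches the brute-force oracle exactly on random data", {
  for (seed in 1:5) {
    m <- sample(12:30, 1)
    n <- sample(3:8, 1)
    d <- random_dataset(m, n, seed = seed)
    for (nn in c(1L, 3L, 7L)) {
      # clamping (when a class has fewer than nn members) is part of the
      # contract and mirrored by the oracle
      s <- suppressWarnings(relieff_scores(d, nn = nn))
      expect_equal(unname(s$scores), naive_relieff(d$genotypes, d$labels, nn),
                   tolerance = 0)
      expect_true(all(s$scores >= -1 & s$scores <= 1))
    }
  }
})

test_that("ReliefF on an 8-instance toy dataset reproduces the oracle update sequence", {
  X <- rbind(c(0, 0, 1), c(0, 1, 1), c(1, 0, 2), c(1, 1, 0),
             c(2, 0, 1), c(2, 1, 0), c(0, 2, 2), c(1, 2, 1))
  y <- c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L)
  d <- make_ds(X, y)
  s <- relieff_scores(d, nn = 1)
  expect_equal(unname(s$scores), naive_relieff(X, y, 1), tolerance = 0)
})

test_that("ReliefF scores behave at the definitional extremes", {
  set.seed(8)
  y <- rep(0:1, each = 25)[sample(50)]
  X <- cbind(y, matrix(sample(0:2, 50 * 4, TRUE), 50, 4), 1L)
  d <- make_ds(X, y)
  s <- relieff_scores(d, nn = 5)$scores
  expect_equal(unname(which.max(s)), 1L)
  expect_gt(s[1], 0)
  expect_identical(unname(s[6]), 0)  # constant feature

  expect_error(relieff_scores(d, nn = 49), class = "reliefbench_invalid_parameter")
  expect_error(relieff_scores(make_ds(X[1:4, ], c(0L, 1L, 1L, 1L)), nn = 1),
               class = "reliefbench_degenerate_class")
  expect_warning(relieff_scores(make_ds(X[1:8, ], c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L)),
                                nn = 5),
                 "using all available")
})

test_that("MultiSURF partitions match the threshold/dead-band arithmetic", {
  # target distances (1, 1, 5, 5): T = 3, sd = 2, dead-band = 1
  X <- rbind(rep(0L, 6),
             c(1L, 0L, 0L, 0L, 0L, 0L),
             c(0L, 1L, 0L, 0L, 0L, 0L),
             c(2L, 2L, 2L, 2L, 2L, 0L),
             c(0L, 2L, 2L, 2L, 2L, 2L))
  d <- make_ds(X, c(0L, 0L, 1L, 1L, 0L))
  p <- multisurf_partition(d, target = 1)
  expect_equal(p$threshold, 3)
  expect_equal(p$deadband, 1)
  expect_identical(p$near_set, 2:3)
  expect_identical(p$far_set, 4:5)

  # all other instances equidistant: sd = 0, both sets empty
  Xe <- rbind(rep(0L, 4), rep(1L, 4), rep(1L, 4), rep(1L, 4), rep(1L, 4))
  de <- make_ds(Xe, c(0L, 0L, 0L, 1L, 1L))
  pe <- multisurf_partition(de, target = 1)
  expect_identical(pe$deadband, 0)
  expect_length(pe$near_set, 0)
  expect_length(pe$far_set, 0)

  # random-data agreement with the per-instance oracle
  dr <- random_dataset(20, 6, seed = 9)
  D <- naive_distance(dr$genotypes)
  for (t in c(1, 7, 20)) {
    po <- naive_surf_partition(D, t)
    pv <- multisurf_partition(dr, t)
    expect_equal(pv$threshold, po$threshold)
    expect_equal(pv$deadband, po$deadband)
    expect_identical(pv$near_set, po$near)
    expect_identical(pv$far_set, po$far)
  }
})

test_that("MultiSURF and MultiSURF* match their brute-force oracles", {
  for (seed in 1:5) {
    m <- sample(12:30, 1)
    n <- sample(3:8, 1)
    d <- random_dataset(m, n, seed = 100 + seed)
    s1 <- multisurf_scores(d)$scores
    s2 <- multisurfstar_scores(d)$scores
    expect_equal(unname(s1), naive_surf(d$genotypes, d$labels), tolerance = 1e-12)
    expect_equal(unname(s2),
                 naive_surf(d$genotypes, d$labels, far_scoring = TRUE),
                 tolerance = 1e-12)
    expect_true(all(abs(c(s1, s2)) <= 1))
  }
})

test_that("MultiSURF-family scorers handle definitional extremes", {
  set.seed(12)
  y <- rep(0:1, each = 30)[sample(60)]
  X <- cbind(y, matrix(sample(0:2, 60 * 5, TRUE), 60, 5), 2L)
  d <- make_ds(X, y)
  s <- multisurf_scores(d)$scores
  expect_equal(unname(which.max(s)), 1L)
  expect_gt(s[1], 0)
  expect_identical(unname(s[7]), 0)
  expect_identical(unname(multisurfstar_scores(d)$scores[7]), 0)
})

test_that("far scoring degrades univariate detection relative to near-only scoring", {
  cfg <- experiment_grid("univariate")[4, ]  # easy, heritability 0.4
  cfg$n_total <- 20L
  cfg$m <- 400L
  set.seed(77)
  mo <- list(make_penetrance_model(1, 0.4))
  wl_star <- wl_near <- integer(8)
  for (r in 1:8) {
    ds <- assemble_dataset(cfg, mo, seed = 7000 + r)
    dist <- pairwise_distance(ds$genotypes)
    wl_star[r] <- weakest_link(multisurfstar_scores(ds, dist = dist),
                               ds$predictive_idx)
    wl_near[r] <- weakest_link(multisurf_scores(ds, dist = dist),
                               ds$predictive_idx)
  }
  expect_gt(mean(wl_star), mean(wl_near))
  expect_false(all(wl_star == 1L))
})

test_that("scores are equivariant to column permutation and invariant to row order", {
  d <- random_dataset(24, 6, seed = 31)
  perm <- c(4, 1, 6, 2, 5, 3)
  dp <- make_ds(d$genotypes[, perm], d$labels)
  for (fn in list(function(x) relieff_scores(x, 3)$scores,
                  function(x) multisurf_scores(x)$scores,
                  function(x) multisurfstar_scores(x)$scores,
                  function(x) mutual_info_scores(x)$scores)) {
    expect_equal(unname(fn(dp)), unname(fn(d))[perm], tolerance = 1e-12)
  }

  rperm <- sample(24)
  dr <- make_ds(d$genotypes[rperm, ], d$labels[rperm])
  for (fn in list(function(x) multisurf_scores(x)$scores,
                  function(x) multisurfstar_scores(x)$scores,
                  function(x) mutual_info_scores(x)$scores)) {
    expect_equal(unname(fn(dr)), unname(fn(d)), tolerance = 1e-12)
  }
})
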