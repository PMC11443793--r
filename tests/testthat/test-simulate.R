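test_that("HWE genotype sampling matches expected frequencies and rejects bad MAFs", {
  g <- sample_genotypes(0.2, m = 1e5, seed = 11)
  freq <- tabulate(g + 1L, 3L) / 1e5
  expected <- c(0.64, 0.32, 0.04)
  se <- sqrt(expected * (1 - expected) / 1e5)
  expect_true(all(abs(freq - expected) < 3 * se))

  expect_error(sample_genotypes(0, 10), class = "reliefbench_invalid_parameter")
  expect_error(sample_genotypes(0.6, 10), class = "reliefbench_invalid_parameter")
  expect_error(sample_genotypes(c(0.2, -0.1), 10),
               class = "reliefbench_invalid_parameter")
})

test_that("XOR datasets encode parity of heterozygosity with full penetrance", {
  d <- make_xor_dataset(2, n_total = 10, m = 500, seed = 3)
  b <- d$genotypes[, 1:2] == 1L
  expect_identical(d$labels, as.integer(rowSums(b) %% 2))
  expect_identical(d$predictive_idx, 1:2)
  expect_identical(colnames(d$genotypes)[1:3], c("M0P0", "M0P1", "N0"))

  # explicit parity cases: (het, hom) -> class 1; (het, het) -> class 0
  expect_equal(sum(c(1, 0) == 1) %% 2, 1)
  i10 <- which(d$genotypes[, 1] == 1L & d$genotypes[, 2] != 1L)
  i11 <- which(d$genotypes[, 1] == 1L & d$genotypes[, 2] == 1L)
  expect_true(all(d$labels[i10] == 1L))
  expect_true(all(d$labels[i11] == 0L))

  expect_error(make_xor_dataset(1, 10, 50), class = "reliefbench_invalid_parameter")
  expect_error(make_xor_dataset(6, 10, 50), class = "reliefbench_invalid_parameter")
  expect_error(make_xor_dataset(3, 2, 50), class = "reliefbench_invalid_parameter")
})

test_that("XOR class balance stays within binomial bounds across orders", {
  for (k in 2:5) {
    d <- make_xor_dataset(k, 20, 1600, seed = 100 + k)
    expect_lt(abs(mean(d$labels) - 0.5), 3 * sqrt(0.25 / 1600))
  }
})

test_that("XOR penetrance tables are exactly pure, strict and fully penetrant", {
  for (k in 2:5) {
    mo <- xor_penetrance_model(k)
    v <- verify_pure_strict(mo, tol = 0)
    expect_true(v$pure_strict)
    expect_identical(v$max_deviation, 0)
    expect_identical(model_prevalence(mo), 0.5)
    expect_identical(model_heritability(mo), 1)
  }
  # brute-force spot check against an independent marginalization for k = 3:
  mo <- xor_penetrance_model(3)
  G <- as.matrix(expand.grid(0:2, 0:2, 0:2))
  f <- as.numeric(rowSums(G == 1) %% 2 == 1)
  w <- c(0.25, 0.5, 0.25)
  for (g1 in 0:2) for (g2 in 0:2) {
    sel <- G[, 1] == g1 & G[, 2] == g2
    expect_equal(sum(f[sel] * w[G[sel, 3] + 1]), 0.5)
  }
})

test_that("penetrance models recover requested heritability and are pure/strict", {
  cases <- list(c(1, 0.4), c(1, 0.05), c(2, 0.05), c(2, 0.4), c(3, 0.2))
  for (cs in cases) {
    mo <- make_penetrance_model(cs[1], cs[2], seed = 1000 + cs[1] * 10 + cs[2] * 100)
    expect_true(all(mo$table >= 0 & mo$table <= 1))
    expect_lt(abs(model_prevalence(mo) - mo$prevalence), 1e-9)
    expect_lt(abs(model_heritability(mo) - cs[2]), 1e-6)
    if (cs[1] >= 2) {
      v <- verify_pure_strict(mo)
      expect_true(v$pure_strict)
      expect_lt(v$max_deviation, 1e-9)
    }
  }
})

test_that("infeasible heritability requests raise a feasibility error", {
  expect_error(
    make_penetrance_model(3, 0.4, prevalence = 0.5, max_tries = 1000, seed = 1),
    class = "reliefbench_feasibility_error")
  expect_error(
    make_penetrance_model(2, 0.9, mafs = 0.05, prevalence = 0.5,
                          max_tries = 1000, seed = 1),
    class = "reliefbench_feasibility_error")
})

test_that("difficulty deciles order models by detectability", {
  easy <- make_penetrance_model(2, 0.2, difficulty = "easy", pop_size = 30, seed = 5)
  hard <- make_penetrance_model(2, 0.2, difficulty = "hard", pop_size = 30, seed = 5)
  expect_gt(reliefbench:::model_detectability(easy),
            reliefbench:::model_detectability(hard))
})

test_that("pure/strict verification flags additive tables and handles degenerate ones", {
  G <- as.matrix(expand.grid(0:2, 0:2))
  additive <- structure(
    list(order = 2L, table = 0.1 + 0.1 * (G[, 1] + G[, 2]), mafs = c(0.2, 0.2)),
    class = "penetrance_model")
  v <- verify_pure_strict(additive)
  expect_false(v$pure_strict)
  expect_gt(v$max_deviation, 0.1)

  constant <- structure(
    list(order = 2L, table = rep(0.3, 9), mafs = c(0.2, 0.2)),
    class = "penetrance_model")
  expect_true(verify_pure_strict(constant)$pure_strict)

  uni <- structure(list(order = 1L, table = c(0, 0.5, 1), mafs = 0.2),
                   class = "penetrance_model")
  expect_error(verify_pure_strict(uni), class = "reliefbench_invalid_parameter")
})

test_that("heterogeneous assembly builds the stated subgroup structure", {
  cfg <- experiment_grid("hetero2way")[2, ]  # 75:25
  set.seed(99)
  models <- list(make_penetrance_model(2, 0.4), make_penetrance_model(2, 0.4))
  d <- assemble_dataset(cfg, models, seed = 7)
  expect_equal(dim(d), c(1600L, 100L))
  expect_identical(d$predictive_idx, 1:4)
  expect_identical(colnames(d$genotypes)[1:4], c("M0P0", "M0P1", "M1P0", "M1P1"))
  expect_equal(sum(d$labels), 800)  # balanced cases/controls

  expect_error(reliefbench:::parse_ratio("60:30"),
               class = "reliefbench_invalid_parameter")
})

test_that("unbalanced Bernoulli labeling recovers the model prevalence", {
  cfg <- experiment_grid("core2way")[1, ]
  cfg$m <- 10000L
  mo <- make_penetrance_model(2, cfg$heritability, seed = 21)
  d <- assemble_dataset(cfg, list(mo), seed = 22, balanced = FALSE)
  K <- mo$prevalence
  expect_lt(abs(mean(d$labels) - K), 3 * sqrt(K * (1 - K) / 10000))
})

test_that("additive assembly combines single-locus models and clips to [0,1]", {
  cfg <- experiment_grid("additive4")
  d <- assemble_dataset(cfg[1, ], seed = 31)
  expect_equal(dim(d), c(1600L, 100L))
  expect_identical(d$predictive_idx, 1:4)
  expect_equal(sum(d$labels), 800)
})

test_that("dataset files round-trip exactly and invalid files raise format errors", {
  tmp <- withr::local_tempdir()
  for (seed in 1:3) {
    d <- make_xor_dataset(3, 12, 60, seed = seed)
    p <- file.path(tmp, sprintf("ds%d.txt", seed))
    write_dataset(d, p)
    back <- read_dataset(p)
    expect_identical(back$genotypes, d$genotypes)
    expect_identical(back$labels, d$labels)
    expect_identical(back$predictive_idx, d$predictive_idx)
  }

  bad <- file.path(tmp, "bad.txt")
  writeLines(c("M0P0\tN0\tClass", "0\t3\t1", "1\t2\t0"), bad)
  err <- tryCatch(read_dataset(bad), error = identity)
  expect_s3_class(err, "reliefbench_format_error")
  expect_match(conditionMessage(err), "row 1")
  expect_match(conditionMessage(err), "N0")

  noclass <- file.path(tmp, "noclass.txt")
  writeLines(c("M0P0\tN0", "0\t1", "1\t2"), noclass)
  expect_error(read_dataset(noclass), class = "reliefbench_format_error")

  badlab <- file.path(tmp, "badlab.txt")
  writeLines(c("M0P0\tClass", "0\t2", "1\t0", "0\t1", "1\t1"), badlab)
  expect_error(read_dataset(badlab), class = "reliefbench_format_error")
})

test_that("generation is reproducible bit-for-bit from the seed", {
  s <- replicate_seed("xor_k4_n40", 7, 123)
  expect_identical(s, replicate_seed("xor_k4_n40", 7, 123))
  expect_false(s == replicate_seed("xor_k4_n40", 8, 123))
  expect_false(s == replicate_seed("xor_k4_n60", 7, 123))

  d1 <- make_xor_dataset(4, 40, 200, seed = s)
  d2 <- make_xor_dataset(4, 40, 200, seed = s)
  expect_identical(d1$genotypes, d2$genotypes)
  expect_identical(d1$labels, d2$labels)

  cfg <- experiment_grid("epi3way")
  set.seed(4); mo <- list(make_penetrance_model(3, 0.2))
  a1 <- assemble_dataset(cfg[1, ], mo, seed = 55)
  a2 <- assemble_dataset(cfg[1, ], mo, seed = 55)
  expect_identical(a1$genotypes, a2$genotypes)
  expect_identical(a1$labels, a2$labels)
})

test_that("the experiment grid reflects the study design", {
  g <- experiment_grid()
  expect_identical(nrow(experiment_grid("xor")), 20L)
  expect_identical(nrow(experiment_grid("core2way")), 32L)
  expect_identical(nrow(experiment_grid("univariate")), 8L)
  expect_true(all(g$replicates >= 1))
  expect_false(any(duplicated(g$config_id)))
  # 3-way runs at heritability 0.2, the simulator's feasibility ceiling
  expect_equal(g$heritability[g$group == "epi3way"], 0.2)
  # scaled-down default substitutes the 100k-feature configuration
  expect_true(any(grepl("scaled", g$config_id)))
  expect_equal(max(experiment_grid(full_scale = TRUE)$n_total), 100000L)
})
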