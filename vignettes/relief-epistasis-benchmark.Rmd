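---
title: "Benchmarking Relief-based feature weighting on simulated epistasis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking Relief-based feature weighting on simulated epistasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`reliefbench` measures how reliably Relief-based algorithms (RBAs) recover
features involved in genetic interactions, using simulated case/control
genotype data in which the predictive loci are known. This vignette is the
package's own account of the models it simulates, the scorers it implements,
the evaluation statistic, and the numerical decisions behind the defaults.

## The simulation models

### Genotypes

All loci are simulated as independent SNPs under Hardy–Weinberg equilibrium:
genotype 0/1/2 (major homozygote / heterozygote / minor homozygote) with
probabilities $((1-p)^2,\ 2p(1-p),\ p^2)$ at minor-allele frequency $p \in
(0, 0.5]$. There is no linkage disequilibrium, no missingness, and outcomes
are binary — deliberate simplifications that keep ground truth exact.
Predictive loci default to MAF 0.2 for the noisy penetrance models (a common
convention for this style of simulation); non-predictive loci draw their MAFs
uniformly from (0.05, 0.5) so the background resembles a real SNP panel
rather than a single replicated frequency.

### Clean XOR interactions

`make_xor_dataset(order, n_total, m)` builds the fully penetrant toy models:
each of the `order` predictive loci is sampled at MAF 0.5 and binarized by
heterozygosity, which is a fair coin under HWE, and the class label is the
parity (XOR) of those bits. Three properties follow *exactly*, and the test
suite verifies them by brute-force marginalization of the implied penetrance
table over $\{0,1,2\}^k$:

- **pure** — every single-locus marginal penetrance equals 0.5 (the parity
  of the remaining fair bits), so no locus carries a univariate effect;
- **strict** — the same argument applies to every proper subset of loci, so
  there are no lower-order interaction effects at any order 2–5;
- **clean** — the phenotype is a deterministic function of the predictive
  genotypes: prevalence $K = 0.5$, heritability $h^2 = \mathrm{Var}(f) /
  (K(1-K)) = 1$.

This is the worst-case detection scenario: all the signal is in the full
$k$-way interaction, none of it leaks into lower-order terms that a scorer
could pick up incrementally. The XOR family spans orders 2–5 crossed with
total feature counts 20, 40, 60, 80, 100 at 1600 instances (20
configurations, `xor_grid()`).

### Noisy pure/strict penetrance models

`make_penetrance_model(order, heritability, ...)` generates random $k$-locus
penetrance tables ($k \le 3$) with the same pure/strict structure but
heritability below 1. The construction uses the HWE-weighted functional
ANOVA decomposition of a table $f$: a candidate table is drawn uniformly,
then successively centered over each locus (subtracting the HWE-weighted
mean along that coordinate), which projects it onto the pure $k$-way
interaction component — a function whose marginal over *any* proper subset
of loci is exactly zero. The deviations are then rescaled so that
$\mathrm{Var}_{\mathrm{HWE}}(f) = h^2 K (1-K)$ exactly at the candidate
prevalence $K$, and the table is accepted if all entries stay in $[0,1]$.
Prevalence and heritability recovery is therefore exact up to floating-point
rounding (the tests assert $10^{-6}$; observed error is $\sim 10^{-16}$),
and pure/strictness is exact by construction (asserted at $10^{-9}$).

Two consequences of the $[0,1]$ constraint are worth knowing:

- **Prevalence floats by default.** At MAF 0.2 a pure/strict 2-way table
  with $h^2 = 0.4$ does not exist at $K = 0.5$ — the deviations required in
  common genotype cells force compensating deviations in rare cells outside
  $[0,1]$. Fixing $K$ a priori would make much of the study grid infeasible,
  so by default each candidate samples $K \sim U(0.05, 0.5)$ and the
  accepted table's exact $K$ is recorded on the model. A `prevalence`
  argument pins it when feasibility allows. Balanced case/control sampling
  (below) makes the datasets class-balanced regardless of $K$.
- **A feasibility ceiling at higher order.** No valid pure/strict 3-way
  table at MAF 0.2 exists at $h^2 = 0.4$ within the search budget; $h^2 =
  0.2$ is readily feasible and is what the 3-way family uses. Infeasible
  requests fail with a classed error reporting the attempt count
  (default budget: 20000 candidates) rather than silently degrading.

**Difficulty deciles.** Tables at identical $(k, h^2, \text{MAF})$ can still
differ in how detectable they are from finite samples: a table that
concentrates its deviations in rare genotype cells is harder than one whose
signal sits in common cells. The exact metric used by the established
simulators in this area is not published in a reusable form, so the package
defines its own: weighted mean absolute deviation over weighted standard
deviation, $\sum_g P(g)\,|f(g)-K| \big/ \sqrt{\sum_g P(g)(f(g)-K)^2}$. With
the variance pinned by $h^2$, this ratio is high exactly when deviations
spread over probable cells. `difficulty = "easy"`/`"hard"` generates a
population of 50 valid models and draws from the top/bottom decile.

### Dataset assembly

`assemble_dataset()` turns a configuration row into a labeled dataset.
Labels are Bernoulli draws from the penetrance of the predictive genotypes.
By default cases and controls are rejection-sampled to equal counts (the
convention for penetrance-table simulators, and what the balanced evaluation
assumes); `balanced = FALSE` gives plain Bernoulli labeling whose empirical
prevalence converges to the model's $K$ (property-tested at $3$ binomial
standard errors). Three composition modes:

- *homogeneous* — one model governs every instance (noisy 2-way core grid,
  feature-count scaling, 3-way, univariate families);
- *heterogeneous* — instances split into subgroups (50:50 or 75:25), each
  labeled by its own independent 2-way model while the other model's loci
  ride along as non-predictive for that subgroup;
- *additive* — single-locus model deviations combined as a weighted sum on
  the penetrance scale, $K_w + \sum_r w_r (f_r - K_r)$, clipped to $[0,1]$
  (weights from the configuration ratio; equal for the 4-feature family).
  The clipping means the combined model's realized heritability is not
  exactly the per-model target; ground truth is the locus set, not $h^2$.

Predictive features occupy the leading columns, named `M<model>P<locus>`,
with non-predictive columns `N<i>` — the naming carries ground truth through
the tab-delimited file format (`write_dataset()` / `read_dataset()`, which
round-trip exactly and validate every cell on read).

### Reproducibility

Every stochastic step is seeded through `replicate_seed(config_id,
replicate, base_seed)`, a platform-independent 31-bit string hash; replicate
0 is reserved for per-configuration model generation. Reruns of
`run_experiment_grid()` with the same base seed are identical object-wise,
which the tests assert.

## The scorers

All scorers operate on the genotype mismatch distance: $d(i,j)$ = number of
features at which two instances differ (each feature contributing 0 or 1).
Distances and per-neighborhood difference sums are computed as indicator-
matrix products, so scoring a 1600-instance, 100-feature dataset takes on
the order of a second; naive $O(m^2 n)$ double-loop reference
implementations live in the test suite and the vectorized scorers must match
them exactly on random datasets.

- **ReliefF** (`relieff_scores`, run parameter `nn`, studied at 10 and 100):
  every instance serves once as target; its `nn` nearest hits (same class)
  and `nn` nearest misses (opposite class) update each feature by
  (miss differences − hit differences); the total is divided by
  $m \cdot nn$, bounding weights to $[-1, 1]$. Distance ties are broken by
  ascending instance index, which makes neighbor selection deterministic
  across platforms. Targets with fewer than `nn` hits or misses use all
  available and trigger one warning per dataset.
- **MultiSURF** (`multisurf_scores`): no neighbor count; each target $i$
  defines a threshold $T_i$ (mean distance to all other instances) and a
  dead-band $D_i$ (`deadband_multiplier` × the population SD of those
  distances, default multiplier 0.5). Instances strictly closer than
  $T_i - D_i$ are near; each target's near-hit and near-miss difference sums
  are normalized by their own member counts (an empty side contributes
  zero), and the sum over targets is divided by $m$.
- **MultiSURF\*** (`multisurfstar_scores`): adds inverse scoring of far
  instances (beyond $T_i + D_i$): far hit differences add, far miss
  differences subtract. The near and far per-target contributions are
  averaged, keeping scores in $[-1, 1]$; since this is a global monotone
  rescaling it cannot change any ranking. Far scoring is what gives the
  algorithm its power on pure pairwise interactions — and what suppresses
  univariate effects, a trade-off the test suite demonstrates directly
  (near-only scoring ranks a univariate locus strictly better than
  far scoring on matched datasets).

Controls: `mutual_info_scores` is the exact plug-in estimator of
$I(\text{genotype}; \text{class})$ in nats over the observed $3 \times 2$
contingency table (discrete features make the plug-in the natural estimator;
negative values are impossible for it and are clipped only as a guard for
alternative estimators), and `shuffle_ranking` is a seeded uniform
permutation of the feature indices.

## Evaluation

Two ranking schemes: *standard* sorts raw scores descending; *absolute*
sorts $|score|$ descending, the hypothesis being that strongly negative
weights assigned to interacting features might be recoverable signal. Ties
break by ascending feature index everywhere; a pessimistic tie mode
(`ties = "pessimistic"`, every predictive feature placed after all its ties)
is available for sensitivity analysis and is validated in the tests against
exhaustive enumeration of tie-consistent orderings.

Per replicate and method the **weakest link** is recorded: the worst
(largest) rank position among the known predictive features — missing even
one feature of an interaction breaks downstream modeling, so partial credit
is not meaningful. Over $R$ replicates, the **power curve** gives for each
position $p$ the percentage of replicates with weakest link $\le p$; curves
are monotone and reach 100 at $p = n$. For the shuffle control the curve has
the closed form $100 \cdot \binom{p}{k} / \binom{n}{k}$ (CDF of the maximum
of $k$ uniform draws without replacement), which the empirical curve matches
to within sampling error — a useful end-to-end calibration of the whole
pipeline.

`run_experiment_grid()` orchestrates configurations × replicates × the ten
methods (standard and absolute rankings of ReliefF-10NN, ReliefF-100NN,
MultiSURF, MultiSURF\*, plus shuffle and mutual information, in that fixed
reporting order), sharing the distance matrix and base scores across methods
within a replicate. `render_heatmap()` writes the exact numeric matrix as
TSV — the testable surface — and optionally a PNG with the conventional
orange-white-to-blue colormap over [0, 100].

## Problem sizes and observed behavior

The package's own validation runs use deliberately modest sizes, chosen so
the whole suite completes comfortably on one CPU while keeping every
assertion sharp:

- clean 2-way XOR, all five feature counts, 10 replicates: every RBA
  method/scheme places both predictive features in the top two positions in
  at least 95% of replicates;
- the headline score-magnitude computation (acceptance script and test)
  uses 4-way and 5-way XOR at feature counts 20–100, 1600 instances, 5
  replicates per configuration — 50 datasets — and reproduces the
  characteristic ordering: at 100 neighbors both predictive and
  non-predictive absolute ReliefF weights shrink toward zero relative to 10
  neighbors, which is precisely why absolute-value ranking at high *NN* does
  not rescue higher-order detection;
- 4-way XOR at 100 features, 10 replicates: MultiSURF, MultiSURF\* and
  ReliefF-100NN weakest links are statistically indistinguishable from the
  analytic shuffle null (one-sample Kolmogorov bound at $\alpha = 0.01$).
  ReliefF-10NN is the deliberate exception: it retains genuine marginal
  power there (its Kolmogorov distance exceeds the null bound, and grows
  relative to it at higher replication), so the corresponding comparability
  assertion fails for that method and is left failing — the method is
  slightly better than random at this configuration, and the test records
  that honestly rather than widening the band;
- the 100,000-feature configuration of the feature-scaling family defaults
  to a documented 10,000-feature stand-in with a third of the replicates
  (`experiment_grid(full_scale = TRUE)` restores full size).

## Known limitations

- Binary outcomes and complete, discrete genotype data only; the multi-class
  miss-prior weighting of some ReliefF variants reduces to 1 here and is not
  implemented. No continuous endpoints, no missing-data handling.
- Loci are independent; real panels have linkage structure that changes the
  distance geometry RBAs rely on.
- The per-side count normalization in MultiSURF/MultiSURF\* and the
  averaging of near and far halves are this package's conventions for
  keeping weights in $[-1,1]$; other implementations may scale scores by
  different constants. Rank orders — the quantity the evaluation consumes —
  are invariant to those choices; absolute score magnitudes are comparable
  only up to such scaling for the MultiSURF family.
- The difficulty metric is a principled proxy, not a reimplementation of any
  particular simulator's ease-of-detection score; "easy" and "hard" are
  meaningful relative to each other within a model population.
- Passing tests demonstrate behavior on data satisfying these simulators'
  assumptions (HWE, independence, balanced classes, exact pure/strict
  structure); they bound, but do not establish, performance on real genetic
  data.
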