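test_that("fixed distributions return their point estimates deterministically", {
  dists <- fix_distributions(parameter_distributions())
  a <- sample_parameters(dists, seed = 1)
  b <- sample_parameters(dists, seed = 2)
  expect_identical(a, b)
  expect_equal(unname(a["cost_colonoscopy"]), 550)
  expect_equal(unname(a["perforation"]), 6e-4, tolerance = 1e-12)
})

test_that("beta draws have the right mean and draws are reproducible", {
  dists <- tibble::tibble(parameter = "p", family = "beta",
                          shape1 = 3, shape2 = 7)
  draws <- vapply(1:10000, function(i) sample_parameters(dists, seed = i)[["p"]],
                  numeric(1))
  m <- 3 / 10
  se <- sqrt(m * (1 - m) / (3 + 7 + 1) / 10000)  # SD of beta / sqrt(n)
  expect_lt(abs(mean(draws) - m), 3 * sqrt(stats::var(draws) / 10000))
  expect_true(all(draws >= 0 & draws <= 1))
  expect_identical(sample_parameters(parameter_distributions(), seed = 9),
                   sample_parameters(parameter_distributions(), seed = 9))
  bad <- tibble::tibble(parameter = "x", family = "cauchy", shape1 = 1, shape2 = 1)
  expect_error(sample_parameters(bad, seed = 1), "family")
})

test_that("a one-sample all-fixed PSA collapses to the deterministic comparison", {
  inputs <- the_inputs()
  strategies <- list(comp = make_uniform(60), alt = make_uniform(58))
  pc <- population_config(n = 3000, seed = 70)
  psa <- run_psa(fix_distributions(parameter_distributions()), strategies, pc,
                 n_samples = 1, seed = 71, inputs = inputs)
  pop <- generate_population(pc)
  res <- evaluate_strategies(pop, strategies, inputs, seed = child_seed(71, 1))
  expect_equal(psa$samples$cost, vapply(res, function(r) mean(r$cost), numeric(1)),
               ignore_attr = TRUE)
  expect_equal(psa$samples$qaly, vapply(res, function(r) mean(r$qaly), numeric(1)),
               ignore_attr = TRUE)
})

test_that("a strategy identical to the comparator has zero increments in every sample", {
  inputs <- the_inputs()
  strategies <- list(comp = make_uniform(60),
                     clone = make_uniform(60, name = "clone"))
  psa <- run_psa(parameter_distributions(), strategies,
                 population_config(n = 1500, seed = 72),
                 n_samples = 4, seed = 73, inputs = inputs)
  wide <- tidyr::pivot_wider(psa$samples, names_from = "strategy",
                             values_from = c("cost", "qaly"))
  expect_equal(wide$cost_comp, wide$cost_clone)
  expect_equal(wide$qaly_comp, wide$qaly_clone)
})

test_that("the PSA pipeline is reproducible bit for bit", {
  inputs <- the_inputs()
  strategies <- list(comp = make_uniform(60), alt = make_sex_stratified(56, 60))
  pc <- population_config(n = 1000, seed = 74)
  a <- run_psa(parameter_distributions(), strategies, pc, n_samples = 3,
               seed = 75, inputs = inputs)
  b <- run_psa(parameter_distributions(), strategies, pc, n_samples = 3,
               seed = 75, inputs = inputs)
  expect_identical(a$samples, b$samples)
})

test_that("doubling the per-sample size shrinks the increment SE by about 1/sqrt(2)", {
  inputs <- the_inputs()
  strategies <- list(comp = make_uniform(60), alt = make_uniform(58))
  dq_at <- function(n, seed) {
    pop <- generate_population(population_config(n = n, seed = seed))
    res <- evaluate_strategies(pop, strategies, inputs, seed = seed + 1)
    mean(res$alt$qaly) - mean(res$comp$qaly)
  }
  reps <- 8
  d_small <- vapply(1:reps, function(i) dq_at(1500, 100 + i), numeric(1))
  d_big <- vapply(1:reps, function(i) dq_at(3000, 200 + i), numeric(1))
  ratio <- stats::sd(d_big) / stats::sd(d_small)
  # loose band: with 8 replicates the SD ratio is itself noisy
  expect_lt(ratio, 1.25)
  expect_gt(ratio, 0.3)
})

test_that("CEAC probabilities match a brute-force count over stored samples", {
  set.seed(99)
  samples <- tidyr::expand_grid(sample = 1:200, strategy = c("a", "b", "c"))
  samples$cost <- stats::runif(nrow(samples), 0, 100)
  samples$qaly <- stats::runif(nrow(samples), 0, 0.01)
  grid <- c(0, 10000, 20000, 50000)
  got <- ceac(samples, grid)
  for (w in grid) {
    counts <- stats::setNames(numeric(3), c("a", "b", "c"))
    for (s in 1:200) {
      rows <- samples[samples$sample == s, ]
      nmbs <- w * rows$qaly - rows$cost
      winners <- rows$strategy[nmbs == max(nmbs)]
      counts[winners] <- counts[winners] + 1 / length(winners)
    }
    for (k in c("a", "b", "c")) {
      expect_equal(got$probability[got$wtp == w & got$strategy == k],
                   unname(counts[k]) / 200)
    }
  }
  sums <- tapply(got$probability, got$wtp, sum)
  expect_equal(as.numeric(sums), rep(1, length(grid)))
})

test_that("CEAC handles dominance and exact ties", {
  samples <- tidyr::expand_grid(sample = 1:10, strategy = c("win", "lose"))
  samples$cost <- ifelse(samples$strategy == "win", 0, 10)
  samples$qaly <- ifelse(samples$strategy == "win", 0.01, 0)
  got <- ceac(samples, c(0, 20000))
  expect_equal(got$probability[got$strategy == "win"], c(1, 1))

  tied <- tidyr::expand_grid(sample = 1:7, strategy = c("x", "y"))
  tied$cost <- 5
  tied$qaly <- 0.001
  got2 <- ceac(tied, c(0, 20000))
  expect_equal(got2$probability, rep(0.5, 4))
  expect_error(ceac(tied[0, ], c(0)), "no PSA samples")
})

test_that("CEAC limits follow mean cost at wtp 0 and mean QALYs at high wtp", {
  set.seed(7)
  samples <- tidyr::expand_grid(sample = 1:50, strategy = c("cheap", "effective"))
  cheap <- samples$strategy == "cheap"
  samples$cost <- ifelse(cheap, stats::rnorm(50, 10, 1), stats::rnorm(50, 50, 1))
  samples$qaly <- ifelse(cheap, stats::rnorm(50, 0.001, 1e-4), stats::rnorm(50, 0.01, 1e-4))
  got <- ceac(samples, c(0, 1e7))
  expect_equal(got$probability[got$wtp == 0 & got$strategy == "cheap"], 1)
  expect_equal(got$probability[got$wtp == 1e7 & got$strategy == "effective"], 1)
})
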