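test_that("generators are deterministic under a fixed seed", {
  expect_identical(simulate_family_frequencies(-10, 20, N = 1000, seed = 5),
                   simulate_family_frequencies(-10, 20, N = 1000, seed = 5))
  g1 <- simulate_genotypes(0.3, 50, seed = 5)
  g2 <- simulate_genotypes(0.3, 50, seed = 5)
  expect_identical(unclass(g1), unclass(g2))
  p1 <- simulate_pool_panel(0.4, 6, 11, seed = 5)
  expect_identical(unclass(p1), unclass(simulate_pool_panel(0.4, 6, 11, seed = 5)))
  b1 <- simulate_study(simulation_config(seed = 3))
  b2 <- simulate_study(simulation_config(seed = 3))
  expect_identical(b1, b2)
  # generators do not disturb the ambient RNG stream
  set.seed(99); before <- .Random.seed
  invisible(simulate_genotypes(0.3, 10, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("family frequency draws follow the ascertained spectrum", {
  # neutral + ascertainment: uniform over the grid (KS distance < 0.02)
  x <- simulate_family_frequencies(0, 1e4, N = 1000, seed = 8)
  ks <- suppressWarnings(ks.test(x, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
  # stochastic ordering under purifying selection
  x_neg <- simulate_family_frequencies(-50, 2000, N = 1000, seed = 9)
  x_0 <- simulate_family_frequencies(0, 2000, N = 1000, seed = 9)
  expect_lt(mean(x_neg), mean(x_0))
})

test_that("genotype draws are Hardy-Weinberg at the requested frequency", {
  expect_identical(unclass(simulate_genotypes(0, 12))[1:3],
                   list(n_hom_present = 0L, n_het = 0L, n_hom_absent = 12L))
  expect_identical(unclass(simulate_genotypes(1, 12))[1:3],
                   list(n_hom_present = 12L, n_het = 0L, n_hom_absent = 0L))
  g <- simulate_genotypes(0.3, 1e4, seed = 10)
  expect_lt(abs(mle_frequency(g)$p_hat - 0.3), 0.02)
  expect_error(simulate_genotypes(1.4, 5), "\\[0, 1\\]")
})

test_that("pool panel simulation agrees with the analytic class probabilities", {
  expect_equal(simulate_pool_panel(0, 10, 11, seed = 1)$m[1], 10L)
  # empirical class frequencies over 1e5 pools vs pool_class_probs
  M <- simulate_pool_panel(0.2, 1e5, 11, seed = 12)
  emp <- M$m[1:3] / 1e5
  th <- pool_class_probs(0.2, 11)[1, 1:3]
  expect_lt(sum(abs(emp - th)) / 2, 0.01)
  # full degradation to the uninformative class
  M6 <- simulate_pool_panel(0.5, 50, 11, degrade_uninformative = 1, seed = 2)
  expect_equal(M6$m[6], 50L)
  # partial degradation lands in the two partial-information classes
  Mp <- simulate_pool_panel(0.5, 200, 11, degrade_partial = 1, seed = 3)
  expect_equal(sum(Mp$m[4:5]), 200L)
})

test_that("cline simulation is monotone and valid only within the angular range", {
  lat <- c(10, 20, 30, 40)
  s <- simulate_cline(0.2, 0.02, lat, n_strains = 30, seed = 4)
  expect_true(all(diff(s$frequency) > 0))
  s0 <- simulate_cline(0.5, 0, lat, n_strains = 30, seed = 4)
  expect_equal(length(unique(s0$frequency)), 1L)
  expect_error(simulate_cline(0.2, 0.1, lat, 30), "pi/2")
  # logistic alternative for misspecification experiments
  sl <- simulate_cline(-3, 0.1, lat, n_strains = 30, model = "logistic", seed = 4)
  expect_true(all(sl$frequency > 0 & sl$frequency < 1))
})

test_that("a simulated study round-trips through every reader", {
  dir <- tempfile("bundle_")
  bundle <- simulate_study(simulation_config(seed = 7), out_dir = dir)
  ann <- read_te_annotations(file.path(dir, "annotations.tsv"))
  panel <- read_pool_panel(file.path(dir, "pool_panel.tsv"))
  gt <- read_genotype_table(file.path(dir, "genotypes.tsv"))
  pops <- read_population_metadata(file.path(dir, "populations.tsv"))
  expect_equal(sort(ann$te_id), sort(panel$te_id))
  expect_setequal(unique(gt$population_id), pops$id)
  expect_equal(nrow(ann), sum(simulation_config()$families$n_elements))
  # truth-table frequencies match the empirical estimates within
  # binomial error (flat clines: every population shares the frequency)
  truth <- bundle$truth
  for (te in truth$te_id[1:8]) {
    counts <- genotype_counts_from_table(gt, te, pops$id[1])
    p_hat <- mle_frequency(counts)$p_hat
    x <- truth$true_freq[truth$te_id == te]
    expect_lt(abs(p_hat - x), 3 * sqrt(x * (1 - x) / (2 * counts$n_strains)) + 0.02)
  }
  # pool counts sum to the panel size
  expect_true(all(rowSums(panel[paste0("m", 1:6)]) == 6))
})
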