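test_that("mutation-selection-balance spectrum has the analytic limits", {
  # normalisation, across a wide range of Ns including extreme values
  for (Ns in c(-1000, -500, -50, -10, 0, 10, 50, 1000)) {
    g <- msb_distribution(Ns, N = 2000)
    expect_true(all(is.finite(g$probs)))
    expect_true(all(g$probs >= 0))
    expect_equal(sum(g$probs), 1, tolerance = 1e-12)
  }
  # neutral limit: probabilities proportional to 1/x on the grid
  g0 <- msb_distribution(0, N = 500)
  ref <- (1 / g0$x) / sum(1 / g0$x)
  expect_equal(g0$probs, ref, tolerance = 1e-12)
  # continuity at the neutral point
  geps <- msb_distribution(1e-6, N = 500)
  expect_equal(geps$probs, g0$probs, tolerance = 1e-4)
  # purifying selection lowers the mean frequency
  gneg <- msb_distribution(-50, N = 500)
  expect_lt(sum(gneg$x * gneg$probs), sum(g0$x * g0$probs))
  expect_error(msb_distribution(Inf), "finite")
  expect_error(msb_distribution(0, N = 1), "at least 2")
})

test_that("ascertainment reweights by frequency", {
  # neutral spectrum becomes uniform
  g0 <- ascertained_distribution(msb_distribution(0, N = 500))
  expect_equal(g0$probs, rep(1 / length(g0$x), length(g0$x)), tolerance = 1e-12)
  # a (numerical) point mass is unchanged
  g <- msb_distribution(0, N = 50)
  pm <- g; pm$probs <- as.numeric(g$x == 0.5)
  asc <- ascertained_distribution(pm)
  expect_equal(asc$probs, pm$probs, tolerance = 1e-15)
  # size-biasing increases the mean, for any input spectrum
  for (Ns in c(-100, -10, 0, 10)) {
    g <- msb_distribution(Ns, N = 500)
    a <- ascertained_distribution(g)
    expect_gte(sum(a$x * a$probs), sum(g$x * g$probs))
  }
})

test_that("pool classification probabilities are exact and match simulation", {
  # no errors, one strain (2 genomes) at x = 0.5: HW proportions
  p <- pool_class_probs(0.5, k = 1, err = error_rates(0, 0))
  expect_equal(unname(p[1, 1:3]), c(0.25, 0.5, 0.25))
  # degenerate frequencies
  expect_equal(unname(pool_class_probs(0, k = 11)[1, "absent"]), 1)
  expect_equal(unname(pool_class_probs(1, k = 11)[1, "fixed"]), 1)
  # primary classes always sum to one; partial classes are their sums
  xs <- seq(0.01, 0.99, by = 0.07)
  P <- pool_class_probs(xs, k = 11)
  expect_equal(unname(rowSums(P[, 1:3])), rep(1, length(xs)), tolerance = 1e-12)
  expect_equal(P[, "absent_or_poly"], P[, "absent"] + P[, "polymorphic"])
  expect_equal(P[, "poly_or_fixed"], P[, "polymorphic"] + P[, "fixed"])

  # against a 1e5-replicate Monte-Carlo simulation at x = 0.2, k = 11
  mc <- oracle_pool_class_mc(0.2, 11, 0.042, 0.010, n_rep = 1e5, seed = 7)
  th <- pool_class_probs(0.2, k = 11)[1, 1:3]
  expect_lt(sum(abs(mc - th)) / 2, 0.01)  # total variation
})

test_that("element observation probability equals the brute-force oracle at N = 50", {
  set.seed(404)
  err <- error_rates()
  grid <- ascertained_distribution(msb_distribution(-8, N = 50))
  for (i in 1:20) {
    m <- as.integer(rmultinom(1, 6, c(0.3, 0.3, 0.1, 0.1, 0.1, 0.1)))
    M <- pool_observation(m[1], m[2], m[3], m[4], m[5], m[6])
    got <- element_obs_prob(M, grid, err)
    want <- oracle_element_obs_prob(m, 11, grid$x, grid$probs, err$e1, err$e2)
    expect_equal(got, want, tolerance = 1e-8)
    expect_gte(got, 0); expect_lte(got, 1)
  }
  # no information: probability one
  expect_equal(element_obs_prob(pool_observation(m6 = 6), grid, err), 1)
  # single absent pool on a point mass, no errors: (1-x)^(2k)
  pm <- grid; pm$probs <- as.numeric(grid$x == 0.5)
  got <- element_obs_prob(pool_observation(m1 = 1, k_strains_per_pool = 3),
                          pm, error_rates(0, 0))
  expect_equal(got, 0.5^6, tolerance = 1e-12)
})

test_that("family log-likelihood is additive and continuous in Ns", {
  set.seed(505)
  err <- error_rates()
  make_els <- function(n, Ns) {
    xs <- simulate_family_frequencies(Ns, n, N = 400)
    lapply(xs, function(x) simulate_pool_panel(x, 6, 11, err))
  }
  A <- make_els(4, -5); B <- make_els(3, -5)
  llA <- family_loglik(-5, A, N = 400, err = err)
  llB <- family_loglik(-5, B, N = 400, err = err)
  llAB <- family_loglik(-5, c(A, B), N = 400, err = err)
  expect_equal(llAB, llA + llB, tolerance = 1e-10)
  # all-uninformative element contributes zero log-likelihood
  expect_equal(family_loglik(-5, list(pool_observation(m6 = 6)), N = 400), 0)
  # continuity
  for (Ns in c(-100, -10, 0.5)) {
    d <- abs(family_loglik(Ns, A, N = 400, err = err) -
               family_loglik(Ns + 1e-3, A, N = 400, err = err))
    expect_lt(d, 0.05)
  }
})

test_that("the true Ns beats distant values in likelihood (median over families)", {
  set.seed(606)
  err <- error_rates()
  diffs_lo <- diffs_hi <- numeric(20)
  for (r in 1:20) {
    xs <- simulate_family_frequencies(-10, 20, N = 1000)
    els <- lapply(xs, function(x) simulate_pool_panel(x, 6, 11, err))
    ll <- function(v) family_loglik(v, els, N = 1000, err = err)
    diffs_lo[r] <- ll(-10) - ll(-30)
    diffs_hi[r] <- ll(-10) - ll(10)
  }
  expect_gt(median(diffs_lo), 0)
  expect_gt(median(diffs_hi), 0)
})

test_that("fit_family recovers selection and flags degenerate cases", {
  set.seed(707)
  err <- error_rates()
  # deleterious family: point estimate near truth, CI excludes 0
  xs <- simulate_family_frequencies(-10, 30, N = 10000, seed = 11)
  els <- lapply(xs, function(x) simulate_pool_panel(x, 6, 11, err))
  est <- fit_family(els, err = err, seed = 1)
  expect_lte(est$ci_low, est$Ns_hat)
  expect_gte(est$ci_high, est$Ns_hat)
  expect_equal(est$classification, "putatively_adaptive_family")
  # the reported optimum is seed-insensitive (deterministic refinement)
  est2 <- fit_family(els, err = err, seed = 2026)
  expect_equal(est$Ns_hat, est2$Ns_hat, tolerance = 1e-3)
  # the published-convention CI drop (2.512) is wider than the chi-square one
  est_narrow <- fit_family(els, err = err, seed = 1, ci_const = qchisq(0.95, 1) / 2)
  expect_lte(est$ci_low, est_narrow$ci_low)
  expect_gte(est$ci_high, est_narrow$ci_high)

  # neutral family with a fixed seed: CI contains 0
  xs0 <- simulate_family_frequencies(0, 30, N = 10000, seed = 12)
  els0 <- lapply(xs0, function(x) simulate_pool_panel(x, 6, 11, err))
  est0 <- fit_family(els0, err = err, seed = 1)
  expect_lte(est0$ci_low, 0)
  expect_gte(est0$ci_high, 0)
  expect_equal(est0$classification, "putatively_neutral")

  # uninformative two-element family: flat likelihood, indeterminate
  flat <- fit_family(list(pool_observation(m6 = 6), pool_observation(m6 = 6)),
                     N = 400, err = err)
  expect_equal(flat$classification, "indeterminate")
  # small family: estimable but classified indeterminate
  small <- fit_family(els[1:2], err = err, seed = 1, min_family_size = 3)
  expect_equal(small$classification, "indeterminate")
})

test_that("fit_all_families groups a panel by family", {
  set.seed(808)
  panel <- rbind(
    data.frame(te_id = paste0("a", 1:4), family = "A",
               m1 = c(0, 1, 0, 0), m2 = c(6, 5, 5, 6), m3 = c(0, 0, 1, 0),
               m4 = 0, m5 = 0, m6 = 0),
    data.frame(te_id = paste0("b", 1:3), family = "B",
               m1 = 0, m2 = c(1, 0, 2), m3 = c(5, 6, 4), m4 = 0, m5 = 0, m6 = 0))
  est <- fit_all_families(panel, N = 1000, seed = 1)
  expect_equal(sort(est$family), c("A", "B"))
  expect_equal(est$n_elements[order(est$family)], c(4L, 3L))
  expect_true(all(est$ci_low <= est$ci_high))
})
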