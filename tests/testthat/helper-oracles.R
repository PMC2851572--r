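# Independent oracle implementations used to cross-check the package.
# These deliberately use naive loops / direct formulas rather than the
# package's vectorised log-space code paths.

# direct three-term evaluation of the HWE genotype log-likelihood
oracle_loglik <- function(n1, n2, n3, p) {
  tm <- function(n, pr) if (n == 0) 0 else n * log(pr)
  tm(n1, p^2) + tm(n2, 2 * p * (1 - p)) + tm(n3, (1 - p)^2)
}

# likelihood-ratio G statistic of a 2x2 allele-count table
oracle_g2x2 <- function(k_a, n2_a, k_b, n2_b) {
  obs <- matrix(c(k_a, n2_a - k_a, k_b, n2_b - k_b), nrow = 2, byrow = TRUE)
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  keep <- obs > 0
  2 * sum(obs[keep] * log(obs[keep] / expd[keep]))
}

# brute-force observation probability for one element: explicit double
# loop over grid frequencies and pool classes, multinomial coefficient
# (over the perfectly classified pools) from factorials
oracle_element_obs_prob <- function(m, k, grid_x, grid_probs, e1, e2) {
  coef <- factorial(sum(m[1:3])) / prod(factorial(m[1:3]))
  total <- 0
  for (i in seq_along(grid_x)) {
    x <- grid_x[i]
    p_abs0 <- (1 - x)^(2 * k); p_fix0 <- x^(2 * k)
    p_poly0 <- 1 - p_abs0 - p_fix0
    p <- c(p_abs0 + e1 * p_poly0,
           (1 - e1 - e2) * p_poly0,
           p_fix0 + e2 * p_poly0)
    p <- c(p, p[1] + p[2], p[2] + p[3])
    prod_p <- 1
    for (j in 1:5) prod_p <- prod_p * p[j]^m[j]
    total <- total + grid_probs[i] * coef * prod_p
  }
  total
}

# Monte-Carlo pool classification frequencies: draw 2k genomes per pool,
# classify, apply misclassification
oracle_pool_class_mc <- function(x, k, e1, e2, n_rep, seed) {
  set.seed(seed)
  copies <- rbinom(n_rep, 2 * k, x)
  cls <- ifelse(copies == 0, "absent",
                ifelse(copies == 2 * k, "fixed", "polymorphic"))
  u <- runif(n_rep)
  poly <- cls == "polymorphic"
  cls[poly & u < e1] <- "absent"
  cls[poly & u >= e1 & u < e1 + e2] <- "fixed"
  c(absent = mean(cls == "absent"),
    polymorphic = mean(cls == "polymorphic"),
    fixed = mean(cls == "fixed"))
}

# brute-force BH step-up: try every threshold rank explicitly
oracle_bh_stepup <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  istar <- 0
  for (i in seq_len(m)) if (p[ord[i]] <= i * alpha / m) istar <- i
  flags <- logical(m)
  if (istar > 0) flags[ord[seq_len(istar)]] <- TRUE
  flags
}

# random genotype counts generator for property tests
random_counts <- function() {
  n <- sample(2:40, 1)
  draw <- as.integer(rmultinom(1, n, runif(3)))
  genotype_counts(draw[1], draw[2], draw[3])
}
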