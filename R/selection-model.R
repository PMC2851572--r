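#' Mutation-selection-balance model for TE family frequencies
#'
#' A TE insertion is modelled as a codominant variant: individuals
#' homozygous for the insertion have fitness 1 + s and heterozygotes
#' 1 + s/2.  In a panmictic diploid population of constant size N the
#' stationary site-frequency distribution on the grid of possible
#' population frequencies x in {1/(2N), ..., (2N-1)/(2N)} is
#'
#'   rho(x | s, N) = c * (1 - exp(-2Ns(1-x))) / (x (1-x))
#'
#' (Wright-Fisher diffusion spectrum under recurrent input of new
#' insertions; for s -> 0 this reduces to the neutral 1/x spectrum), with
#' c the normalising constant making the grid probabilities sum to one.
#' Because the distribution depends on s and N essentially through the
#' product Ns, all fitting is parameterised in Ns with N held fixed.
#'
#' @name msb-model
NULL

# log |expm1(z)|, stable for |z| large and tiny
.log_abs_expm1 <- function(z) {
  out <- numeric(length(z))
  pos <- z > 0
  out[pos] <- z[pos] + log1p(-exp(-z[pos]))
  out[!pos] <- log(-expm1(z[!pos]))
  out
}

.new_grid <- function(N, x, probs) {
  structure(list(N = as.integer(N), x = x, probs = probs),
            class = "frequency_grid")
}

.check_grid <- function(grid) {
  stopifnot(inherits(grid, "frequency_grid"))
  if (any(grid$probs < 0) || abs(sum(grid$probs) - 1) > 1e-12)
    stop("frequency grid probabilities must be non-negative and sum to 1")
  invisible(grid)
}

#' Stationary frequency distribution of a TE family under selection
#'
#' Evaluates the mutation-selection-balance spectrum (see [msb-model]) on
#' the discrete grid `{1/(2N), ..., (2N-1)/(2N)}`.  Evaluation is done in
#' log space so that strongly selected families (`|Ns|` up to 1e3) do not
#' overflow or underflow.
#'
#' @param Ns Product of population size and selection coefficient
#'   (negative for deleterious families).
#' @param N Diploid population size defining the grid (default 1e4, giving
#'   19,999 grid points).
#'
#' @return A `"frequency_grid"` object: list with `N`, `x` (frequencies)
#'   and `probs` (normalised probabilities).
#' @export
msb_distribution <- function(Ns, N = 10000L) {
  if (!is.finite(Ns)) stop("Ns must be finite")
  if (N < 2) stop("N must be at least 2")
  x <- seq_len(2 * N - 1) / (2 * N)
  gamma <- 2 * Ns
  lw <- if (abs(gamma) < 1e-9) log1p(-x) else .log_abs_expm1(-gamma * (1 - x))
  lw <- lw - log(x) - log1p(-x)
  w <- exp(lw - max(lw))
  .new_grid(N, x, w / sum(w))
}

#' Ascertainment correction for discovery in a single sequenced strain
#'
#' TEs in the analysed set were discovered in one sequenced genome, so the
#' probability of a family member being in the data set at all scales with
#' its population frequency x.  This size-biases the frequency spectrum:
#' probabilities are reweighted by x and renormalised.  For the neutral
#' spectrum (proportional to 1/x) the result is uniform over the grid.
#'
#' @param grid A `"frequency_grid"` (typically from [msb_distribution()]).
#' @return A `"frequency_grid"` with the reweighted probabilities.
#' @export
ascertained_distribution <- function(grid) {
  .check_grid(grid)
  w <- grid$probs * grid$x
  .new_grid(grid$N, grid$x, w / sum(w))
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf("frequency grid: N = %d (%d points), mean frequency %.4g\n",
              x$N, length(x$x), sum(x$x * x$probs)))
  invisible(x)
}

#' Pooled-PCR misclassification rates
#'
#' A truly polymorphic pool can be misread as absent (rate `e1`) or as
#' fixed (rate `e2`).  Defaults are the rates estimated for the pooled
#' panel that this model was developed for (0.042 and 0.010 at 11 strains
#' per pool).
#'
#' @param e1 Probability a truly polymorphic pool is scored absent.
#' @param e2 Probability a truly polymorphic pool is scored fixed.
#' @return An `"error_rates"` list.
#' @export
error_rates <- function(e1 = 0.042, e2 = 0.010) {
  if (e1 < 0 || e2 < 0 || e1 + e2 >= 1)
    stop("error rates must satisfy e1, e2 >= 0 and e1 + e2 < 1")
  structure(list(e1 = e1, e2 = e2), class = "error_rates")
}

#' Pool classification counts for one TE
#'
#' Observed pooled-PCR panel data for a single element: the numbers of
#' pools scored absent (`m1`), polymorphic (`m2`), fixed (`m3`),
#' absent-or-polymorphic (`m4`), polymorphic-or-fixed (`m5`), and pools
#' with no usable assay (`m6`, which carry no information and contribute a
#' likelihood factor of one).
#'
#' @param m1,m2,m3,m4,m5,m6 Non-negative pool counts.
#' @param k_strains_per_pool Strains per pool (default 11; each strain
#'   contributes two haploid genomes).
#' @return A `"pool_observation"` list.
#' @export
pool_observation <- function(m1 = 0, m2 = 0, m3 = 0, m4 = 0, m5 = 0, m6 = 0,
                             k_strains_per_pool = 11L) {
  m <- c(m1, m2, m3, m4, m5, m6)
  if (any(m < 0) || any(m != round(m))) stop("pool counts must be non-negative integers")
  if (k_strains_per_pool < 1) stop("k_strains_per_pool must be >= 1")
  structure(list(m = as.integer(m), k = as.integer(k_strains_per_pool)),
            class = "pool_observation")
}

#' @export
print.pool_observation <- function(x, ...) {
  cat(sprintf(
    "pool observation (k = %d strains/pool): absent %d, poly %d, fixed %d, abs|poly %d, poly|fix %d, no-data %d\n",
    x$k, x$m[1], x$m[2], x$m[3], x$m[4], x$m[5], x$m[6]))
  invisible(x)
}

#' Pool classification probabilities at a given population frequency
#'
#' A pool of `k` strains contains `2k` haploid genomes drawn from the
#' population.  Before misclassification, the pool is absent with
#' probability `(1-x)^(2k)`, fixed with probability `x^(2k)` and
#' polymorphic otherwise.  Misclassification moves a fraction `e1` of
#' truly polymorphic pools into the absent class and `e2` into the fixed
#' class.  The two partial-information classes are the sums of their
#' components.
#'
#' @param x Population frequency (vectorised; values 0 and 1 give the
#'   degenerate all-absent / all-fixed distributions).
#' @param k Strains per pool.
#' @param err An [error_rates()] object.
#'
#' @return A matrix with one row per `x` and columns `absent`,
#'   `polymorphic`, `fixed`, `absent_or_poly`, `poly_or_fixed`.  The first
#'   three columns sum to one.
#' @export
pool_class_probs <- function(x, k = 11L, err = error_rates()) {
  stopifnot(inherits(err, "error_rates"))
  if (any(x < 0 | x > 1)) stop("frequencies must lie in [0, 1]")
  if (k < 1) stop("k must be >= 1")
  p_abs0 <- (1 - x)^(2 * k)
  p_fix0 <- x^(2 * k)
  p_poly0 <- pmax(1 - p_abs0 - p_fix0, 0)
  absent <- p_abs0 + err$e1 * p_poly0
  fixed <- p_fix0 + err$e2 * p_poly0
  poly <- (1 - err$e1 - err$e2) * p_poly0
  cbind(absent = absent, polymorphic = poly, fixed = fixed,
        absent_or_poly = absent + poly, poly_or_fixed = poly + fixed)
}

# log multinomial coefficient over the perfectly classified pools
# m1..m3.  The partial-information classes m4/m5 overlap the primary
# classes, so they enter the likelihood as plain powers; giving them a
# share of the coefficient would double-count arrangements and can push
# the "probability" above one.
.log_multinom_coef <- function(m) {
  lgamma(sum(m[1:3]) + 1) - sum(lgamma(m[1:3] + 1))
}

# per-grid-point log observation factor sum_j m_j log P_j(x) (without the
# multinomial coefficient); returns a vector over grid$x
.log_obs_factor <- function(M, x, err) {
  lp <- log(pool_class_probs(x, M$k, err))
  v <- numeric(length(x))
  for (j in 1:5) if (M$m[j] > 0) v <- v + M$m[j] * lp[, j]
  v
}

.log_sum_exp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(v - m)))
}

#' Probability of a pool-panel observation for one element
#'
#' Integrates the multinomial probability of the observed pool
#' classifications over the (ascertained) population-frequency
#' distribution of the element's family.  Uninformative pools (`m6`)
#' contribute a factor of one.  A return value of zero for an impossible
#' observation (e.g. fixed pools under a distribution with all mass near
#' zero) is valid.
#'
#' @param M A [pool_observation()].
#' @param grid An ascertained `"frequency_grid"` for the family.
#' @param err An [error_rates()] object.
#' @return The observation probability, in `[0, 1]`.
#' @export
element_obs_prob <- function(M, grid, err = error_rates()) {
  stopifnot(inherits(M, "pool_observation"))
  .check_grid(grid)
  lw <- log(grid$probs) + .log_obs_factor(M, grid$x, err)
  exp(.log_multinom_coef(M$m) + .log_sum_exp(lw))
}

# Precompute, for a family, the matrix of per-x log observation factors
# (n_grid x n_elements) plus the constant multinomial coefficients.  The
# factors depend on x, k and the error rates but not on Ns, so they are
# shared across all likelihood evaluations during a fit.
.family_loglik_fun <- function(elements, N, err) {
  x <- seq_len(2 * N - 1) / (2 * N)
  C <- vapply(elements, function(M) .log_obs_factor(M, x, err), numeric(length(x)))
  const <- sum(vapply(elements, function(M) .log_multinom_coef(M$m), numeric(1)))
  function(Ns) {
    grid <- ascertained_distribution(msb_distribution(Ns, N))
    lw <- log(grid$probs)
    ll <- const
    for (e in seq_len(ncol(C))) {
      ll <- ll + .log_sum_exp(lw + C[, e])
      if (!is.finite(ll)) return(-Inf)
    }
    ll
  }
}

#' Log-likelihood of a family's pooled observations at a given Ns
#'
#' The family likelihood is the product over its elements of the
#' per-element observation probabilities ([element_obs_prob()]), i.e. the
#' elements are assumed independent.  The ascertained frequency grid is
#' built once per `Ns` evaluation.
#'
#' @param Ns Scaled selection coefficient.
#' @param elements List of [pool_observation()] objects, one per element.
#' @param N Diploid population size (default 1e4).
#' @param err An [error_rates()] object.
#' @return The log-likelihood (`-Inf` if any element has probability 0).
#' @export
family_loglik <- function(Ns, elements, N = 10000L, err = error_rates()) {
  if (length(elements) < 1) stop("a family needs at least one element")
  .family_loglik_fun(elements, N, err)(Ns)
}

#' Fit the selection coefficient of a TE family
#'
#' Maximises the family log-likelihood over `Ns` in `search_range` by
#' simulated annealing (geometric cooling, Gaussian proposals) followed by
#' a deterministic golden-section refinement around the annealing optimum,
#' which makes the reported estimate insensitive to the annealing seed.
#' Confidence bounds solve `log L(Ns_hat) - log L(Ns) = ci_const` on each
#' side of the maximum; bounds that hit the search range are clipped and
#' flagged.  The default drop `ci_const = 2.512` follows the convention
#' this model was published with; `ci_const = qchisq(0.95, 1)/2 = 1.921`
#' gives the textbook 95% profile-likelihood interval.
#'
#' Classification: `putatively_neutral` when the interval contains 0,
#' `putatively_adaptive_family` when `ci_high < 0` (the family is under
#' significant purifying selection, so its high-frequency members are
#' candidate adaptive insertions), and `indeterminate` when the likelihood
#' is flat over the search range or the family has fewer than
#' `min_family_size` elements.
#'
#' @param elements List of [pool_observation()] objects.
#' @param N Diploid population size (default 1e4).
#' @param err An [error_rates()] object.
#' @param search_range Interval of `Ns` values searched (default
#'   `c(-500, 50)`).
#' @param seed Seed for the annealing stage (default 1); the refinement
#'   makes the final estimate seed-insensitive.
#' @param ci_const Log-likelihood drop defining the confidence bounds.
#' @param min_family_size Families smaller than this are reported but
#'   classified `indeterminate`.
#' @param family Optional family name carried through to the result.
#' @param anneal_steps Number of annealing evaluations (default 400).
#' @param flat_tol Log-likelihood range below which the profile is deemed
#'   flat (default 1e-6).
#'
#' @return A `"selection_estimate"`: list with `family`, `Ns_hat`,
#'   `ci_low`, `ci_high`, `max_loglik`, `n_elements`, `classification`,
#'   and `ci_clipped` (logical length-2: lower/upper bound hit the range).
#' @export
fit_family <- function(elements, N = 10000L, err = error_rates(),
                       search_range = c(-500, 50), seed = 1L,
                       ci_const = 2.512, min_family_size = 3L,
                       family = NA_character_, anneal_steps = 400L,
                       flat_tol = 1e-6) {
  if (length(elements) < 1) stop("a family needs at least one element")
  stopifnot(length(search_range) == 2, search_range[1] < search_range[2])
  ll <- .family_loglik_fun(elements, N, err)
  lo <- search_range[1]; hi <- search_range[2]

  # coarse deterministic scan: flatness check + annealing start
  scan <- seq(lo, hi, length.out = 21)
  scan_ll <- vapply(scan, ll, numeric(1))
  flat <- all(!is.finite(scan_ll)) ||
    (diff(range(scan_ll[is.finite(scan_ll)])) < flat_tol)

  if (flat) {
    cur <- scan[which.max(scan_ll)]
    best <- cur; best_ll <- max(scan_ll)
  } else {
    # simulated annealing with geometric cooling
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    cur <- scan[which.max(scan_ll)]
    cur_ll <- max(scan_ll)
    best <- cur; best_ll <- cur_ll
    temp0 <- 5; temp_end <- 1e-3
    cool <- (temp_end / temp0)^(1 / max(anneal_steps - 1, 1))
    width <- (hi - lo) / 4
    temp <- temp0
    for (i in seq_len(anneal_steps)) {
      prop <- cur + stats::rnorm(1, 0, width * max(temp / temp0, 0.02))
      if (prop >= lo && prop <= hi) {
        prop_ll <- ll(prop)
        if (is.finite(prop_ll) &&
            (prop_ll > cur_ll || stats::runif(1) < exp((prop_ll - cur_ll) / temp))) {
          cur <- prop; cur_ll <- prop_ll
          if (cur_ll > best_ll) { best <- cur; best_ll <- cur_ll }
        }
      }
      temp <- temp * cool
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    # deterministic refinement in a bracket around the annealing optimum
    half <- (hi - lo) / 10
    opt <- stats::optimize(ll, lower = max(lo, best - half),
                           upper = min(hi, best + half), maximum = TRUE,
                           tol = 1e-5)
    if (opt$objective > best_ll) { best <- opt$maximum; best_ll <- opt$objective }
  }

  if (flat || !is.finite(best_ll)) {
    est <- structure(
      list(family = family, Ns_hat = NA_real_, ci_low = lo, ci_high = hi,
           max_loglik = if (is.finite(best_ll)) best_ll else NA_real_,
           n_elements = length(elements), classification = "indeterminate",
           ci_clipped = c(lower = TRUE, upper = TRUE)),
      class = "selection_estimate")
    return(est)
  }

  drop_fun <- function(v) ll(v) - (best_ll - ci_const)
  ci <- c(lo, hi); clipped <- c(lower = TRUE, upper = TRUE)
  if (best > lo && drop_fun(lo) < 0) {
    ci[1] <- stats::uniroot(drop_fun, c(lo, best), tol = 1e-4)$root
    clipped["lower"] <- FALSE
  }
  if (best < hi && drop_fun(hi) < 0) {
    ci[2] <- stats::uniroot(drop_fun, c(best, hi), tol = 1e-4)$root
    clipped["upper"] <- FALSE
  }

  classification <- if (length(elements) < min_family_size) {
    "indeterminate"
  } else if (ci[1] <= 0 && ci[2] >= 0) {
    "putatively_neutral"
  } else if (ci[2] < 0) {
    "putatively_adaptive_family"
  } else {
    # interval entirely above zero: no evidence of purifying selection
    "putatively_neutral"
  }

  structure(
    list(family = family, Ns_hat = best, ci_low = ci[1], ci_high = ci[2],
         max_loglik = best_ll, n_elements = length(elements),
         classification = classification, ci_clipped = clipped),
    class = "selection_estimate")
}

#' @export
print.selection_estimate <- function(x, ...) {
  cat(sprintf(
    "selection estimate%s: Ns = %s [%.2f, %.2f], n = %d elements, %s\n",
    if (is.na(x$family)) "" else paste0(" (", x$family, ")"),
    if (is.na(x$Ns_hat)) "NA" else sprintf("%.2f", x$Ns_hat),
    x$ci_low, x$ci_high, x$n_elements, x$classification))
  invisible(x)
}

#' Fit selection coefficients for every family in a pool panel
#'
#' Groups a pool-panel table by family and runs [fit_family()] on each.
#'
#' @param panel A data frame with columns `te_id`, `family`, `m1`..`m6`
#'   (see [read_pool_panel()]).
#' @param k_strains_per_pool Strains per pool.
#' @param ... Passed on to [fit_family()].
#' @return A data frame with one row per family: `family`, `n_elements`,
#'   `Ns_hat`, `ci_low`, `ci_high`, `max_loglik`, `classification`.
#' @export
fit_all_families <- function(panel, k_strains_per_pool = 11L, ...) {
  stopifnot(all(c("family", paste0("m", 1:6)) %in% names(panel)))
  fams <- split(panel, panel$family)
  rows <- lapply(names(fams), function(f) {
    els <- lapply(seq_len(nrow(fams[[f]])), function(i) {
      r <- fams[[f]][i, ]
      pool_observation(r$m1, r$m2, r$m3, r$m4, r$m5, r$m6,
                       k_strains_per_pool = k_strains_per_pool)
    })
    est <- fit_family(els, family = f, ...)
    data.frame(family = f, n_elements = est$n_elements, Ns_hat = est$Ns_hat,
               ci_low = est$ci_low, ci_high = est$ci_high,
               max_loglik = est$max_loglik,
               classification = est$classification,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
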