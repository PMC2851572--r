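#' Synthetic data with the statistical structure the pipeline assumes
#'
#' Generators for every input the analysis consumes: family frequency
#' spectra drawn from the ascertained mutation-selection-balance
#' distribution, Hardy-Weinberg strain genotypes at a given insertion
#' frequency, pooled-PCR panels with misclassification, and latitudinal
#' clines linear on the angular-transformed frequency scale.  Frequencies
#' are drawn from the stationary distribution, not evolved forward in
#' time.  All generators are deterministic given their seed.
#'
#' @name synthetic-data
NULL

# derive a per-stage sub-seed from a bundle seed (kept < 2^31)
.sub_seed <- function(seed, stage) {
  (as.integer(seed) + 97L * as.integer(stage)) %% 2147483587L
}

.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else rm(".Random.seed", envir = globalenv()))
  }
  force(code)
}

#' Draw element frequencies for a family under selection and ascertainment
#'
#' Samples population frequencies from
#' `ascertained_distribution(msb_distribution(Ns, N))`, the distribution
#' of frequencies at which family members discovered in a single
#' sequenced strain segregate.
#'
#' @param Ns Scaled selection coefficient of the family.
#' @param n_elements Number of elements to draw.
#' @param N Diploid population size (default 1e4).
#' @param seed Optional seed.
#' @return Numeric vector of frequencies on the grid.
#' @export
simulate_family_frequencies <- function(Ns, n_elements, N = 10000L, seed = NULL) {
  grid <- ascertained_distribution(msb_distribution(Ns, N))
  .with_seed(seed, sample(grid$x, n_elements, replace = TRUE, prob = grid$probs))
}

#' Draw Hardy-Weinberg strain genotypes at a given insertion frequency
#'
#' @param x Insertion frequency in `[0, 1]`.
#' @param n_strains Number of strains.
#' @param seed Optional seed.
#' @return A [genotype_counts()] object.
#' @export
simulate_genotypes <- function(x, n_strains, seed = NULL) {
  if (x < 0 || x > 1) stop("frequency must lie in [0, 1]")
  probs <- c(x^2, 2 * x * (1 - x), (1 - x)^2)
  draw <- .with_seed(seed, stats::rmultinom(1, n_strains, probs))
  genotype_counts(draw[1], draw[2], draw[3])
}

#' Simulate a pooled-PCR panel for one element
#'
#' Each pool draws `2k` genomes at frequency `x`; a pool with no copies
#' is truly absent, one with all copies truly fixed, otherwise truly
#' polymorphic.  Truly polymorphic pools are misread as absent with rate
#' `e1` and as fixed with rate `e2`.  Optionally, assay quality can be
#' degraded: a fraction of scored pools is demoted to the
#' partial-information classes (absent to absent-or-polymorphic, fixed to
#' polymorphic-or-fixed, polymorphic to either at random), and a fraction
#' to the uninformative class.
#'
#' @param x Insertion frequency.
#' @param n_pools Number of pools.
#' @param k Strains per pool (default 11).
#' @param err An [error_rates()] object.
#' @param degrade_partial Fraction of pools demoted to partial classes.
#' @param degrade_uninformative Fraction demoted to no-data.
#' @param seed Optional seed.
#' @return A [pool_observation()].
#' @export
simulate_pool_panel <- function(x, n_pools, k = 11L, err = error_rates(),
                                degrade_partial = 0, degrade_uninformative = 0,
                                seed = NULL) {
  if (x < 0 || x > 1) stop("frequency must lie in [0, 1]")
  .with_seed(seed, {
    copies <- stats::rbinom(n_pools, 2 * k, x)
    cls <- ifelse(copies == 0, 1L, ifelse(copies == 2 * k, 3L, 2L))
    poly <- cls == 2L
    u <- stats::runif(n_pools)
    cls[poly & u < err$e1] <- 1L
    cls[poly & u >= err$e1 & u < err$e1 + err$e2] <- 3L
    v <- stats::runif(n_pools)
    to_m6 <- v < degrade_uninformative
    to_part <- !to_m6 & v < degrade_uninformative + degrade_partial
    cls[to_part & cls == 1L] <- 4L
    cls[to_part & cls == 3L] <- 5L
    two_way <- to_part & cls == 2L
    cls[two_way] <- sample(c(4L, 5L), sum(two_way), replace = TRUE)
    cls[to_m6] <- 6L
    m <- tabulate(cls, nbins = 6L)
    pool_observation(m[1], m[2], m[3], m[4], m[5], m[6], k_strains_per_pool = k)
  })
}

#' Simulate genotype samples along a latitudinal cline
#'
#' Population frequencies follow a line on the angular-transformed scale:
#' `x_i = sin(intercept + slope * latitude_i)^2` (so the cline-regression
#' model is exactly recoverable).  The linear predictor must stay within
#' `[0, pi/2]`, the range of the angular transform; otherwise the
#' configuration is invalid.  Alternatively, `model = "logistic"` uses
#' `x_i = plogis(intercept + slope * latitude_i)` for misspecification
#' experiments.
#'
#' @param intercept,slope Cline parameters (angular scale, radians, for
#'   the default model).
#' @param latitudes Per-population latitudes (degrees from the equator).
#' @param n_strains Strains sampled per population.
#' @param model `"angular"` (default) or `"logistic"`.
#' @param seed Optional seed.
#' @return A list with `frequency` (true per-population frequencies) and
#'   `genotypes` (list of [genotype_counts()], one per population).
#' @export
simulate_cline <- function(intercept, slope, latitudes, n_strains,
                           model = c("angular", "logistic"), seed = NULL) {
  model <- match.arg(model)
  theta <- intercept + slope * latitudes
  if (model == "angular") {
    if (any(theta < 0 | theta > pi / 2))
      stop("invalid cline config: intercept + slope * latitude must stay in [0, pi/2]")
    x <- sin(theta)^2
  } else {
    x <- stats::plogis(theta)
  }
  gts <- .with_seed(seed, lapply(x, function(xi)
    simulate_genotypes(xi, n_strains)))
  list(frequency = x, genotypes = gts)
}

#' Default simulation configuration
#'
#' The defaults emulate the study design the pipeline is built for: a
#' handful of TE families spanning strong purifying selection to
#' neutrality (sizes of a few elements each, as in genome-wide TE family
#' tables), a six-pool panel of 11 strains per pool with misclassification
#' rates 0.042/0.010, and four populations spanning 17-37 degrees of
#' latitude sampled at 24 strains each.
#'
#' @param seed Bundle seed; all stage seeds derive from it.
#' @param N Diploid population size for the frequency grid.
#' @param families Data frame with `name`, `Ns_true`, `n_elements`.
#' @param n_pools,strains_per_pool,e1,e2 Pool-panel design.
#' @param populations Data frame with `id`, `latitude`, `tmax`, `tmin`,
#'   `rainfall`, `n_strains`.
#' @param cline Data frame with `te_id`, `intercept`, `slope` (angular
#'   scale) for TEs given explicit clines; others are flat.
#' @return A `"simulation_config"` list.
#' @export
simulation_config <- function(
    seed = 1L, N = 10000L,
    families = data.frame(
      name = c("famA", "famB", "famC", "famD", "famE", "famF"),
      Ns_true = c(-100, -50, -10, 0, 0, 0),
      n_elements = c(6L, 5L, 5L, 8L, 6L, 4L)),
    n_pools = 6L, strains_per_pool = 11L, e1 = 0.042, e2 = 0.010,
    populations = data.frame(
      id = c("pop_trop", "pop_sub", "pop_mid", "pop_temp"),
      latitude = c(17, 24, 30, 37),
      tmax = c(30.5, 27.8, 24.1, 19.8),
      tmin = c(19.9, 16.5, 11.0, 9.5),
      rainfall = c(285, 120, 95, 55),
      n_strains = c(24L, 24L, 24L, 24L)),
    cline = NULL) {
  if (any(families$n_elements < 1) || n_pools < 1 || strains_per_pool < 1 ||
      any(populations$n_strains < 1))
    stop("invalid config: all counts must be positive")
  structure(list(seed = as.integer(seed), N = as.integer(N),
                 families = families, n_pools = as.integer(n_pools),
                 strains_per_pool = as.integer(strains_per_pool),
                 err = error_rates(e1, e2), populations = populations,
                 cline = cline),
            class = "simulation_config")
}

#' Simulate a full study fixture bundle
#'
#' Generates every input table the pipeline reads, plus a ground-truth
#' table for parameter-recovery tests: TE annotations, a pooled panel per
#' element, per-population strain genotype tables, population metadata,
#' and the true family selection coefficients, element frequencies and
#' cline slopes.  With `out_dir` set, all tables are also written as TSV
#' in the schemas the readers expect.  Identical config and seed give an
#' identical bundle.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory to write TSV files into.
#' @return A list with `annotations`, `pool_panel`, `genotypes` (long
#'   table), `populations`, `truth` data frames (invisibly if written).
#' @export
simulate_study <- function(config = simulation_config(), out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  fams <- config$families
  # per-element true frequencies from the ascertained family spectra
  te_rows <- list(); pool_rows <- list()
  for (i in seq_len(nrow(fams))) {
    xs <- simulate_family_frequencies(fams$Ns_true[i], fams$n_elements[i],
                                      config$N, seed = .sub_seed(config$seed, i))
    for (j in seq_along(xs)) {
      te_id <- sprintf("TE_%s_%02d", fams$name[i], j)
      te_rows[[te_id]] <- data.frame(
        te_id = te_id, family = fams$name[i], true_freq = xs[j],
        stringsAsFactors = FALSE)
      M <- simulate_pool_panel(xs[j], config$n_pools, config$strains_per_pool,
                               config$err,
                               seed = .sub_seed(config$seed, 1000L + 31L * i + j))
      pool_rows[[te_id]] <- data.frame(
        te_id = te_id, family = fams$name[i],
        m1 = M$m[1], m2 = M$m[2], m3 = M$m[3],
        m4 = M$m[4], m5 = M$m[5], m6 = M$m[6], stringsAsFactors = FALSE)
    }
  }
  tes <- do.call(rbind, te_rows)
  pool_panel <- do.call(rbind, pool_rows)
  rownames(tes) <- rownames(pool_panel) <- NULL

  annotations <- data.frame(
    te_id = tes$te_id, family = tes$family,
    chrom_arm = rep_len(c("2L", "2R", "3L", "3R", "X"), nrow(tes)),
    cytoband = sprintf("%02dA1", seq_len(nrow(tes)) %% 99 + 1),
    length_bp = 500L + 137L * (seq_len(nrow(tes)) %% 20),
    recombination_rate = 2.0,
    inversion_overlap = "", stringsAsFactors = FALSE)

  # per-TE clines on the angular scale; default: flat at the true frequency
  pops <- config$populations
  lat <- abs(pops$latitude)
  gt_rows <- list(); truth_cline <- list()
  for (r in seq_len(nrow(tes))) {
    te <- tes$te_id[r]
    cl <- if (!is.null(config$cline) && te %in% config$cline$te_id)
      config$cline[config$cline$te_id == te, ] else NULL
    if (is.null(cl)) {
      intercept <- angular_transform(tes$true_freq[r]); slope <- 0
    } else {
      intercept <- cl$intercept; slope <- cl$slope
    }
    theta <- intercept + slope * lat
    if (any(theta < 0 | theta > pi / 2))
      stop("invalid cline config for ", te,
           ": intercept + slope * latitude must stay in [0, pi/2]")
    freq <- sin(theta)^2
    truth_cline[[te]] <- data.frame(te_id = te, intercept = intercept,
                                    slope = slope, stringsAsFactors = FALSE)
    for (p in seq_len(nrow(pops))) {
      gc <- simulate_genotypes(freq[p], pops$n_strains[p],
                               seed = .sub_seed(config$seed, 2000L + 53L * r + p))
      calls <- rep(c("PP", "PA", "AA"),
                   c(gc$n_hom_present, gc$n_het, gc$n_hom_absent))
      gt_rows[[length(gt_rows) + 1L]] <- data.frame(
        strain_id = sprintf("%s_s%02d", pops$id[p], seq_along(calls)),
        population_id = pops$id[p], te_id = te, call = calls,
        stringsAsFactors = FALSE)
    }
  }
  genotypes <- do.call(rbind, gt_rows)
  rownames(genotypes) <- NULL

  truth <- merge(
    merge(tes, do.call(rbind, truth_cline), by = "te_id"),
    data.frame(family = fams$name, Ns_true = fams$Ns_true,
               stringsAsFactors = FALSE),
    by = "family")
  truth <- truth[order(truth$te_id),
                 c("te_id", "family", "Ns_true", "true_freq", "intercept", "slope")]
  rownames(truth) <- NULL

  bundle <- list(annotations = annotations, pool_panel = pool_panel,
                 genotypes = genotypes, populations = pops, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(bundle))
      utils::write.table(bundle[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(bundle))
  }
  bundle
}
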