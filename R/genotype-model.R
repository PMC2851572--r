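#' Strain genotype counts for one TE in one population
#'
#' Container for the per-population genotype tally of a single transposable
#' element (TE) insertion site.  Each strain is treated as effectively
#' carrying two haploid genomes, so a strain is homozygous present,
#' heterozygous, or homozygous absent for the insertion.
#'
#' @param n_hom_present Number of strains homozygous for the insertion.
#' @param n_het Number of strains heterozygous for the insertion.
#' @param n_hom_absent Number of strains homozygous for absence.
#'
#' @return An object of class `"genotype_counts"`, a list with the three
#'   counts plus `n_strains` (total strains) and `k` (presence-allele count,
#'   `2 * n_hom_present + n_het`).
#'
#' @examples
#' gc <- genotype_counts(6, 5, 11)
#' mle_frequency(gc)$p_hat  # 17/44
#' @export
genotype_counts <- function(n_hom_present, n_het, n_hom_absent) {
  counts <- c(n_hom_present, n_het, n_hom_absent)
  if (length(counts) != 3L || any(!is.finite(counts)))
    stop("genotype counts must be three finite numbers")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("empty sample: at least one genotyped strain is required")
  structure(
    list(
      n_hom_present = as.integer(n_hom_present),
      n_het = as.integer(n_het),
      n_hom_absent = as.integer(n_hom_absent),
      n_strains = as.integer(n),
      k = as.integer(2L * n_hom_present + n_het)
    ),
    class = "genotype_counts"
  )
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf(
    "genotype counts: %d hom-present / %d het / %d hom-absent (n = %d strains, k = %d/%d alleles)\n",
    x$n_hom_present, x$n_het, x$n_hom_absent, x$n_strains, x$k, 2L * x$n_strains
  ))
  invisible(x)
}

# one multinomial log term with the 0 * log 0 := 0 convention;
# a positive count on a zero-probability class gives -Inf
.ll_term <- function(count, prob) {
  if (count == 0) return(0)
  if (prob <= 0) return(-Inf)
  count * log(prob)
}

#' Log-likelihood of genotype counts given an insertion frequency
#'
#' Under Hardy-Weinberg proportions in a panmictic population, a strain is
#' homozygous present with probability \eqn{p^2}, heterozygous with
#' probability \eqn{2p(1-p)} and homozygous absent with probability
#' \eqn{(1-p)^2}.  The log-likelihood is the sum of the corresponding
#' multinomial log terms, with the convention \eqn{0 \log 0 = 0}; a class
#' observed with positive count but probability zero yields `-Inf`.
#' Boundary frequencies 0 and 1 are handled exactly.
#'
#' @param counts A [genotype_counts()] object.
#' @param p Insertion frequency, in `[0, 1]`.
#'
#' @return The log-likelihood (a single number, possibly `-Inf`).
#' @export
loglik_genotypes <- function(counts, p) {
  stopifnot(inherits(counts, "genotype_counts"))
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must be a single frequency in [0, 1]")
  .ll_term(counts$n_hom_present, p^2) +
    .ll_term(counts$n_het, 2 * p * (1 - p)) +
    .ll_term(counts$n_hom_absent, (1 - p)^2)
}

#' Maximum-likelihood insertion frequency
#'
#' The Hardy-Weinberg genotype likelihood is maximised at the sample allele
#' frequency, i.e. the presence-allele count over twice the number of
#' strains.
#'
#' @param counts A [genotype_counts()] object.
#'
#' @return An object of class `"frequency_estimate"`: a list with `p_hat`
#'   (exactly `k / (2 n)`), `n_strains` and `log_likelihood_at_max`.
#' @export
mle_frequency <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  p_hat <- counts$k / (2 * counts$n_strains)
  structure(
    list(
      p_hat = p_hat,
      n_strains = counts$n_strains,
      log_likelihood_at_max = loglik_genotypes(counts, p_hat)
    ),
    class = "frequency_estimate"
  )
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat(sprintf("ML insertion frequency: %.4f (n = %d strains, logL = %.4f)\n",
              x$p_hat, x$n_strains, x$log_likelihood_at_max))
  invisible(x)
}

.pool_counts <- function(a, b) {
  genotype_counts(a$n_hom_present + b$n_hom_present,
                  a$n_het + b$n_het,
                  a$n_hom_absent + b$n_hom_absent)
}

#' Likelihood-ratio test of frequency heterogeneity between two populations
#'
#' Compares the model in which the two populations have separate insertion
#' frequencies (each fitted by its own maximum-likelihood estimate) against
#' the model with a single shared frequency fitted from the pooled counts.
#' `delta_L` is the difference between the sum of the two separate maximised
#' log-likelihoods and the pooled maximised log-likelihood, so it is always
#' non-negative.  P-values refer the likelihood-ratio statistic `2 * delta_L`
#' to a chi-square distribution with one degree of freedom.  For reference
#' the output also records the alternative decision rule that compares
#' `delta_L` itself against 3.84; both rules are reported because they
#' correspond to two conventions in circulation for this test.
#'
#' Because the heterozygote multiplicity terms cancel between the two
#' models, `delta_L` depends on the data only through the presence-allele
#' counts, and `2 * delta_L` equals the G statistic of the 2x2 allele-count
#' table.
#'
#' @param a,b [genotype_counts()] for the two populations.
#'
#' @return An object of class `"heterogeneity_result"`: a list with
#'   `p_hat_a`, `p_hat_b`, `p_hat_pooled`, `delta_L`, `statistic`
#'   (`= 2 * delta_L`), `p_value`, and the two decision flags
#'   `significant_lrt` (`statistic > qchisq(0.95, 1)`) and
#'   `significant_deltaL_rule` (`delta_L > 3.84`).
#'
#' @examples
#' north <- genotype_counts(0, 0, 24)
#' south <- genotype_counts(6, 5, 11)
#' heterogeneity_test(north, south)
#' @export
heterogeneity_test <- function(a, b) {
  stopifnot(inherits(a, "genotype_counts"), inherits(b, "genotype_counts"))
  fit_a <- mle_frequency(a)
  fit_b <- mle_frequency(b)
  pooled <- .pool_counts(a, b)
  fit_p <- mle_frequency(pooled)
  if (fit_a$p_hat == fit_b$p_hat) {
    delta_L <- 0
  } else {
    delta_L <- (fit_a$log_likelihood_at_max + fit_b$log_likelihood_at_max) -
      (loglik_genotypes(a, fit_p$p_hat) + loglik_genotypes(b, fit_p$p_hat))
    delta_L <- max(delta_L, 0)  # guard against roundoff
  }
  statistic <- 2 * delta_L
  p_value <- if (delta_L == 0) 1 else stats::pchisq(statistic, df = 1, lower.tail = FALSE)
  structure(
    list(
      p_hat_a = fit_a$p_hat,
      p_hat_b = fit_b$p_hat,
      p_hat_pooled = fit_p$p_hat,
      delta_L = delta_L,
      statistic = statistic,
      p_value = p_value,
      significant_lrt = statistic > stats::qchisq(0.95, df = 1),
      significant_deltaL_rule = delta_L > 3.84
    ),
    class = "heterogeneity_result"
  )
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf(
    paste0("frequency heterogeneity test\n",
           "  p_hat (pop A / pop B / pooled): %.4f / %.4f / %.4f\n",
           "  delta_L = %.4f, 2*delta_L = %.4f, chi-square(1) p = %.4g\n"),
    x$p_hat_a, x$p_hat_b, x$p_hat_pooled, x$delta_L, x$statistic, x$p_value
  ))
  invisible(x)
}
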