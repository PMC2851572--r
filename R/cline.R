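#' Angular (arcsine square-root) transform of a frequency
#'
#' Variance-stabilising transform for proportions: `asin(sqrt(p))`, in
#' radians (`0` maps to `0`, `1` to `pi/2`).
#'
#' @param p Frequencies in `[0, 1]` (vectorised).
#' @return Transformed values.
#' @export
angular_transform <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("frequencies must lie in [0, 1]")
  asin(sqrt(p))
}

#' Assemble a cline data set
#'
#' @param populations Data frame with one row per population: columns
#'   `id`, `latitude` (degrees from the equator; absolute value is
#'   taken, so both hemispheres share one axis), `tmax`, `tmin` (deg C,
#'   long-term means) and `rainfall` (mm).
#' @param frequencies Long data frame with columns `te_id`,
#'   `population_id`, `frequency`.
#' @return A `"cline_dataset"` list.
#' @export
cline_dataset <- function(populations, frequencies) {
  need_p <- c("id", "latitude", "tmax", "tmin", "rainfall")
  if (!all(need_p %in% names(populations)))
    stop("populations must have columns ", paste(need_p, collapse = ", "))
  need_f <- c("te_id", "population_id", "frequency")
  if (!all(need_f %in% names(frequencies)))
    stop("frequencies must have columns ", paste(need_f, collapse = ", "))
  if (any(frequencies$frequency < 0 | frequencies$frequency > 1))
    stop("frequencies must lie in [0, 1]")
  if (!all(frequencies$population_id %in% populations$id))
    stop("frequency rows refer to unknown populations")
  populations$latitude <- abs(populations$latitude)
  structure(list(populations = populations, frequencies = frequencies),
            class = "cline_dataset")
}

#' Regress a TE's frequency on latitude or a climate covariate
#'
#' Ordinary least squares of the angular-transformed insertion frequency
#' on the chosen covariate, one population = one data point.  Alongside
#' the linear fit, a quadratic term in the covariate is checked and
#' reported as a flag (`quadratic_detected`); only the linear fit is
#' surfaced.
#'
#' @param dataset A [cline_dataset()].
#' @param te_id Which TE to fit.
#' @param covariate One of `"latitude"`, `"tmax"`, `"tmin"`, `"rainfall"`.
#' @param alpha Significance level used for the quadratic-term flag.
#' @return A `"regression_result"`: list with `te_id`, `covariate`,
#'   `r_squared`, `p_value` (two-sided t test on the slope, n-2 df),
#'   `slope`, `slope_se`, `n`, `quadratic_detected`.
#' @export
fit_cline <- function(dataset, te_id,
                      covariate = c("latitude", "tmax", "tmin", "rainfall"),
                      alpha = 0.05) {
  stopifnot(inherits(dataset, "cline_dataset"))
  covariate <- match.arg(covariate)
  f <- dataset$frequencies[dataset$frequencies$te_id == te_id, ]
  if (nrow(f) == 0) stop("no frequencies for TE ", te_id)
  idx <- match(f$population_id, dataset$populations$id)
  xv <- dataset$populations[[covariate]][idx]
  if (length(xv) < 3) stop("at least 3 populations are required")
  if (length(unique(xv)) == 1) stop("covariate is constant across populations")
  y <- angular_transform(f$frequency)
  fit <- stats::lm(y ~ xv)
  sm <- summary(fit)
  quad <- FALSE
  if (length(unique(xv)) > 2 && length(xv) > 3) {
    qfit <- summary(stats::lm(y ~ xv + I(xv^2)))
    qp <- stats::coef(qfit)["I(xv^2)", "Pr(>|t|)"]
    quad <- is.finite(qp) && qp < alpha
  }
  structure(
    list(te_id = te_id, covariate = covariate,
         r_squared = sm$r.squared,
         p_value = stats::coef(sm)["xv", "Pr(>|t|)"],
         slope = stats::coef(sm)["xv", "Estimate"],
         slope_se = stats::coef(sm)["xv", "Std. Error"],
         n = length(xv), quadratic_detected = quad),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("cline regression %s ~ %s: R2 = %.4f, p = %.4g (slope %.4g, n = %d)\n",
              x$te_id, x$covariate, x$r_squared, x$p_value, x$slope, x$n))
  invisible(x)
}

#' Fit all TE-by-covariate cline regressions
#'
#' @param dataset A [cline_dataset()].
#' @param covariates Covariates to fit (default all four).
#' @return A data frame with one row per TE x covariate: `te_id`,
#'   `covariate`, `r_squared`, `p_value`, `slope`, `quadratic_detected`,
#'   plus `p_printed` which renders p-values above 0.05 as `">0.05"` in
#'   the style of published regression tables (full precision is kept in
#'   `p_value`).
#' @export
fit_all_clines <- function(dataset,
                           covariates = c("latitude", "tmax", "tmin", "rainfall")) {
  tes <- unique(dataset$frequencies$te_id)
  rows <- lapply(tes, function(te) {
    do.call(rbind, lapply(covariates, function(cv) {
      r <- fit_cline(dataset, te, cv)
      data.frame(te_id = te, covariate = cv, r_squared = r$r_squared,
                 p_value = r$p_value, slope = r$slope,
                 quadratic_detected = r$quadratic_detected,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out$p_printed <- ifelse(out$p_value > 0.05, ">0.05",
                          formatC(out$p_value, format = "g", digits = 2))
  out
}

#' Count significant regressions
#'
#' @param results Data frame from [fit_all_clines()] (needs `p_value`).
#' @param alpha Significance level (default 0.05).
#' @return Number of results with `p_value < alpha`.
#' @export
count_significant <- function(results, alpha = 0.05) {
  if (nrow(results) == 0) stop("no regression results supplied")
  sum(results$p_value < alpha)
}
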