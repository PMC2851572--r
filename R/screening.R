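#' Screen configuration for the out-of-Africa candidate filter
#'
#' @param required_na_pools Number of North American pools a TE must be
#'   present in (default 6, i.e. all of them).
#' @param african_strain_freq_max Strain-frequency cutoff in the African
#'   sample; TEs present in at least this fraction of strains are removed
#'   (default 0.30, strict: a TE exactly at the cutoff is removed).
#' @param recombination_min TEs must lie in regions with recombination
#'   rate strictly greater than this (cM/Mb; default 0, with 1 as the
#'   documented robustness alternative).
#' @param count_ambiguous_present If `TRUE`, the absent-or-polymorphic
#'   pool class also counts as "present" in the North American pools
#'   (default `FALSE`: present means polymorphic or fixed).
#' @return A `"screen_config"` list.
#' @export
screen_config <- function(required_na_pools = 6L,
                          african_strain_freq_max = 0.30,
                          recombination_min = 0,
                          count_ambiguous_present = FALSE) {
  if (african_strain_freq_max <= 0 || african_strain_freq_max > 1)
    stop("african_strain_freq_max must lie in (0, 1]")
  structure(list(required_na_pools = as.integer(required_na_pools),
                 african_strain_freq_max = african_strain_freq_max,
                 recombination_min = recombination_min,
                 count_ambiguous_present = count_ambiguous_present),
            class = "screen_config")
}

#' Screen annotated TEs for out-of-Africa adaptation candidates
#'
#' Applies, in order, the four conjunctive filters that reduce an
#' annotated TE set to candidates likely to have risen in frequency
#' during or after the out-of-Africa expansion:
#' \enumerate{
#'   \item present in all `required_na_pools` North American pools
#'     (pool class polymorphic or fixed; the ambiguous
#'     absent-or-polymorphic class counts only with
#'     `count_ambiguous_present = TRUE`);
#'   \item not fixed in the African pool (absent or polymorphic both
#'     pass);
#'   \item located in a region with recombination rate strictly above
#'     `recombination_min`;
#'   \item present in fewer than `african_strain_freq_max` of the
#'     individually assayed African strains (a TE exactly at the cutoff
#'     is removed).
#' }
#' The filters are conjunctive, so the final set does not depend on their
#' order, but the per-stage tallies do.
#'
#' @param annotations Data frame with columns `te_id`, `family`,
#'   `recombination_rate` (and optionally more; see
#'   [read_te_annotations()]).
#' @param pool_panel Data frame with `te_id` and `m1`..`m6` counts over
#'   the North American pools.
#' @param african Data frame with `te_id`, `african_pool_class`
#'   (`absent`/`polymorphic`/`fixed`) and `african_strain_freq`.
#' @param cfg A [screen_config()].
#' @return A list with `candidates` (TE ids passing all filters),
#'   `tallies` (named integer vector of survivors after each stage) and
#'   `flags` (per-TE logical matrix of filter passes).
#' @export
screen_candidates <- function(annotations, pool_panel, african,
                              cfg = screen_config()) {
  stopifnot(inherits(cfg, "screen_config"))
  tes <- union(pool_panel$te_id, african$te_id)
  missing_ann <- setdiff(tes, annotations$te_id)
  if (length(missing_ann) > 0)
    stop("TE(s) missing from annotations: ", paste(missing_ann, collapse = ", "))
  tes <- pool_panel$te_id
  ann <- annotations[match(tes, annotations$te_id), ]
  afr <- african[match(tes, african$te_id), ]
  if (any(is.na(afr$te_id)))
    stop("TE(s) missing from African data: ",
         paste(tes[is.na(afr$te_id)], collapse = ", "))

  n_present <- pool_panel$m2 + pool_panel$m3 +
    if (cfg$count_ambiguous_present) pool_panel$m4 else 0L
  f1 <- n_present >= cfg$required_na_pools
  f2 <- afr$african_pool_class != "fixed"
  f3 <- ann$recombination_rate > cfg$recombination_min
  f4 <- afr$african_strain_freq < cfg$african_strain_freq_max

  flags <- cbind(na_pools = f1, african_not_fixed = f2,
                 recombination = f3, african_freq = f4)
  rownames(flags) <- tes
  keep <- f1
  tallies <- c(input = length(tes), na_pools = sum(keep))
  keep <- keep & f2; tallies["african_not_fixed"] <- sum(keep)
  keep <- keep & f3; tallies["recombination"] <- sum(keep)
  keep <- keep & f4; tallies["african_freq"] <- sum(keep)
  list(candidates = tes[keep], tallies = tallies, flags = flags)
}

#' Classify a TE as putatively adaptive or putatively neutral
#'
#' A TE inherits the classification of its family's selection-coefficient
#' estimate: TEs from families with selection coefficients not
#' significantly different from zero are putatively neutral; TEs from
#' significantly negative (purifying-selection) families are putatively
#' adaptive, as are TEs from families whose coefficient could not be
#' inferred (no clear evidence of neutrality).
#'
#' @param te_id TE identifier.
#' @param annotations Annotation table mapping `te_id` to `family`.
#' @param family_estimates Data frame from [fit_all_families()] (or any
#'   with columns `family`, `classification`).
#' @return `"putatively_adaptive"` or `"putatively_neutral"`.
#' @export
classify_te <- function(te_id, annotations, family_estimates) {
  fam <- annotations$family[match(te_id, annotations$te_id)]
  if (any(is.na(fam)))
    stop("TE(s) missing from annotations: ",
         paste(te_id[is.na(fam)], collapse = ", "))
  cls <- family_estimates$classification[match(fam, family_estimates$family)]
  if (any(is.na(cls)))
    stop("family estimate missing for: ",
         paste(unique(fam[is.na(cls)]), collapse = ", "))
  ifelse(cls == "putatively_neutral", "putatively_neutral", "putatively_adaptive")
}
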