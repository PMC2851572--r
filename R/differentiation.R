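#' Population-pair manifest for differentiation tests
#'
#' Each comparison pairs a tropical with a temperate population.  In the
#' southern hemisphere (Australia) the temperate pole of the pair is the
#' southern population; in the northern hemisphere (North America) it is
#' the northern one.
#'
#' @param pair_id Character vector of pair identifiers.
#' @param hemisphere `"southern"` or `"northern"` per pair.
#' @param population_north,population_south Optional population ids.
#' @return A data frame with a `temperate_pole` column (`"south"` for
#'   southern-hemisphere pairs, `"north"` otherwise).
#' @export
comparison_pairs <- function(pair_id, hemisphere,
                             population_north = NA_character_,
                             population_south = NA_character_) {
  hemisphere <- match.arg(hemisphere, c("southern", "northern"), several.ok = TRUE)
  data.frame(pair_id = pair_id, hemisphere = hemisphere,
             population_north = population_north,
             population_south = population_south,
             temperate_pole = ifelse(hemisphere == "southern", "south", "north"),
             stringsAsFactors = FALSE)
}

#' Default manifest: two Australian collections and one North American
#' @return See [comparison_pairs()].
#' @export
default_pairs <- function() {
  comparison_pairs(pair_id = c("AU2007", "AU2008", "NA"),
                   hemisphere = c("southern", "southern", "northern"))
}

#' Exclude TEs confounded by chromosomal inversions
#'
#' TEs located inside clinal inversions whose confounding effect on
#' insertion frequency cannot be ruled out are removed before the
#' differentiation analysis.
#'
#' @param tes Character vector of TE ids.
#' @param inversion_overlap Named list (or named character vector) mapping
#'   TE id to the inversions it overlaps (`character(0)`/`""` for none).
#' @param confounded Inversion labels that disqualify a TE.
#' @return The retained TE ids; warns if none survive.
#' @export
exclude_inversion_tes <- function(tes, inversion_overlap,
                                  confounded = c("In(3R)Payne", "In(2R)NS")) {
  drop <- vapply(tes, function(te) {
    ov <- inversion_overlap[[te]]
    if (is.null(ov)) return(FALSE)
    any(ov %in% confounded)
  }, logical(1))
  kept <- tes[!drop]
  if (length(kept) == 0 && length(tes) > 0)
    warning("all TEs overlap confounding inversions; empty set returned")
  kept
}

#' Drop strains carrying scored inversions from a genotype table
#'
#' Strains in which a clinal inversion was detected are removed before
#' frequency estimation, so that inversion-linked structure cannot mimic
#' TE frequency differentiation.
#'
#' @param genotypes Genotype table (see [read_genotype_table()]).
#' @param strain_inversions Character vector of strain ids carrying a
#'   scored inversion.
#' @return The filtered genotype table.
#' @export
drop_inversion_strains <- function(genotypes, strain_inversions) {
  genotypes[!(genotypes$strain_id %in% strain_inversions), , drop = FALSE]
}

#' Plain (non-monotone) Benjamini-Hochberg adjusted p-values
#'
#' Computes `q_i = p_i * m / rank_i` with ranks from the ascending sort
#' (ties broken by stable input order), capped at 1, without the step-up
#' monotonicity enforcement of `stats::p.adjust(method = "BH")`.  The
#' plain form is what many published tables report; it can be
#' non-monotone in p (a larger raw p can receive a smaller adjusted
#' value), which the monotone adjustment cannot produce.  Use
#' [bh_significant()] for the actual step-up rejection decisions.
#'
#' @param pvals Raw p-values, all in `(0, 1]`.
#' @param m Number of tests (default `length(pvals)`).
#' @return Adjusted values in input order.
#' @export
bh_adjust_plain <- function(pvals, m = length(pvals)) {
  if (any(!is.finite(pvals)) || any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  ord <- order(pvals)              # stable: ties keep input order
  ranks <- integer(length(pvals))
  ranks[ord] <- seq_along(pvals)
  pmin(pvals * m / ranks, 1)
}

#' Benjamini-Hochberg step-up rejection flags
#'
#' Standard step-up rule: with sorted p-values `p_(1) <= ... <= p_(m)`,
#' reject hypotheses of rank `1..i*` where
#' `i* = max{ i : p_(i) <= i * alpha / m }`.
#'
#' @param pvals Raw p-values in `(0, 1]`.
#' @param alpha Target false discovery rate (default 0.05).
#' @param m Number of tests (default `length(pvals)`).
#' @return Logical vector in input order.
#' @export
bh_significant <- function(pvals, alpha = 0.05, m = length(pvals)) {
  if (any(!is.finite(pvals)) || any(pvals <= 0 | pvals > 1))
    stop("p-values must lie in (0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  ord <- order(pvals)
  sorted <- pvals[ord]
  ok <- which(sorted <= seq_along(sorted) * alpha / m)
  flags <- logical(length(pvals))
  if (length(ok) > 0) flags[ord[seq_len(max(ok))]] <- TRUE
  flags
}

#' Annotate a differentiation table with FDR columns and direction labels
#'
#' Takes per-TE, per-pair test results and adds, within each comparison
#' pair separately: the plain adjusted p-value ([bh_adjust_plain()]), the
#' step-up significance flag ([bh_significant()]), and a direction label
#' (`temperate_higher`, `tropical_higher` or `tie`) based on which pole of
#' the pair has the higher frequency.
#'
#' @param table Data frame with columns `te_id`, `pair_id`, `freq_north`,
#'   `freq_south`, `p_raw` (and optionally `te_class`).
#' @param pairs Pair manifest (see [comparison_pairs()]); default
#'   [default_pairs()].
#' @param alpha FDR level for the step-up decisions.
#' @param pool_comparisons If `TRUE`, apply the FDR correction across all
#'   rows jointly instead of within each pair (off by default).
#' @return The input with columns `q_value`, `significant_bh`,
#'   `direction` appended.
#' @export
annotate_differentiation <- function(table, pairs = default_pairs(),
                                     alpha = 0.05, pool_comparisons = FALSE) {
  need <- c("te_id", "pair_id", "freq_north", "freq_south", "p_raw")
  if (!all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "))
  unknown <- setdiff(unique(table$pair_id), pairs$pair_id)
  if (length(unknown) > 0)
    stop("pair(s) missing from manifest: ", paste(unknown, collapse = ", "))
  table$q_value <- rep(NA_real_, nrow(table))
  table$significant_bh <- rep(NA, nrow(table))
  if (pool_comparisons) {
    table$q_value <- bh_adjust_plain(table$p_raw)
    table$significant_bh <- bh_significant(table$p_raw, alpha)
  } else {
    for (pid in unique(table$pair_id)) {
      idx <- table$pair_id == pid
      table$q_value[idx] <- bh_adjust_plain(table$p_raw[idx])
      table$significant_bh[idx] <- bh_significant(table$p_raw[idx], alpha)
    }
  }
  pole <- pairs$temperate_pole[match(table$pair_id, pairs$pair_id)]
  f_temp <- ifelse(pole == "south", table$freq_south, table$freq_north)
  f_trop <- ifelse(pole == "south", table$freq_north, table$freq_south)
  table$direction <- ifelse(f_temp > f_trop, "temperate_higher",
                            ifelse(f_temp < f_trop, "tropical_higher", "tie"))
  table
}

#' Run heterogeneity tests for every TE across population pairs
#'
#' Builds a differentiation table from a long genotype table by computing
#' ML frequencies and the likelihood-ratio heterogeneity test for every
#' TE in every comparison pair, then annotating with
#' [annotate_differentiation()].  Missing calls (`NA`) are dropped per TE
#' per population, so strain totals may differ across TEs.
#'
#' @param genotypes Genotype table (see [read_genotype_table()]).
#' @param pairs Pair manifest with `population_north`/`population_south`
#'   filled in.
#' @param te_class Optional named vector mapping TE id to
#'   `"putatively_adaptive"`/`"putatively_neutral"`.
#' @param alpha FDR level.
#' @return An annotated differentiation table (one row per TE x pair).
#' @export
differentiation_table <- function(genotypes, pairs, te_class = NULL,
                                  alpha = 0.05) {
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    pn <- pairs$population_north[i]; ps <- pairs$population_south[i]
    sub <- genotypes[genotypes$population_id %in% c(pn, ps), , drop = FALSE]
    for (te in unique(sub$te_id)) {
      cn <- genotype_counts_from_table(sub, te, pn)
      cs <- genotype_counts_from_table(sub, te, ps)
      if (is.null(cn) || is.null(cs)) next
      ht <- heterogeneity_test(cn, cs)
      rows[[length(rows) + 1L]] <- data.frame(
        te_id = te, pair_id = pairs$pair_id[i],
        freq_north = mle_frequency(cn)$p_hat,
        freq_south = mle_frequency(cs)$p_hat,
        delta_L = ht$delta_L, statistic = ht$statistic, p_raw = ht$p_value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(te_class)) out$te_class <- unname(te_class[out$te_id])
  annotate_differentiation(out, pairs, alpha = alpha)
}

#' Summary counts of significant candidate TEs
#'
#' Counts the TEs significant (step-up BH) in at least one comparison,
#' splits them by adaptive/neutral family class, and counts how many show
#' the direction expected under adaptation to temperate climates (higher
#' frequency at the pair's temperate pole in a significant comparison).
#'
#' @param table An annotated differentiation table with a `te_class`
#'   column (see [annotate_differentiation()]).
#' @return A list with `n_unique_significant`, `n_adaptive`,
#'   `n_expected_direction`, `n_neutral_significant` and
#'   `per_pair_counts` (named integer vector of significant rows per
#'   pair).  Row order of the input is irrelevant.
#' @export
summarize_candidates <- function(table) {
  if (nrow(table) == 0) {
    return(list(n_unique_significant = 0L, n_adaptive = 0L,
                n_expected_direction = 0L, n_neutral_significant = 0L,
                per_pair_counts = integer(0)))
  }
  sig <- table[table$significant_bh, , drop = FALSE]
  uniq <- unique(sig$te_id)
  cls <- if ("te_class" %in% names(table))
    tapply(table$te_class, table$te_id, function(v) v[1]) else NULL
  n_adaptive <- if (is.null(cls)) NA_integer_ else
    sum(cls[uniq] == "putatively_adaptive", na.rm = TRUE)
  n_neutral <- if (is.null(cls)) NA_integer_ else
    sum(cls[uniq] == "putatively_neutral", na.rm = TRUE)
  expected <- vapply(uniq, function(te) {
    any(sig$direction[sig$te_id == te] == "temperate_higher")
  }, logical(1))
  per_pair <- vapply(split(sig, sig$pair_id), nrow, integer(1))
  list(n_unique_significant = length(uniq),
       n_adaptive = n_adaptive,
       n_expected_direction = sum(expected),
       n_neutral_significant = n_neutral,
       per_pair_counts = per_pair)
}

# log-likelihood-ratio (G) statistic of an observed/expected count vector
.g_stat <- function(obs, expd) {
  keep <- obs > 0
  2 * sum(obs[keep] * log(obs[keep] / expd[keep]))
}

#' Directionality G-tests for candidate TEs
#'
#' Tests whether direction labels (temperate-higher vs tropical-higher,
#' over TE x pair observations) depart from 1:1 within each family class
#' (replicated goodness-of-fit G-test), and whether direction is
#' independent of class (2x2 independence G-test).  Ties are excluded.
#'
#' This is one defensible contingency construction for direction counts
#' ("interpretation A"); published directionality p-values for this kind
#' of data are not always computed this way, so the output is meant as a
#' qualitative companion to [summarize_candidates()], not as a
#' reproduction of any particular printed value.
#'
#' @param table Annotated differentiation table with `te_class`.
#' @param classes Which classes to test (default both).
#' @param significant_only Restrict to step-up-significant rows
#'   (default `FALSE`: all tested rows carry a direction).
#' @return A list with per-class goodness-of-fit results (`G`, `df`,
#'   `p_value`, `n_temperate`, `n_tropical`) and the 2x2 independence test
#'   (`independence`).  Degenerate tables give `p = 1` with a warning.
#' @export
direction_gtest <- function(table,
                            classes = c("putatively_adaptive", "putatively_neutral"),
                            significant_only = FALSE) {
  stopifnot("te_class" %in% names(table))
  if (significant_only) table <- table[table$significant_bh, , drop = FALSE]
  table <- table[table$direction != "tie", , drop = FALSE]
  per_class <- lapply(classes, function(cl) {
    d <- table$direction[table$te_class == cl]
    n1 <- sum(d == "temperate_higher"); n2 <- sum(d == "tropical_higher")
    if (n1 + n2 == 0) {
      warning("no direction observations for class ", cl, "; p = 1")
      return(list(G = 0, df = 1L, p_value = 1, n_temperate = n1, n_tropical = n2))
    }
    G <- .g_stat(c(n1, n2), rep((n1 + n2) / 2, 2))
    list(G = G, df = 1L, p_value = stats::pchisq(G, 1, lower.tail = FALSE),
         n_temperate = n1, n_tropical = n2)
  })
  names(per_class) <- classes
  tab <- table(factor(table$te_class, levels = classes),
               factor(table$direction,
                      levels = c("temperate_higher", "tropical_higher")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate class-by-direction table; independence p = 1")
    indep <- list(G = 0, df = 1L, p_value = 1, counts = tab)
  } else {
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    G <- .g_stat(as.numeric(tab), as.numeric(expd))
    indep <- list(G = G, df = 1L,
                  p_value = stats::pchisq(G, 1, lower.tail = FALSE),
                  counts = tab)
  }
  list(per_class = per_class, independence = indep,
       interpretation = "A: replicated goodness-of-fit vs 1:1 + 2x2 independence")
}
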