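test_that("plain BH adjustment reproduces printed FDR cells and closed forms", {
  # single p is unchanged; uniform vector gives p*m/i
  expect_equal(bh_adjust_plain(0.37), 0.37)
  p <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(bh_adjust_plain(p), p * 4 / 1:4)
  expect_error(bh_adjust_plain(c(0, 0.5)), "\\(0, 1\\]")
  expect_error(bh_adjust_plain(c(0.5, 1.1)), "\\(0, 1\\]")

  tab <- te_differentiation_fixture()
  au08 <- tab[tab$pair_id == "AU2008", ]
  q <- bh_adjust_plain(au08$p_raw)
  # rank-4 cell: 0.0024 * 28 / 4 = 0.0168, exact
  expect_equal(q[au08$p_raw == 0.0024], 0.0168)
  # top-ranked cell: 6e-08 * 28 = 1.68e-06, printed 1.7e-06
  expect_equal(signif(q[au08$p_raw == 6e-08], 2), 1.7e-06)
  na_col <- tab[tab$pair_id == "NA", ]
  qna <- bh_adjust_plain(na_col$p_raw)
  # rank-2 cell: 9.6e-07 * 28 / 2 = 1.344e-05, printed 1.3e-05
  expect_equal(signif(qna[na_col$p_raw == 9.6e-07], 2), 1.3e-05)
  # the plain form is non-monotone here: the larger raw p-value 0.0017
  # receives a smaller adjusted value than 0.0016 (ranks 6 vs 5)
  expect_lt(qna[na_col$p_raw == 0.0017], qna[na_col$p_raw == 0.0016])

  # whitelist: printed FDR cells that the plain rule reproduces at the
  # precision the rounded raw p-values allow (relative error under 3%,
  # the worst case induced by last-digit rounding of the raw column)
  for (pid in unique(tab$pair_id)) {
    col <- tab[tab$pair_id == pid, ]
    qcol <- bh_adjust_plain(col$p_raw)
    expect_lt(median(abs(qcol - col$fdr_printed) / col$fdr_printed), 0.03)
  }
})

test_that("step-up decisions match brute force, p.adjust, and the printed bold cells", {
  set.seed(909)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))^2
    alpha <- runif(1, 0.01, 0.2)
    got <- bh_significant(p, alpha)
    expect_identical(got, oracle_bh_stepup(p, alpha))
    expect_identical(got, unname(p.adjust(p, "BH") <= alpha))
  }
  expect_identical(bh_significant(rep(1, 10)), rep(FALSE, 10))

  tab <- te_differentiation_fixture()
  for (pid in c("AU2007", "AU2008", "NA")) {
    col <- tab[tab$pair_id == pid, ]
    expect_identical(bh_significant(col$p_raw, 0.05), col$fdr_bold)
  }
  # per-column significant counts: 1, 6, 8
  counts <- vapply(split(tab, tab$pair_id),
                   function(d) sum(bh_significant(d$p_raw, 0.05)), integer(1))
  expect_equal(unname(counts[c("AU2007", "AU2008", "NA")]), c(1L, 6L, 8L))
})

test_that("direction labels follow the pair's temperate pole", {
  tab <- data.frame(
    te_id = c("t1", "t1", "t2"),
    pair_id = c("AU2008", "NA", "AU2008"),
    freq_north = c(0.1, 0.8, 0.5),
    freq_south = c(0.6, 0.2, 0.5),
    p_raw = c(0.001, 0.001, 0.9))
  ann <- annotate_differentiation(tab)
  # south pole temperate in Australia, north pole in North America
  expect_equal(ann$direction, c("temperate_higher", "temperate_higher", "tie"))
  expect_error(annotate_differentiation(transform(tab, pair_id = "XX")),
               "missing from manifest")
})

test_that("candidate summary counts are row-order invariant and correct on fixtures", {
  tab <- annotate_differentiation(te_differentiation_fixture())
  s <- summarize_candidates(tab)
  expect_equal(s$n_unique_significant, 12L)
  expect_equal(s$n_adaptive, 9L)
  expect_equal(s$n_expected_direction, 10L)
  expect_equal(s$n_neutral_significant, 3L)
  set.seed(11)
  s2 <- summarize_candidates(tab[sample(nrow(tab)), ])
  expect_equal(s2[1:4], s[1:4])
  # empty table: all zeros
  s0 <- summarize_candidates(tab[0, ])
  expect_equal(s0$n_unique_significant, 0L)
  expect_equal(s0$n_expected_direction, 0L)
  # single significant TE in the wrong direction
  one <- data.frame(te_id = "t", pair_id = "AU2008", freq_north = 0.9,
                    freq_south = 0.1, p_raw = 1e-6,
                    te_class = "putatively_adaptive")
  s1 <- summarize_candidates(annotate_differentiation(one))
  expect_equal(s1$n_unique_significant, 1L)
  expect_equal(s1$n_expected_direction, 0L)
})

test_that("neutral significant TEs in the fixture are North-America-only", {
  tab <- annotate_differentiation(te_differentiation_fixture())
  sig <- tab[tab$significant_bh & tab$te_class == "putatively_neutral", ]
  expect_equal(unique(sig$pair_id), "NA")
  expect_equal(length(unique(sig$te_id)), 3L)
})

test_that("inversion exclusion drops the right TEs and strains", {
  tes <- c("a", "b", "c", "d")
  ov <- list(a = character(0), b = "In(3R)Payne", c = "In(2L)t", d = "In(2R)NS")
  expect_equal(exclude_inversion_tes(tes, ov), c("a", "c"))
  expect_equal(exclude_inversion_tes(tes, list()), tes)
  expect_warning(kept <- exclude_inversion_tes("b", ov), "empty set")
  expect_length(kept, 0)

  gt <- data.frame(strain_id = c("s1", "s2", "s3"), population_id = "p",
                   te_id = "t", call = c("PP", "PA", "AA"))
  expect_equal(drop_inversion_strains(gt, "s2")$strain_id, c("s1", "s3"))
})

test_that("direction G-tests have their closed forms and match an oracle", {
  # all temperate-higher, n = 20: G = 2 * 20 * ln 2
  raw <- data.frame(te_id = paste0("t", 1:20), pair_id = "AU2008",
                    freq_north = 0.1, freq_south = 0.9, p_raw = 1e-6,
                    te_class = "putatively_adaptive")
  tab <- annotate_differentiation(raw)
  # (independence table is degenerate here — one direction only)
  g <- suppressWarnings(direction_gtest(tab, classes = "putatively_adaptive"))
  expect_equal(g$per_class[[1]]$G, 2 * 20 * log(2), tolerance = 1e-12)
  expect_lt(g$per_class[[1]]$p_value, 1e-5)

  # exactly balanced directions: G = 0, p = 1
  raw2 <- data.frame(te_id = paste0("t", 1:10), pair_id = "AU2008",
                     freq_north = rep(c(0.1, 0.9), 5),
                     freq_south = rep(c(0.9, 0.1), 5), p_raw = 0.5,
                     te_class = "putatively_adaptive")
  g2 <- direction_gtest(annotate_differentiation(raw2),
                        classes = "putatively_adaptive")
  expect_equal(g2$per_class[[1]]$G, 0)
  expect_equal(g2$per_class[[1]]$p_value, 1)

  # 2x2 independence G against an independent implementation
  tab3 <- annotate_differentiation(
    rbind(raw, transform(raw2, te_class = "putatively_neutral",
                         te_id = paste0("n", 1:10))))
  g3 <- direction_gtest(tab3)
  counts <- g3$independence$counts
  expect_equal(g3$independence$G,
               oracle_g2x2(counts[1, 1], sum(counts[1, ]),
                           counts[2, 1], sum(counts[2, ])),
               tolerance = 1e-10)
  # degenerate table warns and returns p = 1
  warns <- capture_warnings(
    g4 <- direction_gtest(tab, classes = c("putatively_adaptive",
                                           "putatively_neutral")))
  expect_true(any(grepl("no direction observations", warns)))
  expect_equal(g4$per_class$putatively_neutral$p_value, 1)
  expect_equal(g4$independence$p_value, 1)
})
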