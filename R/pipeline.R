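#' Pipeline configuration
#'
#' Bundles paths and parameters for [run_subcommand()].  Referenced files
#' are checked for existence at dispatch time.
#'
#' @param genotypes,pool_panel,annotations,african,populations,
#'   frequencies,diff_table Optional input paths (TSV; schemas in the
#'   respective readers).
#' @param out_dir Output directory (created if needed).
#' @param alpha FDR / significance level.
#' @param pool_comparisons Apply FDR across comparisons jointly.
#' @param N Diploid population size for the selection model.
#' @param e1,e2 Pooled-PCR misclassification rates.
#' @param k_strains_per_pool Strains per pool.
#' @param search_range `Ns` search interval for family fits.
#' @param ci_const Profile log-likelihood drop for family CIs.
#' @param seed Seed for stochastic stages.
#' @param log_level `"info"` prints stage messages, `"quiet"` does not.
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(genotypes = NULL, pool_panel = NULL,
                            annotations = NULL, african = NULL,
                            populations = NULL, frequencies = NULL,
                            diff_table = NULL,
                            out_dir = tempfile("teclines_out_"),
                            alpha = 0.05, pool_comparisons = FALSE,
                            N = 10000L, e1 = 0.042, e2 = 0.010,
                            k_strains_per_pool = 11L,
                            search_range = c(-500, 50), ci_const = 2.512,
                            seed = 1L, log_level = c("info", "quiet")) {
  structure(list(genotypes = genotypes, pool_panel = pool_panel,
                 annotations = annotations, african = african,
                 populations = populations, frequencies = frequencies,
                 diff_table = diff_table, out_dir = out_dir, alpha = alpha,
                 pool_comparisons = pool_comparisons, N = as.integer(N),
                 err = error_rates(e1, e2),
                 k_strains_per_pool = as.integer(k_strains_per_pool),
                 search_range = search_range, ci_const = ci_const,
                 seed = as.integer(seed),
                 log_level = match.arg(log_level)),
            class = "pipeline_config")
}

.log_info <- function(config, fmt, ...) {
  if (config$log_level == "info") message(sprintf(fmt, ...))
  invisible(NULL)
}

.need_paths <- function(config, fields) {
  for (f in fields) {
    if (is.null(config[[f]])) stop("config field '", f, "' is required")
    if (!file.exists(config[[f]])) stop("input file not found: ", config[[f]])
  }
}

#' Run one pipeline stage
#'
#' Dispatches to the corresponding module and writes its outputs as TSV
#' into `config$out_dir`:
#' \describe{
#'   \item{`screen`}{[screen_candidates()] on annotations + pool panel +
#'     African data; writes `screen_candidates.tsv` and
#'     `screen_tallies.tsv`.}
#'   \item{`selcoef`}{[fit_all_families()] on the pool panel; writes
#'     `selection_estimates.tsv`.}
#'   \item{`difftest`}{[differentiation_table()] from a genotype table,
#'     or [annotate_differentiation()] of a precomputed table
#'     (`config$diff_table` with columns `te_id`, `pair_id`,
#'     `freq_north`, `freq_south`, `p_raw`, optionally `te_class`);
#'     writes `differentiation.tsv`.}
#'   \item{`cline`}{[fit_all_clines()] on population metadata +
#'     frequencies; writes `cline_regressions.tsv`.}
#'   \item{`simulate`}{[simulate_study()] with the config seed; writes
#'     the fixture bundle.}
#'   \item{`report`}{Reads `differentiation.tsv` from `out_dir` (running
#'     `difftest` first if absent) and writes `report_summary.txt` with
#'     the candidate counts from [summarize_candidates()].}
#' }
#'
#' @param name Subcommand name.
#' @param config A [pipeline_config()].
#' @return The stage's main result, invisibly.
#' @export
run_subcommand <- function(name = c("screen", "selcoef", "difftest",
                                    "cline", "simulate", "report"),
                           config = pipeline_config()) {
  name <- match.arg(name)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(
    name,
    screen = {
      .need_paths(config, c("annotations", "pool_panel", "african"))
      ann <- read_te_annotations(config$annotations)
      panel <- read_pool_panel(config$pool_panel)
      afr <- utils::read.delim(config$african, stringsAsFactors = FALSE)
      res <- screen_candidates(ann, panel, afr)
      .log_info(config, "screen tallies: %s",
                paste(names(res$tallies), res$tallies, sep = "=", collapse = ", "))
      write_tsv(data.frame(te_id = res$candidates),
                file.path(config$out_dir, "screen_candidates.tsv"))
      write_tsv(data.frame(stage = names(res$tallies),
                           surviving = as.integer(res$tallies)),
                file.path(config$out_dir, "screen_tallies.tsv"))
      res
    },
    selcoef = {
      .need_paths(config, "pool_panel")
      panel <- read_pool_panel(config$pool_panel)
      est <- fit_all_families(panel, k_strains_per_pool = config$k_strains_per_pool,
                              N = config$N, err = config$err,
                              search_range = config$search_range,
                              ci_const = config$ci_const, seed = config$seed)
      .log_info(config, "fitted %d families", nrow(est))
      write_tsv(est, file.path(config$out_dir, "selection_estimates.tsv"))
      est
    },
    difftest = {
      if (!is.null(config$diff_table)) {
        .need_paths(config, "diff_table")
        tab <- utils::read.delim(config$diff_table, stringsAsFactors = FALSE,
                                 na.strings = character(0))
        res <- annotate_differentiation(tab, alpha = config$alpha,
                                        pool_comparisons = config$pool_comparisons)
      } else {
        .need_paths(config, c("genotypes", "pool_panel"))
        stop("difftest from raw genotypes needs a pair manifest; use ",
             "differentiation_table() directly or supply diff_table")
      }
      .log_info(config, "difftest: %d rows, %d significant",
                nrow(res), sum(res$significant_bh))
      write_tsv(res, file.path(config$out_dir, "differentiation.tsv"))
      res
    },
    cline = {
      .need_paths(config, c("populations", "frequencies"))
      pops <- read_population_metadata(config$populations)
      freqs <- utils::read.delim(config$frequencies, stringsAsFactors = FALSE)
      res <- fit_all_clines(cline_dataset(pops, freqs))
      .log_info(config, "cline: %d regressions, %d significant at alpha = %g",
                nrow(res), count_significant(res, config$alpha), config$alpha)
      write_tsv(res, file.path(config$out_dir, "cline_regressions.tsv"))
      res
    },
    simulate = {
      bundle <- simulate_study(simulation_config(seed = config$seed,
                                                 N = config$N),
                               out_dir = config$out_dir)
      .log_info(config, "simulated %d TEs in %d families",
                nrow(bundle$annotations), length(unique(bundle$annotations$family)))
      bundle
    },
    report = {
      diff_path <- file.path(config$out_dir, "differentiation.tsv")
      if (!file.exists(diff_path)) run_subcommand("difftest", config)
      tab <- utils::read.delim(diff_path, stringsAsFactors = FALSE,
                               na.strings = character(0))
      tab$significant_bh <- as.logical(tab$significant_bh)
      s <- summarize_candidates(tab)
      lines <- c(
        sprintf("TEs significant in >= 1 comparison: %d", s$n_unique_significant),
        sprintf("  of which putatively adaptive:     %s", s$n_adaptive),
        sprintf("  of which putatively neutral:      %s", s$n_neutral_significant),
        sprintf("  with temperate-pole-higher freq:  %d", s$n_expected_direction),
        if (length(s$per_pair_counts))
          sprintf("  significant rows in %s: %d",
                  names(s$per_pair_counts), s$per_pair_counts))
      writeLines(lines, file.path(config$out_dir, "report_summary.txt"))
      .log_info(config, "%s", paste(lines, collapse = "\n"))
      s
    })
  invisible(out)
}
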