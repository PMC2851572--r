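#' Read a strain genotype table
#'
#' TSV with one row per (strain, TE): columns `strain_id`,
#' `population_id`, `te_id`, `call` in `{PP, PA, AA, NA}` (homozygous
#' present / heterozygous / homozygous absent / missing).  Missing calls
#' are kept in the table and dropped per TE per population when counts
#' are built, so strain totals may differ across TEs.
#'
#' @param path Path to the TSV file.
#' @return A data frame.
#' @export
read_genotype_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = character(0))
  need <- c("strain_id", "population_id", "te_id", "call")
  if (!all(need %in% names(df)))
    stop("genotype table must have columns ", paste(need, collapse = ", "))
  bad <- !(df$call %in% c("PP", "PA", "AA", "NA"))
  if (any(bad))
    stop("invalid genotype call(s) in rows: ",
         paste(utils::head(which(bad), 5), collapse = ", "))
  df
}

#' Tally genotype calls for one TE in one population
#'
#' @param genotypes Genotype table (see [read_genotype_table()]).
#' @param te_id,population_id Which TE / population to tally.
#' @return A [genotype_counts()] object, or `NULL` if no informative
#'   calls exist.
#' @export
genotype_counts_from_table <- function(genotypes, te_id, population_id) {
  calls <- genotypes$call[genotypes$te_id == te_id &
                            genotypes$population_id == population_id]
  calls <- calls[calls != "NA"]
  if (length(calls) == 0) return(NULL)
  genotype_counts(sum(calls == "PP"), sum(calls == "PA"), sum(calls == "AA"))
}

#' Read a pooled-PCR panel table
#'
#' TSV with columns `te_id`, `family`, `m1`..`m6` (pool classification
#' counts; see [pool_observation()]).
#' @param path Path to the TSV file.
#' @return A data frame.
#' @export
read_pool_panel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("te_id", "family", paste0("m", 1:6))
  if (!all(need %in% names(df)))
    stop("pool panel must have columns ", paste(need, collapse = ", "))
  df
}

#' Read a TE annotation table
#'
#' TSV with columns `te_id`, `family`, `chrom_arm`, `cytoband`,
#' `length_bp`, `recombination_rate` (cM/Mb), `inversion_overlap`
#' (comma-separated inversion labels, empty for none).
#' @param path Path to the TSV file.
#' @return A data frame; `inversion_overlap` is split into a list column.
#' @export
read_te_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = character(0))
  need <- c("te_id", "family", "recombination_rate")
  if (!all(need %in% names(df)))
    stop("annotations must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$te_id)) stop("duplicated te_id in annotations")
  if (any(df$recombination_rate < 0)) stop("recombination_rate must be >= 0")
  if ("inversion_overlap" %in% names(df)) {
    ov <- as.character(df$inversion_overlap)
    ov[is.na(ov)] <- ""
    df$inversion_overlap <- ov
    df$inversions <- lapply(strsplit(ov, ","), function(v) v[nzchar(v)])
  }
  df
}

#' Read a population metadata table
#'
#' TSV with columns `id`, `latitude`, `tmax`, `tmin`, `rainfall` (see
#' [cline_dataset()]).
#' @param path Path to the TSV file.
#' @return A data frame.
#' @export
read_population_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "latitude", "tmax", "tmin", "rainfall")
  if (!all(need %in% names(df)))
    stop("population metadata must have columns ", paste(need, collapse = ", "))
  df
}

#' Published 28-TE differentiation table (packaged fixture)
#'
#' The packaged per-TE population frequencies and raw heterogeneity-test
#' p-values for 28 TE insertions across three population-pair
#' comparisons (two Australian collections, AU2007 and AU2008, and one
#' North American, NA), together with each TE's family, chromosome arm
#' and putatively adaptive/neutral family classification, and the
#' FDR-adjusted values as printed in the source table
#' (`fdr_printed`/`fdr_bold`) for cross-checking.
#'
#' @return A long data frame (84 rows): `te_id`, `family`, `chrom_arm`,
#'   `cytoband`, `te_class`, `pair_id`, `freq_north`, `freq_south`,
#'   `p_raw`, `fdr_printed`, `fdr_bold`.
#' @export
te_differentiation_fixture <- function() {
  path <- system.file("extdata", "table1_differentiation.tsv",
                      package = "teclines", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = character(0))
  df$fdr_bold <- as.logical(df$fdr_bold)
  df
}

#' Write a data frame as TSV
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
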