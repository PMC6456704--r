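#' Reported MHC epistatic SNP pairs (published summary statistics)
#'
#' The nine independent epistatic SNP pairs within the MHC region reported
#' by a large ulcerative colitis Immunochip analysis (discovery and
#' replication cohorts of roughly 7,100 cases each), as printed: pair
#' identifiers, positions, nearby genes, LD, per-SNP single-marker P-values,
#' and the unconditional and background-conditional 4-df interaction
#' P-values per cohort. These are published summary statistics bundled for
#' threshold-logic checks; the underlying individual-level data are access
#' controlled and are not part of this package.
#'
#' @return data.frame with one row per pair.
#' @export
reported_pairs <- function() {
  path <- system.file("extdata", "uc_mhc_pairs.tsv", package = "episcan",
                      mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Qualitative significance calls on the reported pairs
#'
#' Applies the pipeline's fixed thresholds ([call_significance()] on the
#' discovery conditional P; replication at the conditional P < `repl_p`
#' rule) to the printed values of [reported_pairs()].
#'
#' @param config a [run_config()] supplying the thresholds.
#' @return list with `n_pairs`, `n_genome_wide`, `n_chip_wide`,
#'   `n_replicated`, and the flagged per-pair data.frame `calls`.
#' @export
reported_pair_calls <- function(config = run_config()) {
  tab <- reported_pairs()
  res <- data.frame(snp1 = tab$snp1, snp2 = tab$snp2,
                    p_cond = tab$p_cond_disc, stringsAsFactors = FALSE)
  res <- call_significance(res, genome_wide = config$genome_p,
                           chip_wide = config$chip_p)
  res$replicated <- tab$p_cond_repl < config$repl_p
  list(n_pairs = nrow(res),
       n_genome_wide = sum(res$genome_wide),
       n_chip_wide = sum(res$chip_wide),
       n_replicated = sum(res$replicated),
       calls = res)
}
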