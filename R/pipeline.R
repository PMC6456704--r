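# End-to-end orchestration: QC -> single-SNP scan -> independence screen ->
# approximate pair screen -> exact and conditional interaction tests ->
# significance calls -> replication, with audit logging of every filter.

#' Pipeline run configuration
#'
#' Bundles every fixed threshold of the protocol with the file paths and
#' seed of one run. Defaults are the protocol's published constants.
#'
#' @param entry_p marginal P for entering the joint background model
#'   (`5e-8`).
#' @param keep_p joint P for staying in the background (`0.05`).
#' @param screen_p approximate interaction P retention threshold (`1e-10`).
#' @param screen_r2 LD exclusion threshold for screened pairs (`0.2`).
#' @param genome_p genome-wide pair significance (`1e-13`).
#' @param chip_p chip-wide 5 percent pair significance (`1.1e-8`).
#' @param repl_p replication threshold (`0.05`).
#' @param hwe_p,maf marker QC thresholds (`1e-6`, `1e-5`).
#' @param mhc_chrom,mhc_start,mhc_end the MHC annotation window (chromosome
#'   6, 28.7-34.0 Mb, closed interval on 1-based positions).
#' @param seed integer seed.
#' @param paths named list of file paths (free-form, carried through).
#' @return validated list of class `run_config`.
#' @export
run_config <- function(entry_p = 5e-8, keep_p = 0.05, screen_p = 1e-10,
                       screen_r2 = 0.2, genome_p = 1e-13, chip_p = 1.1e-8,
                       repl_p = 0.05, hwe_p = 1e-6, maf = 1e-5,
                       mhc_chrom = 6, mhc_start = 28.7e6, mhc_end = 34.0e6,
                       seed = 1, paths = list()) {
  vals <- c(entry_p, keep_p, screen_p, genome_p, chip_p, repl_p, hwe_p, maf)
  stopifnot(all(vals > 0), screen_r2 >= 0, genome_p <= chip_p,
            mhc_start <= mhc_end)
  structure(list(entry_p = entry_p, keep_p = keep_p, screen_p = screen_p,
                 screen_r2 = screen_r2, genome_p = genome_p,
                 chip_p = chip_p, repl_p = repl_p, hwe_p = hwe_p, maf = maf,
                 mhc_chrom = mhc_chrom, mhc_start = mhc_start,
                 mhc_end = mhc_end, seed = as.integer(seed), paths = paths),
            class = "run_config")
}

#' Parse a flat key-value run configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Numeric threshold keys override the [run_config()] defaults; any other
#' key is collected into `paths`.
#'
#' @param path configuration file.
#' @return a [run_config()].
#' @export
parse_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*[=:]\\s*(.*)$", ln))[[1]]
    if (length(m) != 3) stop("malformed config line: ", ln)
    kv[[m[2]]] <- trimws(m[3])
  }
  num_keys <- c("entry_p", "keep_p", "screen_p", "screen_r2", "genome_p",
                "chip_p", "repl_p", "hwe_p", "maf", "mhc_chrom",
                "mhc_start", "mhc_end", "seed")
  args <- list()
  paths <- list()
  for (k in names(kv)) {
    if (k %in% num_keys) args[[k]] <- as.numeric(kv[[k]])
    else paths[[k]] <- kv[[k]]
  }
  args$paths <- paths
  do.call(run_config, args)
}

.in_mhc <- function(markers, ids, config) {
  i <- match(ids, markers$id)
  markers$chrom[i] == config$mhc_chrom &
    markers$pos[i] >= config$mhc_start & markers$pos[i] <= config$mhc_end
}

# optional BED-like annotation: chrom, start, end, name (0-based half-open
# intervals, the usual BED convention); returns "" where no interval
# contains the position
annotate_genes <- function(markers, ids, annotation = NULL) {
  if (is.null(annotation)) return(rep("", length(ids)))
  ann <- read.table(annotation, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "name"))
  i <- match(ids, markers$id)
  vapply(seq_along(ids), function(k) {
    hit <- which(ann$chrom == markers$chrom[i[k]] &
                 ann$start < markers$pos[i[k]] &
                 ann$end >= markers$pos[i[k]])
    if (length(hit)) ann$name[hit[1]] else ""
  }, character(1))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the discovery protocol on one cohort
#'
#' Executes, in order: marker QC, single-SNP scan, independence screen
#' (additive background), exhaustive approximate pair screen, exact and
#' conditional interaction tests, and significance calls; logs the counts
#' after every stage and annotates significant pairs with an in-MHC flag.
#'
#' @param genotypes,cohort the discovery cohort.
#' @param config a [run_config()].
#' @param out_dir optional output directory; when given, every stage table
#'   is written (QC report, scan TSV, background TSV, candidates TSV,
#'   results TSV, run log JSON).
#' @return list with `qc`, `scan`, `background`, `candidates`, `results`
#'   (with significance flags and `in_mhc`), `genotypes` (QC-passed), and
#'   `log` (stage counts).
#' @export
run_discovery <- function(genotypes, cohort, config = run_config(),
                          out_dir = NULL) {
  check_aligned(genotypes, cohort)
  qc <- .stage("qc", qc_filter(genotypes, hwe_threshold = config$hwe_p,
                               maf_threshold = config$maf))
  geno <- qc$genotypes
  scan <- .stage("scan", single_snp_scan(geno, cohort))
  background <- .stage("independence_screen",
                       independence_screen(scan, geno, cohort,
                                           entry_threshold = config$entry_p,
                                           keep_threshold = config$keep_p))
  candidates <- .stage("pair_screen",
                       screen_all_pairs(geno, cohort,
                                        p_threshold = config$screen_p,
                                        r2_threshold = config$screen_r2))
  results <- .stage("exact_epistasis", {
    r <- epistasis_tests(geno, cohort, candidates, background)
    r$r2 <- candidates$r2[match(paste(r$snp1, r$snp2),
                                paste(candidates$snp1, candidates$snp2))]
    call_significance(r, genome_wide = config$genome_p,
                      chip_wide = config$chip_p)
  })
  if (nrow(results)) {
    results$in_mhc <- .in_mhc(geno$markers, results$snp1, config) &
                      .in_mhc(geno$markers, results$snp2, config)
  } else results$in_mhc <- logical(0)

  log <- list(
    n_markers_input = ncol(genotypes$dosage),
    n_markers_qc = ncol(geno$dosage),
    n_genomewide_snps = sum(!is.na(scan$p) & scan$p < config$entry_p),
    n_independent_snps = nrow(background),
    n_pairs_tested = attr(candidates, "n_pairs_tested"),
    n_candidate_pairs = nrow(candidates),
    n_pairs_pass_p = attr(candidates, "n_pass_p"),
    n_pairs_excluded_r2 = attr(candidates, "n_excluded_r2"),
    n_genome_wide_pairs = sum(results$genome_wide),
    n_chip_wide_pairs = sum(results$chip_wide))

  out <- list(qc = qc$report, scan = scan, background = background,
              candidates = candidates, results = results,
              genotypes = geno, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
    w(qc$report, "qc_report.tsv")
    w(scan, "scan.tsv")
    w(as.data.frame(background), "background.tsv")
    w(as.data.frame(candidates), "candidates.tsv")
    write_results(results, file.path(out_dir, "results.tsv"))
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Test discovery-significant pairs in a replication cohort
#'
#' Reruns QC, the single-SNP scan and the independence screen in the
#' replication cohort (its own additive background, unless
#' `reuse_background = TRUE`), then the conditional interaction test for
#' every chip-wide-significant discovery pair, and assembles the combined
#' per-pair report: positions, optional gene annotations, LD, per-cohort
#' single-SNP P, unconditional P and conditional P, plus the replicated
#' flag.
#'
#' @param discovery result of [run_discovery()].
#' @param genotypes,cohort the replication cohort (disjoint samples).
#' @param config a [run_config()].
#' @param reuse_background condition replication tests on the discovery
#'   background instead of recomputing it.
#' @param annotation optional BED-like file (chrom, start, end, name) for
#'   the gene columns.
#' @param out_dir optional output directory for the combined report.
#' @return list with `report` (combined data.frame), `replication`
#'   (raw replication test rows), `background` (replication background),
#'   and `log`.
#' @export
run_replication <- function(discovery, genotypes, cohort,
                            config = run_config(), reuse_background = FALSE,
                            annotation = NULL, out_dir = NULL) {
  check_aligned(genotypes, cohort)
  if (any(genotypes$samples %in% discovery$genotypes$samples))
    stop("replication cohort shares samples with the discovery cohort")
  sig <- discovery$results[discovery$results$chip_wide, , drop = FALSE]
  qc <- .stage("qc", qc_filter(genotypes, hwe_threshold = config$hwe_p,
                               maf_threshold = config$maf))
  geno <- qc$genotypes
  scan <- .stage("scan", single_snp_scan(geno, cohort))
  background <- if (reuse_background) discovery$background
  else .stage("independence_screen",
              independence_screen(scan, geno, cohort,
                                  entry_threshold = config$entry_p,
                                  keep_threshold = config$keep_p))
  repl <- .stage("replication", {
    testable <- sig$snp1 %in% geno$markers$id & sig$snp2 %in% geno$markers$id
    r <- replicate_pairs(sig[testable, , drop = FALSE], geno, cohort,
                         background, alpha = config$repl_p)
    if (any(!testable)) {
      miss <- sig[!testable, c("snp1", "snp2"), drop = FALSE]
      extra <- data.frame(miss, stat_int = NA, df_int = NA, p_int = NA,
                          log10_p_int = NA, stat_cond = NA, df_cond = NA,
                          p_cond = NA, log10_p_cond = NA, n = 0,
                          converged = FALSE, nonstandard_df = FALSE,
                          cohort = "replication",
                          note = "untestable: removed by replication QC",
                          replicated = FALSE)
      r <- rbind(r, extra)
    }
    r
  })

  mk <- discovery$genotypes$markers
  scan_p <- function(tab, ids) tab$p[match(ids, tab$id)]
  i_rep <- match(paste(sig$snp1, sig$snp2), paste(repl$snp1, repl$snp2))
  report <- data.frame(
    snp1 = sig$snp1,
    pos1 = mk$pos[match(sig$snp1, mk$id)],
    gene1 = annotate_genes(mk, sig$snp1, annotation),
    snp2 = sig$snp2,
    pos2 = mk$pos[match(sig$snp2, mk$id)],
    gene2 = annotate_genes(mk, sig$snp2, annotation),
    ld = sig$r2,
    p_snp1_disc = scan_p(discovery$scan, sig$snp1),
    p_snp2_disc = scan_p(discovery$scan, sig$snp2),
    p_int_disc = sig$p_int,
    p_cond_disc = sig$p_cond,
    p_snp1_repl = scan_p(scan, sig$snp1),
    p_snp2_repl = scan_p(scan, sig$snp2),
    p_int_repl = repl$p_int[i_rep],
    p_cond = repl$p_cond[i_rep],
    replicated = repl$replicated[i_rep],
    in_mhc = sig$in_mhc,
    stringsAsFactors = FALSE)
  log <- list(n_significant_pairs = nrow(sig),
              n_replicated = sum(report$replicated, na.rm = TRUE),
              n_repl_background = nrow(background))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(report, file.path(out_dir, "replication_report.tsv"))
    jsonlite::write_json(log, file.path(out_dir, "replication_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(report = report, replication = repl, background = background,
       log = log)
}
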