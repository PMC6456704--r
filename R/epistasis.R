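# Stage 2: exact covariate-adjusted 4-df interaction likelihood-ratio test,
# conditional analysis on the additive background, significance calls and
# replication.

# genotype-factor indicator columns for one SNP: two indicators against the
# homozygous-major reference class, collapsing classes absent from the data.
.factor_columns <- function(g, label) {
  p_alt <- mean(g) / 2
  ref <- if (p_alt <= 0.5) 0L else 2L
  classes <- setdiff(sort(unique(g)), ref)
  cols <- lapply(classes, function(cl) as.numeric(g == cl))
  if (length(cols)) {
    X <- do.call(cbind, cols)
    colnames(X) <- paste0(label, "_g", classes)
  } else X <- matrix(numeric(0), nrow = length(g), ncol = 0)
  X
}

#' Exact interaction likelihood-ratio test for one SNP pair
#'
#' Fits two nested logistic models on the identical complete-case subset:
#' the full model has intercept + cohort covariates + any extra background
#' dosages + two genotype-factor indicators per pair member (reference =
#' homozygous major allele in the tested cohort) + all pairwise products of
#' the indicators; the reduced model omits the products. The statistic is
#' `2 * (ll_full - ll_reduced)`, referred to a chi-squared with 4 df (fewer
#' when a genotype class is absent and its indicator collapses; such tests
#' are flagged `nonstandard_df`).
#'
#' With `extra_covariates` empty this is the unconditional test; passing the
#' additive background identifiers gives the conditional test. Background
#' markers that are themselves pair members are excluded from the extra
#' covariates (their main effects are already in the model via the factor
#' coding).
#'
#' @param genotypes a [genotype_matrix()].
#' @param cohort a [cohort_table()] aligned to `genotypes`.
#' @param pair length-2 vector of marker identifiers (or indices).
#' @param extra_covariates character vector of background marker identifiers
#'   entered as additive dosages.
#' @param cohort_label label stored in the result row.
#' @return one-row data.frame: `snp1`, `snp2`, `stat`, `df`, `p`,
#'   `log10_p`, `n`, `converged`, `separation`, `nonstandard_df`, `cohort`.
#' @export
interaction_lrt <- function(genotypes, cohort, pair,
                            extra_covariates = character(0),
                            cohort_label = "discovery") {
  check_aligned(genotypes, cohort)
  ids <- genotypes$markers$id
  if (is.numeric(pair)) pair <- ids[pair]
  if (length(pair) != 2 || anyNA(match(pair, ids)) || pair[1] == pair[2])
    stop("pair must name two distinct markers")
  extra <- setdiff(as.character(extra_covariates), pair)
  if (anyNA(match(extra, ids)))
    stop("unknown background marker in extra_covariates")

  g1 <- genotypes$dosage[, match(pair[1], ids)]
  g2 <- genotypes$dosage[, match(pair[2], ids)]
  E <- genotypes$dosage[, match(extra, ids), drop = FALSE]
  covs <- cohort$covariates
  cc <- !is.na(g1) & !is.na(g2)
  if (ncol(covs)) cc <- cc & complete.cases(covs)
  if (ncol(E)) cc <- cc & complete.cases(E)

  fail <- function(msg) {
    data.frame(snp1 = pair[1], snp2 = pair[2], stat = NA_real_,
               df = NA_integer_, p = NA_real_, log10_p = NA_real_,
               n = sum(cc), converged = FALSE, separation = FALSE,
               nonstandard_df = FALSE, cohort = cohort_label,
               note = msg, stringsAsFactors = FALSE)
  }
  if (sum(cc) == 0L) return(fail("no complete cases"))
  y <- cohort$status[cc]
  if (all(y == 0L) || all(y == 1L)) return(fail("degenerate outcome"))
  F1 <- .factor_columns(g1[cc], "s1")
  F2 <- .factor_columns(g2[cc], "s2")
  if (ncol(F1) == 0L || ncol(F2) == 0L)
    return(fail("pair member monomorphic on complete cases"))

  inter <- matrix(numeric(0), nrow = sum(cc), ncol = 0)
  for (a in seq_len(ncol(F1)))
    for (b in seq_len(ncol(F2))) {
      inter <- cbind(inter, F1[, a] * F2[, b])
      colnames(inter)[ncol(inter)] <-
        paste0(colnames(F1)[a], "x", colnames(F2)[b])
    }
  df <- ncol(inter)

  base <- cbind(`(Intercept)` = 1, covs[cc, , drop = FALSE])
  if (ncol(E)) {
    Ecc <- E[cc, , drop = FALSE]
    colnames(Ecc) <- extra
    base <- cbind(base, Ecc)
  }
  X_red <- cbind(base, F1, F2)
  X_full <- cbind(X_red, inter)
  fit_red <- tryCatch(logistic_fit(X_red, y), error = function(e) NULL)
  fit_full <- tryCatch(logistic_fit(X_full, y), error = function(e) NULL)
  if (is.null(fit_red) || is.null(fit_full)) return(fail("fit failed"))
  # dropped interaction columns reduce the df of the test
  df_eff <- df - sum(fit_full$dropped %in% colnames(inter))
  if (df_eff <= 0) return(fail("no estimable interaction contrast"))
  stat <- max(0, 2 * (fit_full$loglik - fit_red$loglik))
  log10_p <- pchisq(stat, df = df_eff, lower.tail = FALSE, log.p = TRUE) / log(10)
  data.frame(snp1 = pair[1], snp2 = pair[2], stat = stat, df = df_eff,
             p = 10^log10_p, log10_p = log10_p, n = sum(cc),
             converged = fit_red$converged && fit_full$converged,
             separation = fit_red$separation || fit_full$separation,
             nonstandard_df = df_eff != 4L, cohort = cohort_label,
             note = "", stringsAsFactors = FALSE)
}

#' Unconditional and conditional interaction tests for screened candidates
#'
#' Runs [interaction_lrt()] twice per candidate pair: once with no background
#' (the unconditional, covariate-adjusted test) and once conditioning on the
#' additive background.
#'
#' @param genotypes,cohort the analysis cohort.
#' @param candidates data.frame with columns `snp1`, `snp2` (e.g. from
#'   [screen_all_pairs()]).
#' @param background an `additive_background` (or character vector of marker
#'   ids); empty means the conditional test equals the unconditional one.
#' @param cohort_label label stored in the result rows.
#' @return data.frame with one row per pair: `snp1`, `snp2`, `stat_int`,
#'   `df_int`, `p_int`, `stat_cond`, `df_cond`, `p_cond`, `log10_p_cond`,
#'   `n`, `converged`, `nonstandard_df`, `cohort`.
#' @export
epistasis_tests <- function(genotypes, cohort, candidates,
                            background = character(0),
                            cohort_label = "discovery") {
  bg <- if (is.data.frame(background)) background$id else as.character(background)
  if (nrow(candidates) == 0L)
    return(data.frame(snp1 = character(0), snp2 = character(0),
                      stat_int = numeric(0), df_int = integer(0),
                      p_int = numeric(0), log10_p_int = numeric(0),
                      stat_cond = numeric(0), df_cond = integer(0),
                      p_cond = numeric(0), log10_p_cond = numeric(0),
                      n = integer(0), converged = logical(0),
                      nonstandard_df = logical(0), cohort = character(0),
                      note = character(0), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(candidates)), function(k) {
    pair <- c(candidates$snp1[k], candidates$snp2[k])
    un <- interaction_lrt(genotypes, cohort, pair,
                          cohort_label = cohort_label)
    co <- if (length(bg))
      interaction_lrt(genotypes, cohort, pair, extra_covariates = bg,
                      cohort_label = cohort_label)
    else un
    data.frame(snp1 = pair[1], snp2 = pair[2],
               stat_int = un$stat, df_int = un$df, p_int = un$p,
               log10_p_int = un$log10_p,
               stat_cond = co$stat, df_cond = co$df, p_cond = co$p,
               log10_p_cond = co$log10_p,
               n = un$n, converged = un$converged && co$converged,
               nonstandard_df = un$nonstandard_df || co$nonstandard_df,
               cohort = cohort_label,
               note = paste0(un$note,
                             if (nzchar(co$note) && !identical(un$note, co$note))
                               paste0(";", co$note) else ""),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Iterative proportional fitting of the homogeneous-association model
#'
#' Fits the log-linear model with all three two-way margins (g1 x g2,
#' g1 x status, g2 x status) and no three-way term to a 2x3x3 table —
#' the covariate-free reduced model of the 4-df interaction LRT, used as an
#' independent oracle for the regression formulation. Structural zeros
#' (cells whose two-way margins vanish) stay zero.
#'
#' @param table 2x3x3 array indexed `[status + 1, g1 + 1, g2 + 1]`.
#' @param tol convergence tolerance on the maximum absolute margin
#'   discrepancy (default `1e-9`).
#' @param max_iter sweep cap.
#' @return list with `fitted` (expected counts), `loglik` (multinomial, with
#'   the `0 log 0 = 0` convention), `iterations`, `converged`.
#' @export
ipf_homogeneous_fit <- function(table, tol = 1e-9, max_iter = 10000L) {
  obs <- array(as.numeric(table), dim = c(2, 3, 3))
  N <- sum(obs)
  if (N <= 0) stop("table total must be positive")
  m12 <- apply(obs, c(2, 3), sum)   # g1 x g2
  m1y <- apply(obs, c(1, 2), sum)   # y  x g1
  m2y <- apply(obs, c(1, 3), sum)   # y  x g2
  fit <- array(1, dim = c(2, 3, 3))
  for (y in 1:2) for (a in 1:3) for (b in 1:3)
    if (m12[a, b] == 0 || m1y[y, a] == 0 || m2y[y, b] == 0)
      fit[y, a, b] <- 0
  ratio <- function(num, den) ifelse(den > 0, num / den, 0)
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    f12 <- apply(fit, c(2, 3), sum)
    for (a in 1:3) for (b in 1:3)
      fit[, a, b] <- fit[, a, b] * ratio(m12[a, b], f12[a, b])
    f1y <- apply(fit, c(1, 2), sum)
    for (y in 1:2) for (a in 1:3)
      fit[y, a, ] <- fit[y, a, ] * ratio(m1y[y, a], f1y[y, a])
    f2y <- apply(fit, c(1, 3), sum)
    for (y in 1:2) for (b in 1:3)
      fit[y, , b] <- fit[y, , b] * ratio(m2y[y, b], f2y[y, b])
    disc <- max(abs(apply(fit, c(2, 3), sum) - m12),
                abs(apply(fit, c(1, 2), sum) - m1y),
                abs(apply(fit, c(1, 3), sum) - m2y))
    if (disc < tol) { converged <- TRUE; break }
  }
  pos <- obs > 0
  loglik <- sum(obs[pos] * log(fit[pos] / N))
  list(fitted = fit, loglik = loglik, iterations = it, converged = converged)
}

#' Apply the fixed significance thresholds to conditional interaction P-values
#'
#' @param results data.frame with `p_cond` (e.g. from [epistasis_tests()]).
#' @param genome_wide genome-wide threshold (default `1e-13`).
#' @param chip_wide chip-wide 5 percent threshold (default `1.1e-8`).
#' @return `results` with logical columns `genome_wide` and `chip_wide`
#'   added (genome-wide implies chip-wide).
#' @export
call_significance <- function(results, genome_wide = 1e-13,
                              chip_wide = 1.1e-8) {
  stopifnot(genome_wide <= chip_wide)
  results$genome_wide <- !is.na(results$p_cond) & results$p_cond < genome_wide
  results$chip_wide <- !is.na(results$p_cond) & results$p_cond < chip_wide
  results
}

#' Replication of significant pairs in an independent cohort
#'
#' Reruns the conditional interaction test in the replication cohort with its
#' own additive background; a pair is directly replicated when its
#' conditional P stays below `alpha`. Pairs untestable in the replication
#' cohort (e.g. a genotype class absent) are reported not-replicated with a
#' diagnostic note.
#'
#' @param pairs data.frame with `snp1`, `snp2`.
#' @param genotypes,cohort the replication cohort.
#' @param background the replication-cohort additive background (default
#'   behaviour; pass the discovery background to reuse it instead).
#' @param alpha replication threshold (default `0.05`).
#' @return data.frame: per pair, the replication test columns plus
#'   `replicated`.
#' @export
replicate_pairs <- function(pairs, genotypes, cohort,
                            background = character(0), alpha = 0.05) {
  res <- epistasis_tests(genotypes, cohort, pairs, background,
                         cohort_label = "replication")
  res$replicated <- !is.na(res$p_cond) & res$p_cond < alpha
  res
}
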