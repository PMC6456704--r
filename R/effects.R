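# Orthogonal decomposition of pair effects and observed-scale variance
# accounting. The coding is the frequency-dependent ("statistical") NOIA
# style: per SNP, an additive score a(g) = g - 2p and a dominance score d(g)
# obtained by orthogonalizing the heterozygote indicator against {1, a}
# under Hardy-Weinberg genotype weights, so that under exact HWE at allele
# frequency p the scores have zero mean and zero cross-moment.

#' Orthogonal additive/dominance genotype scores for one SNP
#'
#' @param p allele frequency of the counted (allele2) allele, in (0, 1).
#' @return list with `a` and `d` (numeric length-3 score vectors for
#'   dosages 0, 1, 2) and `w` (the HWE genotype weights used).
#' @export
orthogonal_coding <- function(p) {
  if (!is.finite(p) || p <= 0 || p >= 1)
    stop("allele frequency must be strictly inside (0, 1)")
  q <- 1 - p
  w <- c(q^2, 2 * p * q, p^2)
  a <- c(0, 1, 2) - 2 * p
  # heterozygote indicator orthogonalized against {1, a} under weights w:
  # E[h] = 2pq, E[h a] = 2pq(1-2p), E[a^2] = 2pq
  h <- c(0, 1, 0)
  d <- h - 2 * p * q - (1 - 2 * p) * a
  list(a = a, d = d, w = w)
}

# design columns for the 8 genetic terms of one pair, on given dosages
.pair_effect_columns <- function(g1, g2, p1, p2, prefix = "") {
  c1 <- orthogonal_coding(p1)
  c2 <- orthogonal_coding(p2)
  a1 <- c1$a[g1 + 1L]; d1 <- c1$d[g1 + 1L]
  a2 <- c2$a[g2 + 1L]; d2 <- c2$d[g2 + 1L]
  X <- cbind(A1 = a1, A2 = a2, D1 = d1, D2 = d2,
             A1xA2 = a1 * a2, A1xD2 = a1 * d2,
             D1xA2 = d1 * a2, D1xD2 = d1 * d2)
  if (nzchar(prefix)) colnames(X) <- paste0(prefix, colnames(X))
  X
}

#' Orthogonal effect decomposition of one SNP pair
#'
#' Logistic regression of case status on the cohort covariates plus the 8
#' orthogonal genetic terms (A1, A2, D1, D2, A1xA2, A1xD2, D1xA2, D1xD2)
#' built from each SNP's sample allele frequency in the analysed cohort.
#'
#' @param genotypes,cohort the analysis cohort.
#' @param pair length-2 vector of marker identifiers (or indices).
#' @param cohort_label label stored with the coefficients.
#' @return data.frame with one row per genetic term: `term`, `beta`
#'   (log-odds), `se`, `cohort`, plus attributes `converged` and `n`.
#' @export
decompose_pair <- function(genotypes, cohort, pair,
                           cohort_label = "discovery") {
  check_aligned(genotypes, cohort)
  ids <- genotypes$markers$id
  if (is.numeric(pair)) pair <- ids[pair]
  g1 <- genotypes$dosage[, match(pair[1], ids)]
  g2 <- genotypes$dosage[, match(pair[2], ids)]
  covs <- cohort$covariates
  cc <- !is.na(g1) & !is.na(g2)
  if (ncol(covs)) cc <- cc & complete.cases(covs)
  p1 <- mean(g1[cc]) / 2
  p2 <- mean(g2[cc]) / 2
  G <- .pair_effect_columns(g1[cc], g2[cc], p1, p2)
  X <- cbind(`(Intercept)` = 1, covs[cc, , drop = FALSE], G)
  fit <- logistic_fit(X, cohort$status[cc])
  terms <- colnames(G)
  out <- data.frame(term = terms,
                    beta = unname(fit$coefficients[terms]),
                    se = unname(fit$se[terms]),
                    cohort = cohort_label, stringsAsFactors = FALSE)
  attr(out, "converged") <- fit$converged
  attr(out, "n") <- fit$n
  attr(out, "pair") <- pair
  out
}

#' Decomposition heatmap matrix for a set of pairs
#'
#' @param genotypes,cohort the analysis cohort.
#' @param pairs data.frame with `snp1`, `snp2`.
#' @param cohort_label label for the rows.
#' @return numeric matrix, one row per pair (named `snp1:snp2`), 8 columns
#'   (A1, A2, D1, D2, A1xA2, A1xD2, D1xA2, D1xD2) of log-odds coefficients.
#' @export
decomposition_matrix <- function(genotypes, cohort, pairs,
                                 cohort_label = "discovery") {
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    d <- decompose_pair(genotypes, cohort,
                        c(pairs$snp1[k], pairs$snp2[k]), cohort_label)
    setNames(d$beta, d$term)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- paste0(pairs$snp1, ":", pairs$snp2)
  out
}

# observed-scale R^2: squared Pearson correlation of status with fitted
# probabilities
.obs_r2 <- function(y, fitted) {
  if (sd(fitted) == 0) return(0)
  cor(y, fitted)^2
}

#' Observed-scale variance explained by epistatic pairs beyond the background
#'
#' Fits three nested logistic models on the common complete-case subset:
#' M0 = covariates + additive background dosages; M1 = M0 + the orthogonal
#' main-effect terms (A, D) of every SNP in the pairs; M2 = M1 + the four
#' orthogonal interaction terms per pair. Observed-scale R-squared is the
#' squared Pearson correlation between status and fitted probabilities.
#'
#' @param genotypes,cohort the analysis cohort.
#' @param background an `additive_background` or character vector of marker
#'   ids (additive dosages in every model).
#' @param pairs data.frame with `snp1`, `snp2`; may be empty.
#' @return list with percentages `joint` (R2 of M2), `background` (R2 of
#'   M0), `pairs_beyond_background` (M2 - M0), `interaction_only`
#'   (M2 - M1), `per_pair_average` ((M2 - M0) / n pairs), and `n` (complete
#'   cases). All on the 0-100 scale.
#' @export
variance_explained <- function(genotypes, cohort, background, pairs) {
  check_aligned(genotypes, cohort)
  ids <- genotypes$markers$id
  bg <- if (is.data.frame(background)) background$id else as.character(background)
  covs <- cohort$covariates
  pair_snps <- unique(c(pairs$snp1, pairs$snp2))
  B <- genotypes$dosage[, match(bg, ids), drop = FALSE]
  P <- genotypes$dosage[, match(pair_snps, ids), drop = FALSE]
  cc <- rep(TRUE, length(cohort$status))
  if (ncol(covs)) cc <- cc & complete.cases(covs)
  if (ncol(B)) cc <- cc & complete.cases(B)
  if (ncol(P)) cc <- cc & complete.cases(P)
  y <- cohort$status[cc]

  X0 <- cbind(`(Intercept)` = 1, covs[cc, , drop = FALSE])
  if (length(bg)) {
    Bcc <- B[cc, , drop = FALSE]; colnames(Bcc) <- bg
    X0 <- cbind(X0, Bcc)
  }
  if (nrow(pairs) == 0L) {
    r2_0 <- .obs_r2(y, logistic_fit(X0, y)$fitted)
    return(list(joint = 100 * r2_0, background = 100 * r2_0,
                pairs_beyond_background = 0, interaction_only = 0,
                per_pair_average = 0, n = length(y)))
  }

  freqs <- setNames(colMeans(P[cc, , drop = FALSE]) / 2, pair_snps)
  main_cols <- list(); int_cols <- list()
  for (s in pair_snps) {
    cod <- orthogonal_coding(freqs[[s]])
    g <- P[cc, s]
    main_cols[[paste0(s, "_A")]] <- cod$a[g + 1L]
    main_cols[[paste0(s, "_D")]] <- cod$d[g + 1L]
  }
  for (k in seq_len(nrow(pairs))) {
    s1 <- pairs$snp1[k]; s2 <- pairs$snp2[k]
    a1 <- main_cols[[paste0(s1, "_A")]]; d1 <- main_cols[[paste0(s1, "_D")]]
    a2 <- main_cols[[paste0(s2, "_A")]]; d2 <- main_cols[[paste0(s2, "_D")]]
    pre <- paste0("p", k, "_")
    int_cols[[paste0(pre, "AxA")]] <- a1 * a2
    int_cols[[paste0(pre, "AxD")]] <- a1 * d2
    int_cols[[paste0(pre, "DxA")]] <- d1 * a2
    int_cols[[paste0(pre, "DxD")]] <- d1 * d2
  }
  M <- do.call(cbind, main_cols)
  I <- do.call(cbind, int_cols)
  X1 <- cbind(X0, M)
  X2 <- cbind(X1, I)
  r2_0 <- .obs_r2(y, logistic_fit(X0, y)$fitted)
  r2_1 <- .obs_r2(y, logistic_fit(X1, y)$fitted)
  r2_2 <- .obs_r2(y, logistic_fit(X2, y)$fitted)
  tol <- 1e-10
  if (r2_1 < r2_0 - max(tol, 1e-6 * r2_0) || r2_2 < r2_1 - max(tol, 1e-6 * r2_1))
    stop(sprintf(
      "non-monotone observed-scale R2 along nested models: %.3e, %.3e, %.3e",
      r2_0, r2_1, r2_2))
  list(joint = 100 * r2_2,
       background = 100 * r2_0,
       pairs_beyond_background = 100 * (r2_2 - r2_0),
       interaction_only = 100 * (r2_2 - r2_1),
       per_pair_average = 100 * (r2_2 - r2_0) / nrow(pairs),
       n = length(y))
}
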