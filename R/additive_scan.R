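# Single-SNP association scan and the independence screen that defines the
# additive background: the set of mutually independent single-SNP signals
# (joint-model P < 0.05 among genome-wide-significant SNPs) that conditional
# interaction tests adjust for.

#' Covariate-adjusted single-SNP logistic scan
#'
#' For every marker, fits a logistic regression of case status on the
#' additive allele2 dosage plus the cohort covariates, on complete cases for
#' that marker, and reports the Wald P of the dosage coefficient. Markers
#' with zero dosage variance on their complete cases are flagged
#' `not_testable`; non-converged or separated fits are flagged, never
#' silently dropped.
#'
#' @param genotypes a QC-passed [genotype_matrix()].
#' @param cohort a [cohort_table()] aligned to `genotypes`.
#' @return data.frame with `id`, `beta` (log-odds per allele), `se`, `p`,
#'   `n` (complete cases), `converged`, `separation`, `not_testable`.
#' @export
single_snp_scan <- function(genotypes, cohort) {
  check_aligned(genotypes, cohort)
  covs <- cohort$covariates
  cov_ok <- if (ncol(covs)) complete.cases(covs) else rep(TRUE, length(cohort$status))
  m <- ncol(genotypes$dosage)
  out <- data.frame(id = genotypes$markers$id,
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    n = NA_integer_, converged = NA, separation = NA,
                    not_testable = FALSE, stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    g <- genotypes$dosage[, j]
    cc <- cov_ok & !is.na(g)
    out$n[j] <- sum(cc)
    gj <- g[cc]
    if (sum(cc) == 0L || stats::var(gj) == 0) {
      out$not_testable[j] <- TRUE
      next
    }
    X <- cbind(`(Intercept)` = 1,
               covs[cc, , drop = FALSE],
               dosage = gj)
    fit <- tryCatch(logistic_fit(X, cohort$status[cc]),
                    error = function(e) NULL)
    if (is.null(fit)) { out$not_testable[j] <- TRUE; next }
    out$beta[j] <- fit$coefficients["dosage"]
    out$se[j] <- fit$se["dosage"]
    out$p[j] <- wald_p(fit, "dosage")
    out$converged[j] <- fit$converged
    out$separation[j] <- fit$separation
  }
  out
}

# incremental rank check: does adding column v to the span of basis Q add a
# new direction?
.adds_rank <- function(Q, v, tol = 1e-8) {
  r <- v - Q %*% crossprod(Q, v)
  sqrt(sum(r^2)) > tol * max(1, sqrt(sum(v^2)))
}

#' Independence screen: reduce marginal hits to an additive background
#'
#' Implements the pooled refit rule: (i) select markers with scan P below
#' `entry_threshold`; (ii) among these, drop duplicated / perfectly
#' correlated dosage columns deterministically, keeping the smaller scan P
#' (ties by identifier); (iii) fit one joint logistic model with all selected
#' dosages plus the cohort covariates, resolving any remaining rank
#' deficiency by greedy drops in ascending scan-P order (logged); (iv) retain
#' markers whose joint-model Wald P is below `keep_threshold`.
#'
#' @param hits data.frame from [single_snp_scan()] on the same cohort.
#' @param genotypes,cohort the scanned data.
#' @param entry_threshold marginal significance for entering the joint model
#'   (default `5e-8`, the consensus genome-wide threshold).
#' @param keep_threshold joint-model significance for staying in the
#'   background (default `0.05`).
#' @return data.frame of class `additive_background`: `id`, `joint_beta`,
#'   `joint_se`, `joint_p`, ordered by ascending scan P; attributes
#'   `n_entry`, `dropped_duplicate`, `dropped_rank`, `dropped_joint_p`.
#' @export
independence_screen <- function(hits, genotypes, cohort,
                                entry_threshold = 5e-8,
                                keep_threshold = 0.05) {
  check_aligned(genotypes, cohort)
  sel <- hits[!is.na(hits$p) & hits$p < entry_threshold, , drop = FALSE]
  sel <- sel[order(sel$p, sel$id), , drop = FALSE]
  n_entry <- nrow(sel)
  empty <- function(drop_dup = character(0), drop_rank = character(0)) {
    out <- data.frame(id = character(0), joint_beta = numeric(0),
                      joint_se = numeric(0), joint_p = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "n_entry") <- n_entry
    attr(out, "dropped_duplicate") <- drop_dup
    attr(out, "dropped_rank") <- drop_rank
    attr(out, "dropped_joint_p") <- character(0)
    class(out) <- c("additive_background", "data.frame")
    out
  }
  if (nrow(sel) == 0L) return(empty())

  D <- genotypes$dosage[, match(sel$id, genotypes$markers$id), drop = FALSE]
  covs <- cohort$covariates
  cov_ok <- if (ncol(covs)) complete.cases(covs) else rep(TRUE, nrow(D))

  # (ii) perfect-correlation de-duplication on complete pairs
  keep <- integer(0)
  drop_dup <- character(0)
  for (k in seq_len(ncol(D))) {
    dup <- FALSE
    for (k0 in keep) {
      ok <- !is.na(D[, k]) & !is.na(D[, k0])
      if (sum(ok) < 2) next
      if (sd(D[ok, k]) == 0 || sd(D[ok, k0]) == 0) next
      if (abs(cor(D[ok, k], D[ok, k0])) >= 1 - 1e-12) { dup <- TRUE; break }
    }
    if (dup) drop_dup <- c(drop_dup, sel$id[k]) else keep <- c(keep, k)
  }
  sel <- sel[keep, , drop = FALSE]
  D <- D[, keep, drop = FALSE]

  # (iii) joint fit on complete cases over all retained markers + covariates
  cc <- cov_ok & stats::complete.cases(D)
  if (sum(cc) == 0L) stop("no complete cases for the joint background fit")
  base <- cbind(`(Intercept)` = 1, covs[cc, , drop = FALSE])
  Qb <- qr.Q(qr(base))
  in_model <- logical(nrow(sel))
  Q <- Qb
  drop_rank <- character(0)
  for (k in seq_len(nrow(sel))) {
    v <- D[cc, k]
    if (sd(v) == 0) { drop_rank <- c(drop_rank, sel$id[k]); next }
    if (.adds_rank(Q, v)) {
      in_model[k] <- TRUE
      r <- v - Q %*% crossprod(Q, v)
      Q <- cbind(Q, r / sqrt(sum(r^2)))
    } else drop_rank <- c(drop_rank, sel$id[k])
  }
  sel <- sel[in_model, , drop = FALSE]
  D <- D[, in_model, drop = FALSE]
  if (nrow(sel) == 0L) return(empty(drop_dup, drop_rank))

  X <- cbind(base, D[cc, , drop = FALSE])
  colnames(X) <- c(colnames(base), sel$id)
  fit <- logistic_fit(X, cohort$status[cc])
  if (!fit$converged)
    stop("joint background fit did not converge (",
         fit$n_iter, " iterations, separation=", fit$separation, ")")
  jp <- vapply(sel$id, function(id) wald_p(fit, id), numeric(1))
  retain <- !is.na(jp) & jp < keep_threshold
  out <- data.frame(id = sel$id[retain],
                    joint_beta = unname(fit$coefficients[sel$id[retain]]),
                    joint_se = unname(fit$se[sel$id[retain]]),
                    joint_p = unname(jp[retain]), stringsAsFactors = FALSE)
  attr(out, "n_entry") <- n_entry
  attr(out, "dropped_duplicate") <- drop_dup
  attr(out, "dropped_rank") <- drop_rank
  attr(out, "dropped_joint_p") <- sel$id[!retain]
  class(out) <- c("additive_background", "data.frame")
  out
}
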