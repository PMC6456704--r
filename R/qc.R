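#' Hardy-Weinberg equilibrium exact test
#'
#' Two-sided exact test conditional on the observed allele counts: the P-value
#' sums the conditional probabilities of every heterozygote count no more
#' likely than the observed one (the Wigginton-style SNP-HWE test, matching
#' PLINK defaults). Probabilities are computed by the stable recurrence on the
#' heterozygote count, normalized at the end.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative; total > 0).
#' @return exact P-value in `[0, 1]`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all genotype counts are zero")
  n_rare <- 2 * min(n_AA, n_aa) + n_Aa   # copies of the rarer allele
  if (n_rare == 0) return(1)             # monomorphic: single possible table

  # possible heterozygote counts share the parity of the rare-allele count
  het_lo <- n_rare %% 2
  hets <- seq.int(het_lo, n_rare, by = 2L)
  # recurrence: P(h+2)/P(h) = 4*hom_r(h)*hom_c(h) / ((h+2)*(h+1))
  # with hom_r(h) = (n_rare - h)/2, hom_c(h) = n - (h + hom_r(h))
  logp <- numeric(length(hets))
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1L]
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    logp[k] <- logp[k - 1L] +
      log(4 * hom_r * hom_c) - log((h + 2) * (h + 1))
  }
  logp <- logp - max(logp)
  prob <- exp(logp)
  prob <- prob / sum(prob)
  obs <- match(n_Aa, hets)
  if (is.na(obs)) stop("observed heterozygote count inconsistent with allele counts")
  min(1, sum(prob[prob <= prob[obs] * (1 + 1e-12)]))
}

#' Per-marker QC summary
#'
#' Computes the HWE exact P and empirical minor allele frequency for every
#' marker of a genotype matrix (on non-missing calls).
#'
#' @param genotypes a [genotype_matrix()].
#' @param status optional 0/1 vector; required when `controls_only = TRUE`.
#' @param controls_only if `TRUE`, compute QC statistics in controls only;
#'   the default uses all samples (consortium-style QC precedes case/control
#'   analysis).
#' @return data.frame with `id`, `n_AA`, `n_Aa`, `n_aa` (AA = homozygous
#'   allele1), `maf`, `hwe_p`.
#' @export
marker_qc <- function(genotypes, status = NULL, controls_only = FALSE) {
  d <- genotypes$dosage
  if (controls_only) {
    if (is.null(status)) stop("controls_only = TRUE requires status")
    d <- d[status == 0L, , drop = FALSE]
  }
  n0 <- colSums(d == 0L, na.rm = TRUE)
  n1 <- colSums(d == 1L, na.rm = TRUE)
  n2 <- colSums(d == 2L, na.rm = TRUE)
  tot <- n0 + n1 + n2
  f_alt <- ifelse(tot > 0, (n1 + 2 * n2) / (2 * tot), NA_real_)
  maf <- pmin(f_alt, 1 - f_alt)
  hwe_p <- vapply(seq_along(tot), function(j) {
    if (tot[j] == 0) return(NA_real_)
    hwe_exact_test(n0[j], n1[j], n2[j])
  }, numeric(1))
  data.frame(id = genotypes$markers$id, n_AA = n0, n_Aa = n1, n_aa = n2,
             maf = maf, hwe_p = hwe_p, stringsAsFactors = FALSE)
}

#' Marker QC filter
#'
#' Removes markers failing the Hardy-Weinberg exact test (P below
#' `hwe_threshold`) or the minor-allele-frequency floor. A marker passes iff
#' `hwe_p >= hwe_threshold` and `maf >= maf_threshold`; markers with no
#' observed genotypes fail. The filter is idempotent.
#'
#' @inheritParams marker_qc
#' @param hwe_threshold HWE exact P threshold (default `1e-6`).
#' @param maf_threshold minor allele frequency floor (default `1e-5`).
#' @return list with `genotypes` (filtered matrix) and `report` (per-marker
#'   data.frame with `pass` flag and `reason`, covering every input marker).
#' @export
qc_filter <- function(genotypes, status = NULL, controls_only = FALSE,
                      hwe_threshold = 1e-6, maf_threshold = 1e-5) {
  rep_df <- marker_qc(genotypes, status, controls_only)
  fail_hwe <- !is.na(rep_df$hwe_p) & rep_df$hwe_p < hwe_threshold
  fail_maf <- is.na(rep_df$maf) | rep_df$maf < maf_threshold
  rep_df$pass <- !fail_hwe & !fail_maf
  rep_df$reason <- ""
  rep_df$reason[fail_maf] <- "maf"
  rep_df$reason[fail_hwe] <- ifelse(fail_maf[fail_hwe], "hwe;maf", "hwe")
  list(genotypes = genotypes[, which(rep_df$pass)], report = rep_df)
}
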