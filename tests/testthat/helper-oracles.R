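# Independent oracles and small fixture builders. These deliberately avoid
# the code paths they check: the HWE oracle enumerates tables from the
# conditional distribution directly, the counting oracle uses logical
# class masks per cell, and fixture genotypes are built with plain rbinom.

# full-enumeration HWE exact test (conditional on allele counts)
hwe_enum <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  if (nA == 0 || nA == 2 * n) return(1)
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  lp <- vapply(hets, function(h) {
    a <- (nA - h) / 2
    b <- n - h - a
    lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(b) +
      h * log(2) + lfactorial(nA) + lfactorial(2 * n - nA) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  sum(p[p <= p[match(n_Aa, hets)] * (1 + 1e-12)])
}

# naive per-class counting oracle for one pair (no bit operations)
naive_pair_table <- function(x, y, status) {
  out <- array(0L, dim = c(2, 3, 3))
  for (s in 0:1)
    for (g1 in 0:2)
      for (g2 in 0:2)
        out[s + 1, g1 + 1, g2 + 1] <-
          sum(!is.na(x) & !is.na(y) & x == g1 & y == g2 & status == s)
  out
}

# independent genotype matrix: unlinked binomial markers
rand_geno <- function(n, m, maf = NULL, missing_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(maf)) maf <- runif(m, 0.05, 0.5)
  maf <- rep_len(maf, m)
  d <- sapply(maf, function(f) rbinom(n, 2, f))
  if (missing_rate > 0) d[runif(n * m) < missing_rate] <- NA
  genotype_matrix(matrix(as.integer(d), n, m),
                  data.frame(id = sprintf("m%03d", 1:m), chrom = 6L,
                             pos = 28700000L + (1:m) * 1000L,
                             allele1 = "A", allele2 = "B",
                             stringsAsFactors = FALSE),
                  sprintf("s%05d", 1:n))
}

rand_cohort <- function(geno, status, covariates = NULL) {
  cohort_table(geno$samples, status, covariates)
}

# saturated multinomial log-likelihood of a table
sat_loglik <- function(tab) {
  tab <- as.numeric(tab)
  sum(tab[tab > 0] * log(tab[tab > 0] / sum(tab)))
}

# random 2x3x3 multinomial table
rand_table <- function(n = 2000) {
  pr <- runif(18)
  array(rmultinom(1, n, pr), dim = c(2, 3, 3))
}

# grouped-logistic reduced-model (homogeneous) log-likelihood oracle: the
# prospective logistic log-likelihood plus the fixed (g1,g2) marginal term
# equals the multinomial log-likelihood of the log-linear no-three-way model
grouped_reduced_loglik <- function(tab) {
  grid <- expand.grid(y = 0:1, g1 = 0:2, g2 = 0:2)
  X <- cbind(1, grid$g1 == 1, grid$g1 == 2, grid$g2 == 1, grid$g2 == 2) * 1
  colnames(X) <- c("i", "a1", "b1", "a2", "b2")
  f <- logistic_fit(X, grid$y, weights = as.numeric(tab))
  m12 <- apply(tab, c(2, 3), sum)
  f$loglik + sum(m12[m12 > 0] * log(m12[m12 > 0] / sum(tab)))
}
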