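test_that("IPF preserves two-way margins and fixes homogeneous tables", {
  set.seed(61)
  for (k in 1:15) {
    tab <- rand_table(1000)
    fit <- ipf_homogeneous_fit(tab)
    expect_true(fit$converged)
    expect_lt(max(abs(apply(fit$fitted, c(2, 3), sum) - apply(tab, c(2, 3), sum))), 1e-8)
    expect_lt(max(abs(apply(fit$fitted, c(1, 2), sum) - apply(tab, c(1, 2), sum))), 1e-8)
    expect_lt(max(abs(apply(fit$fitted, c(1, 3), sum) - apply(tab, c(1, 3), sum))), 1e-8)
    # a homogeneous table is a fixed point: refitting reproduces it
    refit <- ipf_homogeneous_fit(fit$fitted)
    expect_lt(max(abs(refit$fitted - fit$fitted)), 1e-6)
  }
  # structural zeros: a whole genotype class absent
  tab <- rand_table(800); tab[, , 1] <- 0
  fit <- ipf_homogeneous_fit(tab)
  expect_true(all(fit$fitted[, , 1] == 0))
  expect_true(is.finite(fit$loglik))
})

test_that("no-covariate interaction LRT equals the IPF formulation", {
  set.seed(67)
  for (k in 1:5) {
    n <- 2000
    g1 <- rbinom(n, 2, runif(1, 0.2, 0.5))
    g2 <- rbinom(n, 2, runif(1, 0.2, 0.5))
    y <- rbinom(n, 1, plogis(-0.3 + 0.3 * g1 - 0.2 * g2 +
                               0.25 * (g1 == 1) * (g2 == 1)))
    geno <- genotype_matrix(cbind(g1, g2),
                            data.frame(id = c("m1", "m2"), chrom = 1,
                                       pos = 1:2, allele1 = "A",
                                       allele2 = "B"), paste0("s", 1:n))
    co <- rand_cohort(geno, y)
    lrt <- interaction_lrt(geno, co, c("m1", "m2"))
    tab <- naive_pair_table(g1, g2, y)
    stat_ipf <- 2 * (sat_loglik(tab) - ipf_homogeneous_fit(tab)$loglik)
    expect_equal(lrt$stat, stat_ipf, tolerance = 1e-6)
    expect_equal(lrt$df, 4L)
    # swapping pair members leaves the statistic unchanged
    swap <- interaction_lrt(geno, co, c("m2", "m1"))
    expect_equal(swap$stat, lrt$stat, tolerance = 1e-8)
  }
  # chi-squared reference: stat 9.488 with 4 df sits at P = 0.0500
  expect_equal(signif(pchisq(9.488, 4, lower.tail = FALSE), 3), 0.05)
})

test_that("main-effects-only tables give a near-zero interaction statistic", {
  set.seed(71)
  for (k in 1:5) {
    hom <- ipf_homogeneous_fit(rand_table(3000))$fitted  # exactly homogeneous
    grid <- expand.grid(y = 0:1, g1 = 0:2, g2 = 0:2)
    F1 <- cbind(g1a = (grid$g1 == 1) * 1, g1b = (grid$g1 == 2) * 1)
    F2 <- cbind(g2a = (grid$g2 == 1) * 1, g2b = (grid$g2 == 2) * 1)
    inter <- cbind(F1[, 1] * F2[, 1], F1[, 1] * F2[, 2],
                   F1[, 2] * F2[, 1], F1[, 2] * F2[, 2])
    w <- as.numeric(hom)
    red <- logistic_fit(cbind(1, F1, F2), grid$y, weights = w)
    full <- logistic_fit(cbind(1, F1, F2, inter), grid$y, weights = w)
    expect_lt(2 * (full$loglik - red$loglik), 1e-6)
  }
})

test_that("conditioning on a causal additive SNP removes its leakage", {
  # y depends additively on m3; pair (m1, m2) in LD with m3 shows inflated
  # unconditional evidence relative to the conditional test
  set.seed(73)
  n <- 8000
  z <- rnorm(n)
  mk <- function(rho) {
    h <- function() (rho * z + sqrt(1 - rho^2) * rnorm(n)) < qnorm(0.3)
    as.integer(h() + h())
  }
  g3 <- as.integer((z < qnorm(0.3)) + ((0.9 * z + sqrt(1 - 0.81) * rnorm(n)) < qnorm(0.3)))
  g1 <- mk(0.6); g2 <- mk(0.6)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * g3))
  geno <- genotype_matrix(cbind(m1 = g1, m2 = g2, m3 = g3),
                          data.frame(id = c("m1", "m2", "m3"), chrom = 1,
                                     pos = 1:3, allele1 = "A", allele2 = "B"),
                          paste0("s", 1:n))
  co <- rand_cohort(geno, y)
  res <- epistasis_tests(geno, co, data.frame(snp1 = "m1", snp2 = "m2"),
                         background = "m3")
  expect_lte(res$stat_cond, res$stat_int + 1e-6)
  # empty background: conditional equals unconditional
  res0 <- epistasis_tests(geno, co, data.frame(snp1 = "m1", snp2 = "m2"))
  expect_equal(res0$p_cond, res0$p_int)
  # pair members in the background are excluded from the extra covariates
  res1 <- interaction_lrt(geno, co, c("m1", "m2"),
                          extra_covariates = c("m1", "m2", "m3"))
  res2 <- interaction_lrt(geno, co, c("m1", "m2"), extra_covariates = "m3")
  expect_equal(res1$stat, res2$stat, tolerance = 1e-10)
})

test_that("significance thresholds reproduce the published qualitative calls", {
  res <- data.frame(snp1 = "a", snp2 = "b",
                    p_cond = c(3.12e-21, 3.32e-9, 2e-8))
  out <- call_significance(res)
  expect_equal(out$genome_wide, c(TRUE, FALSE, FALSE))
  expect_equal(out$chip_wide, c(TRUE, TRUE, FALSE))
  expect_true(all(!out$genome_wide | out$chip_wide))
  expect_error(call_significance(res, genome_wide = 1e-3, chip_wide = 1e-8))

  calls <- reported_pair_calls()
  expect_equal(calls$n_pairs, 9)
  expect_equal(calls$n_chip_wide, 9)
  expect_equal(calls$n_replicated, 8)
  failed <- calls$calls[!calls$calls$replicated, ]
  expect_equal(failed$snp1, "rs1964995")
})

test_that("replication calls follow the conditional P < 0.05 rule", {
  set.seed(79)
  n <- 6000
  g1 <- rbinom(n, 2, 0.4); g2 <- rbinom(n, 2, 0.4)
  y <- rbinom(n, 1, plogis(-0.6 + 1.2 * ((g1 %% 2) != (g2 %% 2))))
  geno <- genotype_matrix(cbind(p1 = g1, p2 = g2),
                          data.frame(id = c("p1", "p2"), chrom = 1, pos = 1:2,
                                     allele1 = "A", allele2 = "B"),
                          paste0("s", 1:n))
  co <- rand_cohort(geno, y)
  rep_out <- replicate_pairs(data.frame(snp1 = "p1", snp2 = "p2"), geno, co)
  expect_true(rep_out$replicated)
  expect_equal(rep_out$cohort, "replication")
  # null pair in pure-noise data is (almost surely) not replicated
  y0 <- rbinom(n, 1, 0.5)
  co0 <- rand_cohort(geno, y0)
  rep0 <- replicate_pairs(data.frame(snp1 = "p1", snp2 = "p2"), geno, co0)
  expect_type(rep0$replicated, "logical")
})
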