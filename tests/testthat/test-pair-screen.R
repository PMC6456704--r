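test_that("bit planes count genotype classes and validity exactly", {
  d <- matrix(c(0L, 0L, 1L, 1L, 2L, 2L, NA, 0L), ncol = 1)
  geno <- genotype_matrix(d, data.frame(id = "m", chrom = 1, pos = 1,
                                        allele1 = "A", allele2 = "B"),
                          paste0("s", 1:8))
  pc <- plane_popcounts(encode_bit_planes(geno))
  expect_equal(unname(pc["m", ]), c(3L, 2L, 2L, 7L))

  geno <- rand_geno(203, 10, missing_rate = 0.15, seed = 31)
  pc <- plane_popcounts(encode_bit_planes(geno))
  expect_equal(pc[, "g0"] + pc[, "g1"] + pc[, "g2"], pc[, "valid"])
  expect_equal(unname(pc[, "valid"]), unname(colSums(!is.na(geno$dosage))))
})

test_that("bit-plane pair tables equal the naive class-mask oracle", {
  set.seed(13)
  for (k in 1:6) {
    n <- sample(50:300, 1)
    m <- sample(4:12, 1)
    geno <- rand_geno(n, m, missing_rate = runif(1, 0, 0.2))
    status <- rbinom(n, 1, 0.4)
    planes <- encode_bit_planes(geno)
    for (pair in list(c(1, 2), c(1, m), c(2, 3))) {
      got <- pair_table(planes, pair[1], pair[2], status)
      want <- naive_pair_table(geno$dosage[, pair[1]],
                               geno$dosage[, pair[2]], status)
      expect_equal(unname(unclass(got)), want, ignore_attr = TRUE)
    }
  }
})

test_that("pair tables respect margins, missingness and degenerate markers", {
  geno <- rand_geno(400, 3, missing_rate = 0.1, seed = 47)
  geno$dosage[, 3] <- NA_integer_
  status <- rep(c(0L, 1L), 200)
  planes <- encode_bit_planes(geno)
  tab <- pair_table(planes, 1, 2, status)
  both <- !is.na(geno$dosage[, 1]) & !is.na(geno$dosage[, 2])
  expect_equal(sum(tab), sum(both))
  # margins match single-marker counts on the complete-pair subset
  g1 <- geno$dosage[both, 1]
  expect_equal(unname(apply(tab, 2, sum)),
               unname(sapply(0:2, function(g) sum(g1 == g))))
  expect_true(all(pair_table(planes, 1, 3, status) == 0L))
  expect_error(pair_table(planes, 2, 2, status), "distinct")
})

test_that("KSA statistic: independence gives zero; symmetric under swaps", {
  tab <- array(100, dim = c(2, 3, 3))   # exact three-way independence
  ks <- ksa_statistic(tab)
  expect_equal(ks$statistic, 0, tolerance = 1e-10)
  expect_equal(ks$p, 1)

  set.seed(19)
  for (k in 1:20) {
    tab <- rand_table(1500)
    s1 <- ksa_statistic(tab)$statistic
    s2 <- ksa_statistic(aperm(tab, c(1, 3, 2)))$statistic  # swap markers
    expect_equal(s1, s2, tolerance = 1e-9)
    expect_gte(s1, 0)
  }
  # degenerate table (one genotype class absent) must not fail
  tab <- rand_table(500)
  tab[, 3, ] <- 0
  expect_gte(ksa_statistic(tab)$statistic, 0)
  expect_error(ksa_statistic(array(0, dim = c(2, 3, 3))), "positive")
})

test_that("dosage r2 matches hand-computed values", {
  d <- cbind(c(0L, 1L, 2L, 0L, 1L, 2L), c(0L, 0L, 1L, 1L, 2L, 2L))
  geno <- genotype_matrix(d, data.frame(id = c("x", "y"), chrom = 1,
                                        pos = 1:2, allele1 = "A",
                                        allele2 = "B"), paste0("s", 1:6))
  # cross-product sum 2, each centered SS 4 -> r = 0.5, r2 = 0.25
  expect_equal(dosage_r2(geno, 1, 2), 0.25, tolerance = 1e-12)
  expect_equal(dosage_r2(geno, 1, 2), cor(d[, 1], d[, 2])^2, tolerance = 1e-12)

  d2 <- cbind(d[, 1], d[, 1], 2L - d[, 1], c(1L, 1L, 1L, 1L, 1L, 1L))
  geno2 <- genotype_matrix(d2, data.frame(id = letters[1:4], chrom = 1,
                                          pos = 1:4, allele1 = "A",
                                          allele2 = "B"), paste0("s", 1:6))
  expect_equal(dosage_r2(geno2, 1, 2), 1)
  expect_equal(dosage_r2(geno2, 1, 3), 1)   # perfect negative correlation
  expect_true(is.na(dosage_r2(geno2, 1, 4)))
})

test_that("screen retains strong low-LD pairs and excludes high-LD pairs", {
  set.seed(53)
  n <- 4000
  g1 <- rbinom(n, 2, 0.4)
  g2 <- rbinom(n, 2, 0.4)
  noise <- matrix(as.integer(rbinom(n * 6, 2, 0.3)), n, 6)
  d <- cbind(g1, g2, noise)
  storage.mode(d) <- "integer"
  geno <- genotype_matrix(d, data.frame(id = sprintf("v%02d", 1:8), chrom = 6,
                                        pos = 28700000 + (1:8) * 1000,
                                        allele1 = "A", allele2 = "B"),
                          sprintf("s%04d", 1:n))
  # strong XOR-like interaction between the unlinked markers 1 and 2
  eta <- 1.4 * ((g1 %% 2) != (g2 %% 2))
  y <- rbinom(n, 1, plogis(-0.7 + eta))
  co <- rand_cohort(geno, y)
  cand <- screen_all_pairs(geno, co, p_threshold = 1e-10, r2_threshold = 0.2)
  expect_gte(nrow(cand), 1)
  expect_equal(c(cand$snp1[1], cand$snp2[1]), c("v01", "v02"))
  expect_true(all(cand$r2 < 0.2))
  # impossible threshold: clean empty result
  none <- screen_all_pairs(geno, co, p_threshold = 1e-300)
  expect_equal(nrow(none), 0)
  expect_equal(attr(none, "n_pairs_tested"), 28)
})

test_that("a planted pair with r2 = 0.5 between members is excluded regardless of P", {
  set.seed(54)
  n <- 5000
  g1 <- rbinom(n, 2, 0.4)
  copy <- runif(n) < 0.7                     # noisy copy: r ~ 0.7, r2 ~ 0.5
  g3 <- ifelse(copy, g1, rbinom(n, 2, 0.4))
  d <- cbind(g1, g3, as.integer(rbinom(n, 2, 0.3)))
  storage.mode(d) <- "integer"
  geno <- genotype_matrix(d, data.frame(id = c("u1", "u2", "u3"), chrom = 6,
                                        pos = 28700000 + (1:3) * 1000,
                                        allele1 = "A", allele2 = "B"),
                          sprintf("s%04d", 1:n))
  y <- rbinom(n, 1, plogis(-0.7 + 1.6 * ((g1 %% 2) != (g3 %% 2))))
  co <- rand_cohort(geno, y)
  expect_gt(dosage_r2(geno, "u1", "u2"), 0.2)
  cand <- screen_all_pairs(geno, co, p_threshold = 1e-10, r2_threshold = 0.2)
  expect_false(any(cand$snp1 == "u1" & cand$snp2 == "u2"))
  expect_gte(attr(cand, "n_excluded_r2"), 1)
})

test_that("screen output is invariant to marker order up to tie-breaks", {
  set.seed(59)
  n <- 1500
  g1 <- rbinom(n, 2, 0.4); g2 <- rbinom(n, 2, 0.4)
  y <- rbinom(n, 1, plogis(-0.5 + 1.5 * ((g1 %% 2) != (g2 %% 2))))
  extra <- matrix(as.integer(rbinom(n * 3, 2, 0.3)), n, 3)
  d <- cbind(g1, g2, extra); storage.mode(d) <- "integer"
  mk <- data.frame(id = paste0("w", 1:5), chrom = 1, pos = 1:5,
                   allele1 = "A", allele2 = "B")
  geno <- genotype_matrix(d, mk, paste0("s", 1:n))
  co <- rand_cohort(geno, y)
  perm <- c(4, 2, 5, 1, 3)
  geno_p <- geno[, perm]
  a <- screen_all_pairs(geno, co, p_threshold = 1e-4)
  b <- screen_all_pairs(geno_p, co, p_threshold = 1e-4)
  norm <- function(x) {
    key <- t(apply(cbind(x$snp1, x$snp2), 1, sort))
    x$snp1 <- key[, 1]; x$snp2 <- key[, 2]
    x[order(x$p_approx, x$snp1, x$snp2), c("snp1", "snp2", "stat")]
  }
  expect_equal(norm(a), norm(b), ignore_attr = TRUE, tolerance = 1e-9)
})
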