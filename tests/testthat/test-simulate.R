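test_that("simulation is deterministic in (config, seed)", {
  cfg <- sim_config(n_cases = 150, n_controls = 150, n_markers = 20,
                    missing_rate = 0.01, seed = 99)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  expect_identical(s1$cohort$status, s2$cohort$status)
  expect_identical(s1$cohort$covariates, s2$cohort$covariates)
  s3 <- simulate_cohort(sim_config(n_cases = 150, n_controls = 150,
                                   n_markers = 20, missing_rate = 0.01,
                                   seed = 100))
  expect_false(identical(s1$genotypes$dosage, s3$genotypes$dosage))
})

test_that("null config yields the requested allele frequencies and HWE", {
  cfg <- sim_config(n_cases = 5000, n_controls = 5000, n_markers = 100,
                    maf_range = c(0.3, 0.3), block_structure = list(c(10, 0.8)),
                    n_subpops = 1, n_batches = 1, batch_effect_sd = 0,
                    fst_like_divergence = 0, missing_rate = 0, n_pcs = 0,
                    seed = 17)
  sim <- simulate_cohort(cfg)
  expect_equal(mean(sim$cohort$status), 0.5)
  f <- colMeans(sim$genotypes$dosage) / 2
  expect_true(all(abs(f - 0.3) <= 0.02))
  hwe <- marker_qc(sim$genotypes)$hwe_p
  expect_gte(mean(hwe > 1e-3), 0.99)
})

test_that("LD decays with distance inside blocks and vanishes across blocks", {
  cfg <- sim_config(n_cases = 2500, n_controls = 2500, n_markers = 30,
                    block_structure = list(c(15, 0.9)), maf_range = c(0.2, 0.4),
                    n_subpops = 1, n_batches = 1, fst_like_divergence = 0,
                    missing_rate = 0, n_pcs = 0, seed = 23)
  sim <- simulate_cohort(cfg)
  r2_1 <- dosage_r2(sim$genotypes, 1, 2)
  r2_5 <- dosage_r2(sim$genotypes, 1, 6)
  r2_10 <- dosage_r2(sim$genotypes, 1, 11)
  expect_gt(r2_1, r2_5)
  expect_gt(r2_5, r2_10)
  expect_lt(dosage_r2(sim$genotypes, 10, 20), 0.05)  # across block boundary
})

test_that("planted additive effects are recovered by the generating model", {
  hits <- 0
  for (rep in 1:4) {
    cfg <- sim_config(n_cases = 4000, n_controls = 4000, n_markers = 10,
                      block_structure = list(c(5, 0.5)),
                      maf_range = c(0.2, 0.4),
                      additive_effects = data.frame(marker = 3, beta = 0.3),
                      n_subpops = 1, n_batches = 1, fst_like_divergence = 0,
                      missing_rate = 0, n_pcs = 0, seed = 300 + rep)
    sim <- simulate_cohort(cfg)
    X <- cbind(1, sim$genotypes$dosage[, 3])
    fit <- logistic_fit(X, sim$cohort$status)
    if (abs(fit$coefficients[2] - 0.3) <= 3 * fit$se[2]) hits <- hits + 1
  }
  expect_gte(hits, 3)
})

test_that("extreme planted effects trigger the intercept-search failure", {
  cfg <- sim_config(n_cases = 10, n_controls = 990, n_markers = 5,
                    maf_range = c(0.3, 0.3),
                    additive_effects = data.frame(marker = 1, beta = 60),
                    n_subpops = 1, n_batches = 1, missing_rate = 0,
                    n_pcs = 0, seed = 31)
  expect_error(simulate_cohort(cfg), "intercept search")
})

test_that("stratified split is exact, disjoint and exhaustive", {
  geno <- rand_geno(300, 3, seed = 41)
  co <- rand_cohort(geno, rep(c(1L, 0L), c(100, 200)))
  sp <- split_cohort(geno, co, fraction = 0.5, seed = 2)
  expect_equal(sum(sp$discovery$cohort$status), 50)
  expect_equal(sum(1 - sp$discovery$cohort$status), 100)
  expect_length(intersect(sp$discovery$genotypes$samples,
                          sp$replication$genotypes$samples), 0)
  expect_setequal(c(sp$discovery$genotypes$samples,
                    sp$replication$genotypes$samples), geno$samples)

  # cohort-scale stratified rule: 14,224 cases / 33,954 controls halve to
  # 7,112 cases per side
  big <- cohort_table(sprintf("x%05d", 1:48178),
                      rep(c(1L, 0L), c(14224, 33954)))
  bigg <- genotype_matrix(matrix(0L, 48178, 1),
                          data.frame(id = "m1", chrom = 1, pos = 1,
                                     allele1 = "A", allele2 = "B"),
                          big$sample_id)
  sp2 <- split_cohort(bigg, big, fraction = 0.5, seed = 3)
  expect_equal(sum(sp2$discovery$cohort$status), 7112)
  expect_equal(sum(sp2$replication$cohort$status), 7112)

  none <- cohort_table(paste0("s", 1:5), rep(0L, 5))
  geno5 <- rand_geno(5, 2, seed = 1)
  none$sample_id <- geno5$samples
  expect_error(split_cohort(geno5, none, 0.5, 1), "empty stratum")
})

test_that("synthetic cohorts round-trip to disk with truth record", {
  cfg <- sim_config(n_cases = 60, n_controls = 60, n_markers = 8,
                    additive_effects = data.frame(marker = 2, beta = 0.4),
                    epistatic_effects = list(list(pair = c(3, 7),
                                                  beta = diag(3) * 0.5)),
                    missing_rate = 0.02, seed = 77)
  sim <- simulate_cohort(cfg)
  prefix <- tempfile()
  write_synthetic_cohort(sim, prefix)
  rt <- read_plink(prefix)
  expect_identical(rt$genotypes$dosage, sim$genotypes$dosage)
  expect_identical(rt$fam$status, sim$cohort$status)
  truth <- jsonlite::read_json(paste0(prefix, ".truth.json"),
                               simplifyVector = FALSE)
  expect_equal(truth$additive[[1]]$beta, 0.4)
  expect_equal(as.numeric(unlist(truth$epistatic[[1]]$pair)), c(3, 7))
})
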