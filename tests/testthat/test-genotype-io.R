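test_that("PLINK triplet round-trips bit-exactly, including missing calls", {
  d <- matrix(c(0L, 1L, 2L, NA, 0L,
                2L, 2L, 0L, 1L, NA,
                0L, 0L, 0L, 1L, 2L), ncol = 3)
  geno <- genotype_matrix(d, data.frame(id = c("a", "b", "c"), chrom = 6,
                                        pos = c(10L, 20L, 30L),
                                        allele1 = "A", allele2 = "G"),
                          paste0("s", 1:5))
  prefix <- tempfile()
  write_plink(geno, prefix, status = c(0, 1, 0, 1, 1))
  rt <- read_plink(prefix)
  expect_identical(rt$genotypes$dosage, geno$dosage)
  expect_identical(rt$genotypes$markers$pos, geno$markers$pos)
  expect_identical(rt$fam$status, c(0L, 1L, 0L, 1L, 1L))

  set.seed(21)
  for (k in 1:10) {
    g <- rand_geno(sample(3:40, 1), sample(1:15, 1),
                   missing_rate = 0.1)
    p <- tempfile()
    write_plink(g, p)
    expect_identical(read_plink(p)$genotypes$dosage, g$dosage)
  }
})

test_that("bed bytes follow the 2-bit SNP-major code", {
  # dosages {0,1,2}: codes 00, 10, 11, LSB pair first -> 0b00111000 = 0x38
  geno <- genotype_matrix(matrix(c(0L, 1L, 2L), ncol = 1),
                          data.frame(id = "m", chrom = 1, pos = 1L,
                                     allele1 = "A", allele2 = "B"),
                          paste0("s", 1:3))
  prefix <- tempfile()
  write_plink(geno, prefix)
  raw <- readBin(paste0(prefix, ".bed"), "raw", 10)
  expect_identical(raw[1:3], as.raw(c(0x6c, 0x1b, 0x01)))
  expect_identical(raw[4], as.raw(0x38))
  expect_identical(read_plink(prefix)$genotypes$dosage[, 1], c(s1 = 0L, s2 = 1L, s3 = 2L))
})

test_that("malformed bed files fail with explicit messages", {
  geno <- rand_geno(6, 2, seed = 5)
  prefix <- tempfile()
  write_plink(geno, prefix)
  bed <- paste0(prefix, ".bed")
  raw <- readBin(bed, "raw", file.size(bed))

  writeBin(c(as.raw(c(0x6c, 0x1b, 0x00)), raw[-(1:3)]), bed)
  expect_error(read_plink(prefix), "sample-major")
  writeBin(c(as.raw(c(0xde, 0xad, 0x01)), raw[-(1:3)]), bed)
  expect_error(read_plink(prefix), "magic")
  writeBin(raw[-length(raw)], bed)
  expect_error(read_plink(prefix), "truncated")
  writeBin(raw, bed)
  expect_silent(read_plink(prefix))
  expect_error(read_plink(tempfile()), "missing file")
})

test_that("covariate files are aligned, validated, and exclusions counted", {
  samples <- paste0("s", 1:5)
  tab <- data.frame(FID = samples[c(3, 1, 5, 2)], IID = samples[c(3, 1, 5, 2)],
                    PC1 = c(0.3, 0.1, 0.5, 0.2), batch2 = c(1, 0, 0, 1))
  path <- tempfile()
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  co <- read_covariates(path, samples, status = c(0, 1, 0, 1, 0))
  expect_equal(co$covariates[, "PC1"], c(0.1, 0.2, 0.3, NA, 0.5),
               ignore_attr = TRUE)
  expect_equal(attr(co, "n_excluded"), 1)
  expect_equal(attr(co, "excluded"), "s4")

  tab2 <- rbind(tab, tab[1, ])
  write.table(tab2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_covariates(path, samples, rep(0:1, c(3, 2))), "duplicated IID")

  tab$PC1 <- as.character(tab$PC1)
  tab$PC1[2] <- "x1"
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_covariates(path, samples, rep(0:1, c(3, 2))),
               "non-numeric covariate value in column 'PC1', row 2")
})

test_that("results dialect: ordering, tie-breaks, and P formatting", {
  path <- tempfile()
  write_results(data.frame(snp1 = character(0), snp2 = character(0),
                           p_cond = numeric(0)), path)
  expect_equal(length(readLines(path)), 1)   # header only

  rec <- data.frame(snp1 = c("rsB", "rsA", "rsC"), snp2 = c("rsZ", "rsZ", "rsY"),
                    p_cond = c(1e-3, 1e-3, 3.12e-21))
  write_results(rec, path)
  lines <- readLines(path)
  expect_match(lines[2], "^rsC\trsY\t3.12E-21$")
  # equal conditional P: ordered by (snp1, snp2)
  expect_match(lines[3], "^rsA")
  expect_match(lines[4], "^rsB")
})
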