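# PLINK 1 binary codec. SNP-major bed only (magic 0x6c 0x1b 0x01); each marker
# occupies ceiling(n/4) bytes, two bits per sample, least-significant pair
# first: 00 -> homozygous allele1 (dosage 0), 01 -> missing, 10 -> het,
# 11 -> homozygous allele2 (dosage 2). Dosage counts allele2 copies.

# 256 x 4 lookup: byte value -> dosages of the 4 samples it packs
.bed_decode_lut <- local({
  code2dos <- c(0L, NA_integer_, 1L, 2L)     # 2-bit codes 00, 01, 10, 11
  lut <- matrix(NA_integer_, nrow = 256, ncol = 4)
  for (b in 0:255)
    for (s in 0:3)
      lut[b + 1L, s + 1L] <- code2dos[bitwAnd(bitwShiftR(b, 2L * s), 3L) + 1L]
  lut
})

.dos2code <- function(d) {
  code <- integer(length(d))
  code[is.na(d)] <- 1L
  code[!is.na(d) & d == 1L] <- 2L
  code[!is.na(d) & d == 2L] <- 3L
  code
}

#' Write a genotype matrix as a PLINK bed/bim/fam triplet
#'
#' @param genotypes a [genotype_matrix()].
#' @param prefix output path prefix; `prefix.bed`, `prefix.bim`, `prefix.fam`
#'   are created.
#' @param status optional 0/1 phenotype written to the fam file (encoded
#'   1 = control, 2 = case; `-9` when absent).
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(genotypes, prefix, status = NULL) {
  d <- genotypes$dosage
  n <- nrow(d); m <- ncol(d)
  nbytes <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4L * nbytes - n
  mult <- 4L^(0:3)
  for (j in seq_len(m)) {
    code <- c(.dos2code(d[, j]), integer(pad))   # pad bits are 00
    bytes <- colSums(matrix(code * rep(mult, times = nbytes), nrow = 4L))
    writeBin(as.raw(bytes), con)
  }
  mk <- genotypes$markers
  bim <- data.frame(mk$chrom, mk$id, 0L, mk$pos, mk$allele1, mk$allele2)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  pheno <- if (is.null(status)) rep(-9L, n) else as.integer(status) + 1L
  fam <- data.frame(genotypes$samples, genotypes$samples, 0L, 0L, 0L, pheno)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read a PLINK bed/bim/fam triplet
#'
#' Only SNP-major mode is supported. Decoding round-trips with
#' [write_plink()] bit-exactly, including missing calls.
#'
#' @param prefix path prefix of the triplet.
#' @return list with `genotypes` (a [genotype_matrix()]) and `fam` (the fam
#'   table as a data.frame, with `status` decoded to 0/1/NA).
#' @export
read_plink <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  bim_path <- paste0(prefix, ".bim")
  fam_path <- paste0(prefix, ".fam")
  for (f in c(bed_path, bim_path, fam_path))
    if (!file.exists(f)) stop("missing file: ", f)
  bim <- read.table(bim_path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "id", "cm", "pos",
                                  "allele1", "allele2"))
  fam <- read.table(fam_path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"))
  n <- nrow(fam); m <- nrow(bim)
  nbytes <- ceiling(n / 4)
  sz <- file.size(bed_path)
  raw <- readBin(bed_path, what = "raw", n = sz)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK bed file (bad magic bytes): ", bed_path)
  if (raw[3] == as.raw(0x00))
    stop("sample-major bed files are not supported: ", bed_path)
  if (raw[3] != as.raw(0x01))
    stop("unknown bed mode byte: ", bed_path)
  if (length(raw) != 3 + nbytes * m)
    stop(sprintf(
      "truncated or oversized bed file %s: expected %d data bytes for %d samples x %d markers, found %d",
      bed_path, nbytes * m, n, m, length(raw) - 3))
  body <- as.integer(raw[-(1:3)])
  dos <- .bed_decode_lut[body + 1L, , drop = FALSE]     # (nbytes*m) x 4
  dos <- matrix(t(dos), nrow = 4L * nbytes)             # samples+pad x m
  dos <- dos[seq_len(n), , drop = FALSE]
  status <- ifelse(fam$pheno %in% c(1L, 2L), fam$pheno - 1L, NA_integer_)
  fam$status <- status
  geno <- genotype_matrix(dos, bim[, c("id", "chrom", "pos",
                                       "allele1", "allele2")], fam$iid)
  list(genotypes = geno, fam = fam)
}

#' Read a covariate file and align it to a cohort's sample order
#'
#' Whitespace/tab-delimited with a header whose first two columns are FID and
#' IID; remaining columns must be numeric covariates. Samples present in the
#' genotype data but absent from the covariate file are flagged for case-wise
#' exclusion rather than dropped silently.
#'
#' @param path covariate file path.
#' @param samples character vector of sample identifiers in genotype order.
#' @param status 0/1 phenotype vector aligned to `samples`.
#' @return a [cohort_table()] aligned to `samples`; covariates of samples
#'   missing from the file are `NA` and counted in attribute `n_excluded`.
#' @export
read_covariates <- function(path, samples, status) {
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (ncol(tab) < 2) stop("covariate file needs at least FID and IID columns")
  iid <- as.character(tab[[2]])
  if (anyDuplicated(iid))
    stop("duplicated IID in covariate file: ",
         paste(unique(iid[duplicated(iid)]), collapse = ", "))
  cov_cols <- names(tab)[-(1:2)]
  for (cc in cov_cols) {
    v <- tab[[cc]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & v != "NA")
      if (length(bad))
        stop(sprintf("non-numeric covariate value in column '%s', row %d: '%s'",
                     cc, bad[1], v[bad[1]]))
      tab[[cc]] <- vn
    }
  }
  idx <- match(samples, iid)
  covs <- as.matrix(tab[idx, cov_cols, drop = FALSE])
  rownames(covs) <- samples
  out <- cohort_table(samples, status, covs)
  attr(out, "n_excluded") <- sum(is.na(idx))
  attr(out, "excluded") <- samples[is.na(idx)]
  out
}

#' Write a covariate table (FID, IID, covariates) to a tab-separated file
#'
#' @param cohort a [cohort_table()].
#' @param path output path.
#' @export
write_covariates <- function(cohort, path) {
  df <- data.frame(FID = cohort$sample_id, IID = cohort$sample_id,
                   cohort$covariates, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# scientific-notation formatter used by the results dialect: "3.12E-21"
format_p <- function(p, digits = 3) {
  out <- toupper(formatC(p, format = "e", digits = digits - 1))
  out[is.na(p)] <- "NA"
  out
}

#' Write epistasis results in the tab-separated reporting dialect
#'
#' One header line; P-values rendered in scientific notation with three
#' significant digits (`3.12E-21`); rows ordered by ascending conditional P,
#' ties broken by (SNP1 id, SNP2 id).
#'
#' @param records data.frame of results; columns named `p_*` or ending in
#'   `_p` are formatted as P-values. Ordering uses column `p_cond` when
#'   present (falling back to `p_int`), then `snp1`, `snp2`.
#' @param path output path.
#' @export
write_results <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records)) {
    ord_p <- if ("p_cond" %in% names(records)) records$p_cond
             else if ("p_int" %in% names(records)) records$p_int
             else rep(0, nrow(records))
    o <- order(ord_p, records$snp1, records$snp2)
    records <- records[o, , drop = FALSE]
  }
  is_p <- grepl("^p_|_p$|^P_", names(records))
  for (j in which(is_p)) records[[j]] <- format_p(records[[j]])
  num <- vapply(records, is.numeric, logical(1)) & !is_p
  for (j in which(num)) records[[j]] <- formatC(records[[j]], format = "fg")
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
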