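#' Genotype matrix container
#'
#' Holds biallelic genotypes as allele2 dosages (0, 1, 2 or `NA` for missing)
#' together with marker metadata. The dosage counts copies of `allele2` (the
#' second allele of the marker record), matching PLINK bed semantics; the minor
#' allele is determined empirically per cohort, never assumed.
#'
#' @param dosage integer matrix, samples in rows, markers in columns; values
#'   in `{0, 1, 2, NA}`.
#' @param markers data.frame with columns `id`, `chrom`, `pos`, `allele1`,
#'   `allele2`; one row per column of `dosage`. Marker ids must be unique,
#'   positions non-negative integers.
#' @param samples character vector of sample identifiers, one per row of
#'   `dosage`.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, markers, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  stopifnot(nrow(markers) == ncol(dosage), length(samples) == nrow(dosage))
  required <- c("id", "chrom", "pos", "allele1", "allele2")
  if (!all(required %in% names(markers)))
    stop("markers must have columns: ", paste(required, collapse = ", "))
  if (anyDuplicated(markers$id))
    stop("marker identifiers must be unique")
  if (any(markers$pos < 0))
    stop("marker positions must be non-negative")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA")
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  markers$pos <- as.integer(markers$pos)
  rownames(dosage) <- samples
  colnames(dosage) <- markers$id
  structure(
    list(dosage = dosage, markers = markers,
         samples = as.character(samples), counted = "allele2"),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers (dosage counts %s)\n",
              nrow(x$dosage), ncol(x$dosage), x$counted))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or markers
#'
#' @param x a [genotype_matrix()].
#' @param i sample index (logical, integer or identifier).
#' @param j marker index (logical, integer or identifier).
#' @param ... ignored.
#' @param drop ignored; subsetting always returns a `genotype_matrix`.
#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(j)) j <- match(j, x$markers$id)
  genotype_matrix(x$dosage[i, j, drop = FALSE],
                  x$markers[j, , drop = FALSE],
                  x$samples[i])
}

#' Cohort phenotype/covariate table
#'
#' Per-sample binary disease status plus numeric covariates (principal
#' component scores, batch indicator dummies).
#'
#' @param sample_id character vector of sample identifiers.
#' @param status integer vector in `{0, 1}`; 1 = case, 0 = control.
#' @param covariates numeric matrix (possibly zero columns) with one row per
#'   sample and named columns; full column rank is checked at fit time, not
#'   here.
#'
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(sample_id, status, covariates = NULL) {
  n <- length(sample_id)
  status <- as.integer(status)
  stopifnot(length(status) == n)
  if (!all(status %in% c(0L, 1L)))
    stop("status must be binary 0/1")
  if (is.null(covariates))
    covariates <- matrix(numeric(0), nrow = n, ncol = 0)
  covariates <- as.matrix(covariates)
  stopifnot(nrow(covariates) == n)
  if (ncol(covariates) > 0 && is.null(colnames(covariates)))
    colnames(covariates) <- paste0("COV", seq_len(ncol(covariates)))
  structure(
    list(sample_id = as.character(sample_id), status = status,
         covariates = covariates),
    class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d samples (%d cases / %d controls), %d covariates\n",
              length(x$sample_id), sum(x$status), sum(1L - x$status),
              ncol(x$covariates)))
  invisible(x)
}

#' @export
`[.cohort_table` <- function(x, i, ...) {
  cohort_table(x$sample_id[i], x$status[i],
               x$covariates[i, , drop = FALSE])
}

# Align a cohort table to a genotype matrix; errors on mismatch.
check_aligned <- function(genotypes, cohort) {
  if (!identical(genotypes$samples, cohort$sample_id))
    stop("genotype matrix and cohort table sample identifiers do not match")
  invisible(TRUE)
}
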