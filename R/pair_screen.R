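# Stage 1 of the two-step epistasis search: exhaustive, covariate-free
# approximate interaction screening of all marker pairs, BOOST-style. The
# screening statistic compares the saturated genotype x genotype x status
# distribution against its Kirkwood superposition approximation (KSA), a
# normalized product of the three two-way margins. Because the KSA statistic
# upper-bounds the exact homogeneous-association LRT, screening at a P
# threshold never discards a pair whose exact covariate-free P would pass the
# same threshold.

#' Encode a genotype matrix as per-genotype bit planes
#'
#' Builds, for every marker, three bit vectors over samples (one per genotype
#' class) packed into 64-bit words; missing calls set no bit, so the validity
#' vector is their union and every pair contingency table is obtained by
#' popcounts of AND-ed planes.
#'
#' @param genotypes a [genotype_matrix()].
#' @return an object of class `bit_planes` wrapping the packed store.
#' @export
encode_bit_planes <- function(genotypes) {
  ptr <- cpp_encode_planes(genotypes$dosage)
  structure(list(ptr = ptr, n = nrow(genotypes$dosage),
                 m = ncol(genotypes$dosage), ids = genotypes$markers$id),
            class = "bit_planes")
}

#' @export
print.bit_planes <- function(x, ...) {
  cat(sprintf("bit_planes: %d markers x %d samples\n", x$m, x$n))
  invisible(x)
}

#' Per-marker genotype-class and validity popcounts of a bit-plane store
#'
#' @param planes a [encode_bit_planes()] store.
#' @return integer matrix (markers x 4): counts of dosage 0, 1, 2 and valid
#'   (non-missing) calls.
#' @export
plane_popcounts <- function(planes) {
  out <- cpp_plane_popcounts(planes$ptr)
  dimnames(out) <- list(planes$ids, c("g0", "g1", "g2", "valid"))
  out
}

#' 2 x 3 x 3 status-by-genotype-by-genotype contingency table for one pair
#'
#' Counts are popcounts of AND-ed bit planes on pairwise-complete samples.
#'
#' @param planes a [encode_bit_planes()] store.
#' @param i,j marker indices or identifiers (distinct).
#' @param status 0/1 vector over samples.
#' @return integer array of dim `c(2, 3, 3)` indexed `[status + 1, g1 + 1,
#'   g2 + 1]`.
#' @export
pair_table <- function(planes, i, j, status) {
  if (is.character(i)) i <- match(i, planes$ids)
  if (is.character(j)) j <- match(j, planes$ids)
  if (is.na(i) || is.na(j) || i == j) stop("pair members must be distinct markers")
  v <- cpp_pair_table(planes$ptr, i, j, as.integer(status))
  array(v, dim = c(2, 3, 3),
        dimnames = list(y = c("0", "1"), g1 = 0:2, g2 = 0:2))
}

# column index helpers for the flat 18-count layout (y + 2*g1 + 6*g2)
.tab_idx <- local({
  g2 <- rep(0:2, each = 6)
  g1 <- rep(rep(0:2, each = 2), times = 3)
  y <- rep(0:1, times = 9)
  list(y = y, g1 = g1, g2 = g2)
})

# Vectorized KSA statistic over a matrix of flat 18-count tables (rows =
# pairs). Returns 2*[ll(saturated) - ll(KSA)]; empty cells contribute zero.
ksa_statistic_many <- function(counts) {
  counts <- matrix(as.numeric(counts), ncol = 18)
  idx <- .tab_idx
  agg <- function(fac) {
    u <- sort(unique(fac))
    A <- outer(fac, u, "==") * 1
    counts %*% A
  }
  f12 <- idx$g1 * 3 + idx$g2
  f1y <- idx$g1 * 2 + idx$y
  f2y <- idx$g2 * 2 + idx$y
  M12 <- agg(f12); M1y <- agg(f1y); M2y <- agg(f2y)
  M1 <- agg(idx$g1); M2 <- agg(idx$g2); My <- agg(idx$y)
  N <- rowSums(counts)

  # per-cell margin lookups (columns of the aggregated matrices)
  c12 <- f12 + 1L; c1y <- f1y + 1L; c2y <- f2y + 1L
  c1 <- idx$g1 + 1L; c2 <- idx$g2 + 1L; cy <- idx$y + 1L
  q_un <- matrix(0, nrow(counts), 18)
  for (k in 1:18) {
    den <- M1[, c1[k]] * M2[, c2[k]] * My[, cy[k]]
    num <- M12[, c12[k]] * M1y[, c1y[k]] * M2y[, c2y[k]]
    q_un[, k] <- ifelse(den > 0, num / den, 0)
  }
  tau <- rowSums(q_un)
  stat <- numeric(nrow(counts))
  for (k in 1:18) {
    n_k <- counts[, k]
    pos <- n_k > 0
    if (!any(pos)) next
    # n>0 implies every margin >0, hence q_un>0
    stat[pos] <- stat[pos] + n_k[pos] *
      (log(n_k[pos] / N[pos]) - log(q_un[pos, k] / tau[pos]))
  }
  2 * stat
}

#' BOOST-style KSA interaction statistic for one pair table
#'
#' The statistic is `2 * [ll(saturated) - ll(KSA)]`, where the saturated
#' log-likelihood uses observed cell proportions and the KSA distribution is
#' the normalized product of the three two-way margins divided by the one-way
#' margins. The approximate P is the upper tail of a chi-squared with 4 df.
#' Empty cells contribute zero (`0 * log 0 = 0`); genotype classes entirely
#' absent simply contribute nothing — the statistic never fails on degenerate
#' tables.
#'
#' @param table a 2x3x3 array from [pair_table()] (or an 18-count vector in
#'   its flat layout).
#' @return list with `statistic` and `p` (chi-squared 4 df upper tail).
#' @export
ksa_statistic <- function(table) {
  counts <- as.numeric(table)
  if (length(counts) != 18) stop("expected a 2x3x3 table")
  if (sum(counts) <= 0) stop("table total must be positive")
  stat <- ksa_statistic_many(matrix(counts, nrow = 1))
  list(statistic = stat, p = pchisq(stat, df = 4, lower.tail = FALSE))
}

#' Squared Pearson correlation of two dosage vectors
#'
#' Composite (unphased-dosage) LD estimate on pairwise-complete samples.
#'
#' @param genotypes a [genotype_matrix()].
#' @param i,j marker indices or identifiers.
#' @return r-squared in `[0, 1]`, or `NA` when either dosage has zero
#'   variance on the pairwise-complete subset.
#' @export
dosage_r2 <- function(genotypes, i, j) {
  if (is.character(i)) i <- match(i, genotypes$markers$id)
  if (is.character(j)) j <- match(j, genotypes$markers$id)
  x <- genotypes$dosage[, i]
  y <- genotypes$dosage[, j]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2 || sd(x) == 0 || sd(y) == 0) return(NA_real_)
  unname(cor(x, y)^2)
}

#' Exhaustive approximate interaction screen over all marker pairs
#'
#' Evaluates the KSA statistic for every unordered marker pair via bit-plane
#' popcounts, retains pairs with approximate P below `p_threshold`, then
#' applies the LD filter `r2 < r2_threshold` (squared dosage correlation;
#' pairs with undefined r-squared are excluded and logged). Output is ordered
#' by ascending approximate P, ties broken by marker identifiers.
#'
#' @param genotypes a QC-passed [genotype_matrix()].
#' @param cohort a [cohort_table()] aligned to `genotypes`.
#' @param p_threshold approximate-P retention threshold (default `1e-10`).
#' @param r2_threshold LD exclusion threshold (default `0.2`).
#' @param chunk_pairs approximate number of pairs per internal block
#'   (memory control only; results are identical for any value).
#' @return data.frame of class `pair_candidates`: `snp1`, `snp2`, `stat`,
#'   `p_approx`, `r2`, plus attributes `n_pairs_tested`, `n_pass_p`,
#'   `n_excluded_r2`, `n_undefined_r2`.
#' @export
screen_all_pairs <- function(genotypes, cohort, p_threshold = 1e-10,
                             r2_threshold = 0.2, chunk_pairs = 2e5) {
  check_aligned(genotypes, cohort)
  m <- ncol(genotypes$dosage)
  planes <- encode_bit_planes(genotypes)
  status <- as.integer(cohort$status)
  hits <- list()
  if (m >= 2) {
    # chunk rows of the pair triangle so tables stay within memory
    i <- 1L
    while (i <= m - 1L) {
      to <- i
      npairs <- m - i
      while (to < m - 1L && npairs + (m - to - 1L) <= chunk_pairs) {
        to <- to + 1L
        npairs <- npairs + (m - to)
      }
      blk <- cpp_block_tables(planes$ptr, status, i, to)
      stat <- ksa_statistic_many(blk$counts)
      logp <- pchisq(stat, df = 4, lower.tail = FALSE, log.p = TRUE)
      pass <- logp < log(p_threshold)
      if (any(pass)) {
        hits[[length(hits) + 1L]] <- data.frame(
          i = blk$i[pass], j = blk$j[pass], stat = stat[pass],
          p_approx = exp(logp[pass]))
      }
      i <- to + 1L
    }
  }
  n_tested <- if (m >= 2) m * (m - 1) / 2 else 0
  if (length(hits)) hits <- do.call(rbind, hits)
  else hits <- data.frame(i = integer(0), j = integer(0),
                          stat = numeric(0), p_approx = numeric(0))
  n_pass_p <- nrow(hits)
  # LD filter, applied after the P filter
  r2 <- vapply(seq_len(nrow(hits)), function(k)
    dosage_r2(genotypes, hits$i[k], hits$j[k]), numeric(1))
  undefined <- is.na(r2)
  keep <- !undefined & r2 < r2_threshold
  out <- data.frame(snp1 = genotypes$markers$id[hits$i[keep]],
                    snp2 = genotypes$markers$id[hits$j[keep]],
                    stat = hits$stat[keep], p_approx = hits$p_approx[keep],
                    r2 = r2[keep], stringsAsFactors = FALSE)
  out <- out[order(out$p_approx, out$snp1, out$snp2), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_pairs_tested") <- n_tested
  attr(out, "n_pass_p") <- n_pass_p
  attr(out, "n_excluded_r2") <- sum(!undefined & r2 >= r2_threshold)
  attr(out, "n_undefined_r2") <- sum(undefined)
  class(out) <- c("pair_candidates", "data.frame")
  out
}
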