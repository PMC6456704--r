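# Synthetic case-control cohort generator. Emulates a dense Immunochip-like
# region: biallelic SNPs in LD blocks (correlated latent Gaussian haplotype
# signals, thresholded, two haplotypes summed to a dosage — exact HWE
# marginals with tunable r^2), case-control status from a logistic model
# with planted additive SNPs and planted 3x3 epistatic matrices, batch
# effects, and two-subpopulation ancestry (Balding-Nichols allele-frequency
# divergence) captured downstream by genotype-derived PC covariates.
# Sampling is retrospective: a large population is simulated at a prevalence
# equal to the requested case fraction, then the requested numbers of cases
# and controls are drawn, keeping logistic effect sizes interpretable.

#' Simulation configuration
#'
#' @param n_cases,n_controls requested cohort sizes.
#' @param n_markers number of biallelic markers.
#' @param block_structure list of `c(length, rho)` pairs cycled across the
#'   markers: each LD block uses an AR(1) latent correlation `rho` in
#'   `[0, 1)` between adjacent markers, so marker pairs at distance `k`
#'   have latent correlation `rho^k` (r2 monotone non-increasing with
#'   distance in expectation).
#' @param maf_range interval in `(0, 0.5]` for ancestral allele frequencies
#'   (drawn uniformly).
#' @param additive_effects data.frame with columns `marker` (index) and
#'   `beta` (log-odds per allele2 copy), or `NULL`.
#' @param epistatic_effects list of `list(pair = c(i, j), beta = 3x3
#'   matrix)` of log-odds offsets indexed by `[g1 + 1, g2 + 1]`, or `NULL`.
#' @param n_batches genotyping batches; per-batch log-odds shifts are drawn
#'   `N(0, batch_effect_sd)` and batch dummies become covariates.
#' @param batch_effect_sd batch shift scale (log-odds).
#' @param n_subpops subpopulations; per-subpop allele frequencies are drawn
#'   Balding-Nichols around the ancestral frequency with divergence
#'   `fst_like_divergence`, and per-subpop log-odds shifts are drawn
#'   `N(0, subpop_effect_sd)`.
#' @param fst_like_divergence Fst-like divergence in `[0, 0.5)`.
#' @param subpop_effect_sd subpopulation shift scale (log-odds).
#' @param missing_rate uniform missing-call rate in `[0, 0.1]`.
#' @param n_pcs number of principal components added as covariates.
#' @param seed integer RNG seed; (config, seed) fully determines the output.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 10000, n_controls = 10000, n_markers = 300,
                       block_structure = list(c(20, 0.9)),
                       maf_range = c(0.05, 0.5),
                       additive_effects = NULL, epistatic_effects = NULL,
                       n_batches = 4, batch_effect_sd = 0.1,
                       n_subpops = 2, fst_like_divergence = 0.005,
                       subpop_effect_sd = 0.1,
                       missing_rate = 0.002, n_pcs = 5, seed = 1) {
  stopifnot(n_cases >= 1, n_controls >= 1, n_markers >= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            n_batches >= 1, batch_effect_sd >= 0,
            n_subpops >= 1, fst_like_divergence >= 0, fst_like_divergence < 0.5,
            missing_rate >= 0, missing_rate <= 0.1, n_pcs >= 0)
  for (b in block_structure)
    stopifnot(length(b) == 2, b[1] >= 1, b[2] >= 0, b[2] < 1)
  if (!is.null(additive_effects)) {
    additive_effects <- as.data.frame(additive_effects)
    stopifnot(all(c("marker", "beta") %in% names(additive_effects)),
              all(additive_effects$marker >= 1),
              all(additive_effects$marker <= n_markers))
  }
  if (!is.null(epistatic_effects)) {
    for (e in epistatic_effects) {
      stopifnot(length(e$pair) == 2, e$pair[1] != e$pair[2],
                all(e$pair >= 1), all(e$pair <= n_markers),
                all(dim(as.matrix(e$beta)) == c(3, 3)))
    }
  }
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_markers = as.integer(n_markers), block_structure = block_structure,
    maf_range = maf_range, additive_effects = additive_effects,
    epistatic_effects = epistatic_effects, n_batches = as.integer(n_batches),
    batch_effect_sd = batch_effect_sd, n_subpops = as.integer(n_subpops),
    fst_like_divergence = fst_like_divergence,
    subpop_effect_sd = subpop_effect_sd, missing_rate = missing_rate,
    n_pcs = as.integer(n_pcs), seed = as.integer(seed)),
    class = "sim_config")
}

# per-marker block id and AR(1) rho from the cycled block structure
.block_layout <- function(m, block_structure) {
  block <- integer(m); rho <- numeric(m)
  j <- 1L; b <- 1L; id <- 1L
  while (j <= m) {
    len <- min(block_structure[[b]][1], m - j + 1L)
    block[j:(j + len - 1L)] <- id
    rho[j:(j + len - 1L)] <- block_structure[[b]][2]
    j <- j + len
    id <- id + 1L
    b <- if (b == length(block_structure)) 1L else b + 1L
  }
  list(block = block, rho = rho)
}

# one haplotype matrix (nn x m of 0/1) under block-wise AR(1) latents, with
# subpopulation-specific thresholds
.sim_haplotype <- function(nn, freqs, subpop, block, rho) {
  m <- length(block)
  z <- matrix(0, nn, m)
  for (j in seq_len(m)) {
    if (j > 1 && block[j] == block[j - 1L])
      z[, j] <- rho[j] * z[, j - 1L] + sqrt(1 - rho[j]^2) * rnorm(nn)
    else
      z[, j] <- rnorm(nn)
  }
  thr <- qnorm(freqs)                       # n_subpops x m matrix of thresholds
  (z < thr[subpop, , drop = FALSE]) + 0L
}

# linear predictor without intercept for a dosage chunk
.sim_eta <- function(dos, config, batch_eff, subpop_eff, batch, subpop) {
  eta <- batch_eff[batch] + subpop_eff[subpop]
  ae <- config$additive_effects
  if (!is.null(ae) && nrow(ae))
    for (k in seq_len(nrow(ae)))
      eta <- eta + ae$beta[k] * dos[, ae$marker[k]]
  if (!is.null(config$epistatic_effects))
    for (e in config$epistatic_effects) {
      M <- as.matrix(e$beta)
      eta <- eta + M[cbind(dos[, e$pair[1]] + 1L, dos[, e$pair[2]] + 1L)]
    }
  eta
}

#' Simulate a case-control cohort with known genetic architecture
#'
#' See [sim_config()] for the generative model. The logistic intercept is
#' solved numerically (bisection on a large calibration population) so the
#' population prevalence equals `n_cases / (n_cases + n_controls)`; the
#' requested numbers of cases and controls are then sampled retrospectively.
#' Identical config (including seed) gives bit-identical output.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (a [genotype_matrix()]), `cohort` (a
#'   [cohort_table()] with PC and batch-dummy covariates), and `truth`
#'   (planted effects, per-sample subpopulation and batch labels, solved
#'   intercept, batch and subpopulation shifts, allele frequencies).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$n_markers
  N <- config$n_cases + config$n_controls
  target <- config$n_cases / N

  f_anc <- runif(m, config$maf_range[1], config$maf_range[2])
  lay <- .block_layout(m, config$block_structure)
  Fst <- config$fst_like_divergence
  freqs <- matrix(rep(f_anc, each = config$n_subpops),
                  nrow = config$n_subpops)
  if (config$n_subpops > 1 && Fst > 0) {
    shape <- (1 - Fst) / Fst
    for (k in seq_len(config$n_subpops))
      freqs[k, ] <- rbeta(m, f_anc * shape, (1 - f_anc) * shape)
    freqs <- pmin(pmax(freqs, 1e-4), 1 - 1e-4)
  }
  batch_eff <- if (config$n_batches > 1)
    rnorm(config$n_batches, 0, config$batch_effect_sd) else 0
  subpop_eff <- if (config$n_subpops > 1)
    rnorm(config$n_subpops, 0, config$subpop_effect_sd) else 0

  gen_chunk <- function(nn) {
    subpop <- sample.int(config$n_subpops, nn, replace = TRUE)
    batch <- sample.int(config$n_batches, nn, replace = TRUE)
    dos <- .sim_haplotype(nn, freqs, subpop, lay$block, lay$rho) +
           .sim_haplotype(nn, freqs, subpop, lay$block, lay$rho)
    eta <- .sim_eta(dos, config, batch_eff, subpop_eff, batch, subpop)
    list(dos = dos, eta = eta, subpop = subpop, batch = batch)
  }

  # intercept: population prevalence == requested case fraction
  calib <- gen_chunk(max(N, 5000L))
  prev <- function(c0) mean(plogis(c0 + calib$eta)) - target
  lo <- -30; hi <- 30
  if (prev(lo) > 0 || prev(hi) < 0)
    stop(sprintf(
      "unachievable case fraction %.4f: intercept search failed within [%g, %g] (planted effects too extreme)",
      target, lo, hi))
  intercept <- stats::uniroot(prev, c(lo, hi), tol = 1e-10)$root

  # retrospective sampling of cases and controls from the population
  need_case <- config$n_cases; need_ctrl <- config$n_controls
  dos_list <- list(); status_list <- list(); sub_list <- list(); bat_list <- list()
  chunk <- calib
  max_chunks <- 50L
  for (it in seq_len(max_chunks)) {
    y <- rbinom(length(chunk$eta), 1L, plogis(intercept + chunk$eta))
    take_case <- which(y == 1L)[seq_len(min(need_case, sum(y == 1L)))]
    take_ctrl <- which(y == 0L)[seq_len(min(need_ctrl, sum(y == 0L)))]
    take <- sort(c(take_case, take_ctrl))
    if (length(take)) {
      dos_list[[it]] <- chunk$dos[take, , drop = FALSE]
      status_list[[it]] <- y[take]
      sub_list[[it]] <- chunk$subpop[take]
      bat_list[[it]] <- chunk$batch[take]
      need_case <- need_case - length(take_case)
      need_ctrl <- need_ctrl - length(take_ctrl)
    }
    if (need_case == 0L && need_ctrl == 0L) break
    if (it == max_chunks)
      stop("unachievable case/control quota after ", max_chunks,
           " population chunks (intercept search bound [-30, 30])")
    chunk <- gen_chunk(max(2L * (need_case + need_ctrl), 1000L))
  }
  dos <- do.call(rbind, dos_list)
  status <- unlist(status_list)
  subpop <- unlist(sub_list)
  batch <- unlist(bat_list)

  # uniform missingness, applied after phenotype assignment
  if (config$missing_rate > 0) {
    miss <- runif(length(dos)) < config$missing_rate
    dos[miss] <- NA_integer_
  }

  samples <- sprintf("S%06d", seq_len(nrow(dos)))
  markers <- data.frame(
    id = sprintf("snp%04d", seq_len(m)), chrom = 6L,
    pos = 28700000L + (seq_len(m) - 1L) * 10000L,
    allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
  geno <- genotype_matrix(dos, markers, samples)

  covs <- matrix(numeric(0), nrow = nrow(dos), ncol = 0)
  if (config$n_pcs > 0) {
    pcs <- genotype_pcs(geno, config$n_pcs)
    covs <- cbind(covs, pcs)
  }
  if (config$n_batches > 1) {
    bd <- outer(batch, 2:config$n_batches, "==") * 1
    colnames(bd) <- paste0("batch", 2:config$n_batches)
    covs <- cbind(covs, bd)
  }
  cohort <- cohort_table(samples, status, covs)

  truth <- list(additive = config$additive_effects,
                epistatic = config$epistatic_effects,
                subpop = subpop, batch = batch,
                intercept = intercept, batch_effects = batch_eff,
                subpop_effects = subpop_eff,
                ancestral_freqs = f_anc,
                subpop_freqs = freqs)
  list(genotypes = geno, cohort = cohort, truth = truth)
}

#' Principal components of a genotype matrix
#'
#' Top components of the column-centered, column-scaled dosage matrix
#' (missing calls mean-imputed for this computation only).
#'
#' @param genotypes a [genotype_matrix()].
#' @param k number of components.
#' @return numeric matrix (samples x k) with columns `PC1..PCk`.
#' @export
genotype_pcs <- function(genotypes, k = 5) {
  X <- genotypes$dosage
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mu[j]
  }
  X <- sweep(X, 2, mu)
  sds <- apply(X, 2, sd)
  keep <- sds > 0
  X <- sweep(X[, keep, drop = FALSE], 2, sds[keep], "/")
  k <- min(k, ncol(X), nrow(X) - 1L)
  dec <- eigen(crossprod(X) / (nrow(X) - 1), symmetric = TRUE)
  pcs <- X %*% dec$vectors[, seq_len(k), drop = FALSE]
  colnames(pcs) <- paste0("PC", seq_len(k))
  pcs
}

#' Stratified split of a cohort into discovery and replication halves
#'
#' The split fraction is applied within cases and within controls
#' separately, so stratum counts differ from the exact fraction by at most
#' one; the partition is disjoint and exhaustive, and seeded.
#'
#' @param genotypes,cohort the full cohort.
#' @param fraction fraction assigned to the first (discovery) half.
#' @param seed integer seed for the stratified draw.
#' @return list with elements `discovery` and `replication`, each a list
#'   with `genotypes` and `cohort`.
#' @export
split_cohort <- function(genotypes, cohort, fraction = 0.5, seed = 1) {
  check_aligned(genotypes, cohort)
  stopifnot(fraction > 0, fraction < 1)
  set.seed(seed)
  idx1 <- integer(0)
  for (s in c(1L, 0L)) {
    stratum <- which(cohort$status == s)
    if (length(stratum) == 0L)
      stop("empty stratum: no samples with status ", s)
    n1 <- round(fraction * length(stratum))
    idx1 <- c(idx1, sort(sample(stratum, n1)))
  }
  idx1 <- sort(idx1)
  idx2 <- setdiff(seq_along(cohort$status), idx1)
  list(discovery = list(genotypes = genotypes[idx1, ],
                        cohort = cohort[idx1]),
       replication = list(genotypes = genotypes[idx2, ],
                          cohort = cohort[idx2]))
}

#' Write a simulated cohort to disk (PLINK triplet, covariates, truth JSON)
#'
#' @param sim result of [simulate_cohort()].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_synthetic_cohort <- function(sim, prefix) {
  write_plink(sim$genotypes, prefix, status = sim$cohort$status)
  write_covariates(sim$cohort, paste0(prefix, ".covar"))
  truth <- sim$truth
  truth$epistatic <- lapply(truth$epistatic, function(e)
    list(pair = e$pair, beta = as.matrix(e$beta)))
  jsonlite::write_json(truth, paste0(prefix, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(prefix)
}
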