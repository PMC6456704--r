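#' Maximum-likelihood logistic regression by IRLS
#'
#' Shared fitting engine for every model in the pipeline. Fits
#' `logit P(y = 1) = X beta` by iteratively reweighted least squares with
#' step-halving, declaring convergence when the log-likelihood change drops
#' below `1e-10` and the maximum coefficient change below `1e-8` (at most 100
#' iterations). Rank-deficient columns are dropped deterministically (pivoted
#' QR order) and reported; their coefficients are `NA`.
#'
#' Quasi-complete separation is flagged when some coefficient exceeds 15 in
#' absolute value on the logit scale while the likelihood is still improving;
#' no penalization is applied — callers decide how to treat flagged fits.
#'
#' @param X numeric design matrix including an intercept column.
#' @param y binary response vector (0/1).
#' @param weights optional non-negative case weights (grouped-data fits).
#' @param max_iter,ll_tol,beta_tol convergence controls.
#'
#' @return list with `coefficients` (named, `NA` for dropped columns),
#'   `loglik`, `vcov` (for retained columns), `se`, `fitted`, `converged`,
#'   `separation`, `dropped` (names of dropped columns), `n_iter`, `n`.
#' @export
logistic_fit <- function(X, y, weights = NULL,
                         max_iter = 100L, ll_tol = 1e-10, beta_tol = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (is.null(weights)) weights <- rep(1, length(y))
  stopifnot(length(weights) == length(y), all(weights >= 0))
  keep_obs <- weights > 0
  if (!all(keep_obs)) {
    X <- X[keep_obs, , drop = FALSE]
    y <- y[keep_obs]
    weights <- weights[keep_obs]
  }
  n <- nrow(X)
  if (n == 0L) stop("no observations with positive weight")
  wy <- sum(weights * y)
  if (wy == 0 || wy == sum(weights))
    stop("degenerate outcome: all observations share one status")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))

  # deterministic rank handling: pivoted QR on the weighted design
  qrX <- qr(X * sqrt(weights))
  rank <- qrX$rank
  pivot <- qrX$pivot
  kept <- sort(pivot[seq_len(rank)])
  dropped <- colnames(X)[setdiff(seq_len(ncol(X)), kept)]
  Xk <- X[, kept, drop = FALSE]
  p <- ncol(Xk)

  beta <- numeric(p)
  eta <- drop(Xk %*% beta)
  mu <- plogis(eta)
  ll_bern <- function(eta) {
    # log(1 + e^eta) computed stably for large |eta|
    lse <- ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta)))
    sum(weights * (y * eta - lse))
  }
  ll <- ll_bern(eta)
  converged <- FALSE
  separation <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w <- weights * mu * (1 - mu)
    w <- pmax(w, 1e-12)
    z <- eta + (y - mu) / pmax(mu * (1 - mu), 1e-12)
    # normal equations with Cholesky (fast path); pivoted QR as fallback
    fit <- tryCatch({
      H <- crossprod(Xk, Xk * w)
      b <- crossprod(Xk, w * z)
      drop(chol2inv(chol(H)) %*% b)
    }, error = function(e) NULL)
    if (is.null(fit))
      fit <- tryCatch(
        qr.coef(qr(Xk * sqrt(w)), sqrt(w) * z),
        error = function(e) NULL)
    if (is.null(fit) || anyNA(fit)) break
    step <- fit - beta
    # step-halving if the likelihood would decrease
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      eta_new <- drop(Xk %*% beta_new)
      ll_new <- ll_bern(eta_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-8) { beta_new <- beta; eta_new <- eta; ll_new <- ll; break }
    }
    dll <- abs(ll_new - ll)
    dbeta <- max(abs(beta_new - beta))
    beta <- beta_new; eta <- eta_new; mu <- plogis(eta); ll <- ll_new
    if (max(abs(beta)) > 15) separation <- TRUE
    if (dll < ll_tol && dbeta < beta_tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }

  w <- weights * mu * (1 - mu)
  info <- crossprod(Xk * sqrt(w))
  vcov <- tryCatch(solve(info), error = function(e)
    matrix(NA_real_, p, p))
  se_k <- sqrt(pmax(diag(vcov), 0))
  coef_full <- setNames(rep(NA_real_, ncol(X)), colnames(X))
  coef_full[kept] <- beta
  se_full <- setNames(rep(NA_real_, ncol(X)), colnames(X))
  se_full[kept] <- se_k
  dimnames(vcov) <- list(colnames(X)[kept], colnames(X)[kept])

  list(coefficients = coef_full, loglik = ll, vcov = vcov, se = se_full,
       fitted = mu, converged = converged, separation = separation,
       dropped = dropped, n_iter = iter, n = n)
}

#' Wald test P-value for one coefficient of a logistic fit
#'
#' @param fit result of [logistic_fit()].
#' @param term coefficient name.
#' @return two-sided P-value from the normal approximation, `NA` if the term
#'   was dropped or its SE is unavailable.
#' @export
wald_p <- function(fit, term) {
  b <- fit$coefficients[term]
  s <- fit$se[term]
  if (is.na(b) || is.na(s) || s <= 0) return(NA_real_)
  unname(2 * stats::pnorm(-abs(b / s)))
}
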