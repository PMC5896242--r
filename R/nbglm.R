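# Negative-binomial GLM fitting by iteratively reweighted least squares,
# vectorized across genes. All genes share one design matrix X; weights,
# working responses and coefficient updates are carried as genes x samples
# matrices so each IRLS sweep is a handful of dense matrix products. The
# per-gene normal equations (p x p with p small) are solved in a loop over
# the not-yet-converged genes only.
#
# Model per gene g:  y_gs ~ NB(mu_gs, alpha_g),  Var = mu + alpha mu^2,
#                    log mu_gs = x_s' beta_g + offset_s
# Offsets carry the log size factors so coefficients are on the normalized
# scale.

#' Fit per-gene negative-binomial GLMs with a shared design matrix
#'
#' Workhorse used by [fit_contrasts()] and [interaction_test()]. Coefficients
#' are on the natural-log scale; IRLS stops for a gene when the largest
#' absolute coefficient change drops below `tol`, and genes that have not
#' converged after `max_iter` sweeps are flagged.
#'
#' @param counts integer matrix, genes x samples.
#' @param X design matrix, samples x coefficients (full column rank).
#' @param offset per-sample offset on the natural-log scale (typically
#'   `log(size_factors)`), recycled across genes.
#' @param alpha per-gene NB dispersion (variance = mu + alpha * mu^2);
#'   recycled if length 1. `alpha = 0` gives a Poisson fit.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   coefficient scale.
#' @return list with `coef` (genes x p, natural log), `mu` (fitted means),
#'   `converged` (logical), `iter` (sweeps used).
#' @keywords internal
nb_glm_fit <- function(counts, X, offset, alpha, max_iter = 50L, tol = 1e-8) {
  Y <- as.matrix(counts)
  storage.mode(Y) <- "double"
  G <- nrow(Y)
  n <- ncol(Y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, length(offset) == n)
  alpha <- rep_len(alpha, G)
  off <- matrix(offset, G, n, byrow = TRUE)

  # warm start: OLS on shifted log counts
  z0 <- log(Y + 0.5) - off
  beta <- t(solve(crossprod(X), crossprod(X, t(z0))))

  # index pairs for the upper triangle of X'WX, so the per-gene cross
  # products come out of a single (G x n) %*% (n x npairs) product
  ut <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  Xpairs <- X[, ut[, 1], drop = FALSE] * X[, ut[, 2], drop = FALSE]

  converged <- rep(FALSE, G)
  iter_used <- rep(NA_integer_, G)
  ridge <- diag(1e-10, p)

  for (it in seq_len(max_iter)) {
    active <- which(!converged)
    if (length(active) == 0L) break
    eta <- tcrossprod(beta, X) + off
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - off) + (Y - mu) / mu
    M <- w %*% Xpairs
    U <- (w * z) %*% X
    A <- matrix(0, p, p)
    for (g in active) {
      A[ut] <- M[g, ]
      A[lower.tri(A)] <- t(A)[lower.tri(A)]
      bg <- tryCatch(solve(A + ridge, U[g, ]),
                     error = function(e) rep(NA_real_, p))
      if (anyNA(bg)) {
        converged[g] <- FALSE
        beta[g, ] <- NA_real_
        iter_used[g] <- it
        next
      }
      if (max(abs(bg - beta[g, ])) < tol) {
        converged[g] <- TRUE
        iter_used[g] <- it
      }
      beta[g, ] <- bg
    }
    # genes that went NA stay out of further sweeps
    converged[!is.finite(rowSums(beta))] <- TRUE
  }
  failed <- !is.finite(rowSums(beta))
  converged[failed] <- FALSE

  eta <- tcrossprod(ifelse(is.finite(beta), beta, 0), X) + off
  eta <- pmin(pmax(eta, -30), 30)
  mu <- exp(eta)
  mu[failed, ] <- NA_real_
  list(coef = beta, mu = mu, converged = converged, iter = iter_used)
}

#' Wald statistics for a linear contrast of NB GLM coefficients
#'
#' @param fit result of [nb_glm_fit()].
#' @param X the design matrix the fit used.
#' @param alpha per-gene dispersions used in the fit.
#' @param contrast numeric vector of length `ncol(X)`.
#' @return data.frame with `estimate` (natural log), `se`, `stat`, `p`.
#' @keywords internal
nb_wald <- function(fit, X, alpha, contrast) {
  G <- nrow(fit$coef)
  p <- ncol(X)
  alpha <- rep_len(alpha, G)
  stopifnot(length(contrast) == p)
  est <- as.numeric(fit$coef %*% contrast)
  se <- rep(NA_real_, G)
  ut <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  Xpairs <- X[, ut[, 1], drop = FALSE] * X[, ut[, 2], drop = FALSE]
  w <- fit$mu / (1 + alpha * fit$mu)
  ok <- fit$converged & is.finite(rowSums(w))
  M <- w %*% Xpairs
  A <- matrix(0, p, p)
  for (g in which(ok)) {
    A[ut] <- M[g, ]
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    v <- tryCatch(drop(crossprod(contrast, solve(A, contrast))),
                  error = function(e) NA_real_)
    if (is.finite(v) && v >= 0) se[g] <- sqrt(v)
  }
  stat <- est / se
  data.frame(estimate = est, se = se, stat = stat,
             p = 2 * pnorm(-abs(stat)))
}
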