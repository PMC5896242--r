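# Dispersion estimation for the NB GLM stage.
#
# Per-gene dispersions solve the Pearson moment equation
#     sum_s (y_s - mu_s)^2 / (mu_s + alpha mu_s^2)  =  n - p
# (the generalized-Pearson chi-square matched to its residual degrees of
# freedom); the left side is monotone decreasing in alpha so the root is
# found by bisection, vectorized across genes. Because a handful of
# residual degrees of freedom make the gene-wise root very noisy, a
# mean-dispersion trend is estimated by pooling genes into expression bins
# and solving the same equation per bin, and the working dispersion is the
# MAXIMUM of the gene-wise and trend values — deliberately conservative, so
# that genes whose dispersion is underestimated by chance do not inflate
# their Wald statistics.

# Solve the pooled Pearson equation on a set of genes. resid2, mu are
# matrices (rows = genes); target = n_genes * (n - p).
pearson_alpha_pooled <- function(resid2, mu, target, lo = 0, hi = 10) {
  f <- function(a) sum(resid2 / (mu + a * mu^2)) - target
  if (f(lo) <= 0) return(lo)
  if (f(hi) >= 0) return(hi)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Vectorized per-gene bisection of the same equation; returns 0 for genes
# already underdispersed at alpha = 0.
pearson_alpha_genewise <- function(resid2, mu, df, hi = 10) {
  G <- nrow(mu)
  fval <- function(a) rowSums(resid2 / (mu + a * mu^2)) - df
  lo <- rep(0, G)
  up <- rep(hi, G)
  at_zero <- fval(rep(0, G)) <= 0
  at_hi <- fval(rep(hi, G)) >= 0
  for (i in 1:60) {
    mid <- (lo + up) / 2
    pos <- fval(mid) > 0
    lo[pos] <- mid[pos]
    up[!pos] <- mid[!pos]
  }
  out <- (lo + up) / 2
  out[at_zero] <- 0
  out[at_hi] <- hi
  out
}

#' Estimate per-gene NB dispersions (Pearson matching + pooled trend)
#'
#' Two-stage procedure. A Poisson GLM under the full design gives initial
#' fitted means and a single pooled dispersion; the means are refitted at
#' that pooled value so the Pearson statistic sees approximately correct
#' weights. Gene-wise dispersions then solve the Pearson moment equation
#' against the residual degrees of freedom, a mean-dispersion trend is
#' obtained by pooling genes into expression bins and solving the same
#' equation per bin, and the working dispersion per gene is
#' `max(gene-wise, trend)` clamped to `[1e-8, 10]`. Degenerate genes
#' (zero variance, or no finite gene-wise root) receive the trend value.
#'
#' @param counts filtered counts matrix, genes x samples.
#' @param design sample sheet (see [sample_design()]).
#' @param size_factors optional precomputed size factors.
#' @param design_type `"paired"` (`~ dog + biopsy`) or `"interaction"`
#'   (two-cohort nested model); sets the mean model used for residuals.
#' @param n_bins number of expression bins for the trend (capped so each
#'   bin keeps >= 20 genes).
#' @return data.frame with `gene_id`, `base_mean`, `alpha_gene`,
#'   `alpha_trend`, `alpha` (the working value) and `method`; the pooled
#'   initial dispersion is in `attr(, "alpha_pooled")`.
#' @export
estimate_dispersions <- function(counts, design, size_factors = NULL,
                                 design_type = c("paired", "interaction"),
                                 n_bins = 20L) {
  design_type <- match.arg(design_type)
  counts <- as.matrix(counts)
  design <- sample_design(design)
  counts <- counts[, design$sample_id, drop = FALSE]
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  X <- if (design_type == "paired") design_matrix_paired(design)
       else design_matrix_interaction(design)
  n <- ncol(counts)
  p <- ncol(X)
  if (n <= p) stop("design leaves no residual degrees of freedom")
  df <- n - p
  off <- log(size_factors)

  fit0 <- nb_glm_fit(counts, X, off, alpha = 0)
  ok0 <- fit0$converged
  a_pool <- pearson_alpha_pooled((counts - fit0$mu)[ok0, , drop = FALSE]^2,
                                 fit0$mu[ok0, , drop = FALSE],
                                 target = sum(ok0) * df)
  fit1 <- nb_glm_fit(counts, X, off, alpha = a_pool)
  mu <- fit1$mu
  ok <- fit1$converged & is.finite(rowSums(mu)) & rowSums(counts) > 0
  resid2 <- (counts - mu)^2

  alpha_gene <- rep(NA_real_, nrow(counts))
  alpha_gene[ok] <- pearson_alpha_genewise(resid2[ok, , drop = FALSE],
                                           mu[ok, , drop = FALSE], df)
  base_mean <- rowMeans(sweep(counts, 2, size_factors, "/"))

  # pooled trend over expression bins
  alpha_trend <- rep(1e-8, nrow(counts))
  idx <- which(ok)
  if (length(idx) >= 20) {
    nb <- max(1L, min(as.integer(n_bins), length(idx) %/% 20L))
    ord <- idx[order(base_mean[idx])]
    bin <- cut(seq_along(ord), breaks = nb, labels = FALSE)
    bin_alpha <- numeric(nb)
    bin_mean <- numeric(nb)
    for (b in seq_len(nb)) {
      gs <- ord[bin == b]
      bin_alpha[b] <- pearson_alpha_pooled(resid2[gs, , drop = FALSE],
                                           mu[gs, , drop = FALSE],
                                           target = length(gs) * df)
      bin_mean[b] <- median(base_mean[gs])
    }
    if (nb == 1L) {
      alpha_trend[] <- bin_alpha
    } else {
      tr <- approx(x = log(bin_mean), y = bin_alpha,
                   xout = log(pmax(base_mean, min(bin_mean))),
                   rule = 2)$y
      alpha_trend <- tr
    }
  } else if (length(idx) > 0) {
    alpha_trend[] <- median(alpha_gene[idx])
  }
  alpha_trend <- pmin(pmax(alpha_trend, 1e-8), 10)

  alpha <- pmax(pmin(pmax(alpha_gene, 1e-8), 10), alpha_trend)
  method <- ifelse(is.finite(alpha_gene) & alpha_gene >= alpha_trend,
                   "gene-wise", "trend")
  sel <- !is.finite(alpha)
  alpha[sel] <- alpha_trend[sel]
  method[sel] <- "trend"
  out <- data.frame(gene_id = rownames(counts),
                    base_mean = base_mean,
                    alpha_gene = alpha_gene,
                    alpha_trend = alpha_trend,
                    alpha = alpha,
                    method = method,
                    row.names = NULL)
  attr(out, "alpha_pooled") <- a_pool
  out
}
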