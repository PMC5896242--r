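#' Per-contrast NB GLM differential expression over the paired design
#'
#' Fits each gene's counts to a negative-binomial GLM with design
#' `~ dog + biopsy` (dog columns absorb the pairing between serial biopsies
#' of the same animal), log size factors as offsets and gene-wise
#' dispersions from [estimate_dispersions()], then Wald-tests the requested
#' pairwise biopsy contrasts. Fold changes are `2^coefficient`, i.e. read
#' off the model, not recomputed from normalized means. Genes with zero
#' counts in every sample, or whose IRLS fit did not converge, carry the
#' not-tested marker (`tested = FALSE`, numeric columns `NA`) and are
#' excluded from the Benjamini-Hochberg denominator.
#'
#' @param counts filtered counts, genes x samples (apply
#'   [filter_low_expression()] first).
#' @param design sample sheet (see [sample_design()]); all samples must be
#'   from a single regression-status arm or the pairing is still valid but
#'   the biopsy effects average over arms.
#' @param contrasts character vector among `"S_vs_P"`, `"R_vs_S"`,
#'   `"R_vs_P"`, `"B2_vs_B1"`, `"B3_vs_B1"`. Defaults to the three phase
#'   contrasts when biopsy 3 is present, else `"B2_vs_B1"`.
#' @param size_factors,dispersions optional precomputed values.
#' @return named list of data.frames (one per contrast), each with columns
#'   `gene_id`, `base_mean`, `log2fc`, `se` (log2 scale), `p`, `padj`,
#'   `tested`.
#' @export
fit_contrasts <- function(counts, design, contrasts = NULL,
                          size_factors = NULL, dispersions = NULL) {
  counts <- as.matrix(counts)
  design <- sample_design(design)
  counts <- counts[, design$sample_id, drop = FALSE]
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(counts, design, size_factors)
  alpha <- dispersions$alpha[match(rownames(counts), dispersions$gene_id)]
  X <- design_matrix_paired(design)
  if (ncol(counts) <= ncol(X))
    stop("design leaves no residual degrees of freedom")
  if (is.null(contrasts)) {
    contrasts <- if (3L %in% design$biopsy) c("S_vs_P", "R_vs_S", "R_vs_P")
                 else "B2_vs_B1"
  }
  fit <- nb_glm_fit(counts, X, log(size_factors), alpha)
  base_mean <- rowMeans(sweep(counts, 2, size_factors, "/"))
  testable <- fit$converged & rowSums(counts) > 0
  n_failed <- sum(!fit$converged)
  if (n_failed > 0)
    warning(n_failed, " gene(s) failed IRLS convergence; marked not-tested")

  out <- lapply(contrasts, function(cname) {
    cv <- paired_contrast(X, cname)
    w <- nb_wald(fit, X, alpha, cv)
    res <- data.frame(gene_id = rownames(counts),
                      base_mean = base_mean,
                      log2fc = w$estimate / log(2),
                      se = w$se / log(2),
                      p = w$p,
                      padj = NA_real_,
                      tested = testable & is.finite(w$p),
                      row.names = NULL)
    res$log2fc[!res$tested] <- NA_real_
    res$se[!res$tested] <- NA_real_
    res$p[!res$tested] <- NA_real_
    res$padj[res$tested] <- adjust_bh(res$p[res$tested])
    res
  })
  names(out) <- contrasts
  out
}

#' Benjamini-Hochberg adjusted p values
#'
#' Classic step-up false-discovery-rate adjustment (monotone, capped at 1),
#' applied to tested genes only — exclude not-tested markers before
#' calling.
#'
#' @param p numeric vector of p values in `[0, 1]`, no `NA`.
#' @return numeric vector of adjusted p values, same order as `p`.
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
adjust_bh <- function(p) {
  if (anyNA(p)) stop("p contains NA; exclude not-tested genes first")
  if (any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call significant genes at fold-change and adjusted-p cutoffs
#'
#' A gene is called iff `|log2fc| > log2(fc_threshold)` **and**
#' `padj < alpha`, both strict, mirroring the study cutoffs FC > 10 and
#' adjusted p < 0.01. Direction is the sign of the fold change.
#'
#' @param result one contrast's data.frame from [fit_contrasts()].
#' @param fc_threshold fold-change cutoff on the natural scale (default 10).
#' @param alpha adjusted-p cutoff (default 0.01).
#' @return data.frame `gene_id`, `direction` (+1 up, -1 down), `log2fc`,
#'   `padj` — the directed significant set.
#' @export
call_significant <- function(result, fc_threshold = 10, alpha = 0.01) {
  stopifnot(fc_threshold > 0, alpha > 0)
  keep <- result$tested &
    abs(result$log2fc) > log2(fc_threshold) &
    result$padj < alpha
  keep[is.na(keep)] <- FALSE
  data.frame(gene_id = result$gene_id[keep],
             direction = sign(result$log2fc[keep]),
             log2fc = result$log2fc[keep],
             padj = result$padj[keep],
             row.names = NULL)
}

#' Test whether the biopsy-2 response differs between regression statuses
#'
#' Fits the two-cohort nested model
#' `~ regression + regression:dog + regression:time` and Wald-tests the
#' difference of the biopsy-2 time effect between the regressive and
#' non-regressive arms (the R-B2/R-B1 versus NR-B2/NR-B1 comparison).
#' Per the study's phrasing, the significance cut for this test is a raw
#' p < 0.05; `adjusted = TRUE` switches the returned `padj` threshold use
#' to BH-adjusted values for callers that prefer it.
#'
#' @param counts filtered counts, genes x samples.
#' @param design sample sheet containing both statuses, two biopsies per
#'   dog, and at least two dogs per arm.
#' @param size_factors,dispersions optional precomputed values.
#' @return data.frame as in [fit_contrasts()] (contrast name
#'   `"interaction"`); `log2fc` is the between-arm difference of
#'   within-dog log2 fold changes.
#' @export
interaction_test <- function(counts, design, size_factors = NULL,
                             dispersions = NULL) {
  counts <- as.matrix(counts)
  design <- sample_design(design)
  counts <- counts[, design$sample_id, drop = FALSE]
  if (length(unique(design$regression_status)) < 2)
    stop("interaction test needs both regression statuses")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(counts, design, size_factors,
                                        design_type = "interaction")
  alpha <- dispersions$alpha[match(rownames(counts), dispersions$gene_id)]
  X <- design_matrix_interaction(design)
  if (ncol(counts) <= ncol(X))
    stop("design leaves no residual degrees of freedom")
  cn <- colnames(X)
  c_reg <- grep("statusREGRESSIVE:biopsy2", cn, fixed = TRUE)
  c_non <- grep("statusNON_REGRESSIVE:biopsy2", cn, fixed = TRUE)
  if (length(c_reg) != 1L || length(c_non) != 1L)
    stop("interaction design must contain biopsy-2 time effects in both arms")
  cv <- numeric(ncol(X))
  cv[c_reg] <- 1
  cv[c_non] <- -1

  fit <- nb_glm_fit(counts, X, log(size_factors), alpha)
  w <- nb_wald(fit, X, alpha, cv)
  base_mean <- rowMeans(sweep(counts, 2, size_factors, "/"))
  testable <- fit$converged & rowSums(counts) > 0 & is.finite(w$p)
  res <- data.frame(gene_id = rownames(counts),
                    base_mean = base_mean,
                    log2fc = w$estimate / log(2),
                    se = w$se / log(2),
                    p = w$p,
                    padj = NA_real_,
                    tested = testable,
                    row.names = NULL)
  res$log2fc[!res$tested] <- NA_real_
  res$se[!res$tested] <- NA_real_
  res$p[!res$tested] <- NA_real_
  res$padj[res$tested] <- adjust_bh(res$p[res$tested])
  res
}

#' Genes significant in the interaction test
#'
#' @param result data.frame from [interaction_test()].
#' @param alpha significance cut (default 0.05).
#' @param adjusted compare `padj` instead of raw `p` (default `FALSE`,
#'   matching the study's raw p < 0.05 phrasing).
#' @return directed significant set as in [call_significant()] (direction
#'   is the sign of the between-arm difference).
#' @export
call_interaction <- function(result, alpha = 0.05, adjusted = FALSE) {
  pv <- if (adjusted) result$padj else result$p
  keep <- result$tested & pv < alpha
  keep[is.na(keep)] <- FALSE
  data.frame(gene_id = result$gene_id[keep],
             direction = sign(result$log2fc[keep]),
             log2fc = result$log2fc[keep],
             padj = result$padj[keep],
             row.names = NULL)
}
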