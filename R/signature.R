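#' Venn counts and percent overlap between two gene sets
#'
#' Reports `|A\B|`, `|A∩B|`, `|B\A|` and the percentage of the first set
#' shared with the second, truncated to one decimal — the convention under
#' which 648 of 1016 genes prints as 63.7% — always computed as
#' `100 * |A∩B| / |A|`.
#'
#' @param A,B character vectors of gene ids (duplicates ignored).
#' @return list with `a_only`, `shared`, `b_only`, `percent_of_a`
#'   (`NA` with a warning when `A` is empty).
#' @export
set_overlap <- function(A, B) {
  A <- unique(as.character(A))
  B <- unique(as.character(B))
  shared <- length(intersect(A, B))
  out <- list(a_only = length(setdiff(A, B)),
              shared = shared,
              b_only = length(setdiff(B, A)),
              percent_of_a = NA_real_)
  if (length(A) == 0) {
    warning("first set is empty; percent overlap undefined")
  } else {
    out$percent_of_a <- floor(1000 * shared / length(A)) / 10
  }
  out
}

#' Core-regression-signature set algebra
#'
#' From the directed significant sets of the two experiments:
#' `candidate = sig_reg_7xx ∩ sig_interaction` (genes significant in the
#' regressing two-biopsy cohort whose response also differs between
#' regression statuses), and
#' `core = candidate ∩ sig_C5 \ sig_C6` (additionally significant in the
#' fully regressing index case but not in the non-regressing one).
#' Genes whose direction disagrees between `sig_reg_7xx` and `sig_C5` are
#' retained but flagged.
#'
#' @param sig_reg_7xx directed significant set, regressive-cohort B2/B1.
#' @param sig_interaction significant set from [call_interaction()].
#' @param sig_C5,sig_C6 directed significant sets of the two index cases.
#' @return list with `candidate` and `core` (data.frames `gene_id`,
#'   `direction`, `discordant`), plus the input set sizes in `sizes`.
#' @export
core_signature <- function(sig_reg_7xx, sig_interaction, sig_C5, sig_C6) {
  cand_ids <- intersect(sig_reg_7xx$gene_id, sig_interaction$gene_id)
  core_ids <- setdiff(intersect(cand_ids, sig_C5$gene_id), sig_C6$gene_id)
  mk <- function(ids) {
    i <- match(ids, sig_reg_7xx$gene_id)
    j <- match(ids, sig_C5$gene_id)
    data.frame(gene_id = ids,
               direction = sig_reg_7xx$direction[i],
               discordant = !is.na(j) &
                 sig_reg_7xx$direction[i] != sig_C5$direction[j],
               row.names = NULL)
  }
  list(candidate = mk(cand_ids),
       core = mk(core_ids),
       sizes = c(sig_reg_7xx = length(unique(sig_reg_7xx$gene_id)),
                 sig_interaction = length(unique(sig_interaction$gene_id)),
                 candidate = length(cand_ids),
                 core = length(core_ids)))
}

#' Log2 expression relative to a geometric-mean baseline, sorted
#'
#' Builds the heatmap matrix: each entry is
#' `log2(x + pc) - mean_b log2(x_b + pc)` over the baseline samples, i.e.
#' expression relative to the geometric mean of the baselines (mean of the
#' logs). Rows are sorted descending by the chosen sort column's relative
#' expression (for three-biopsy designs the final-biopsy column; for
#' two-biopsy designs the geometric mean over the biopsy-2 columns of the
#' sort samples).
#'
#' @param normalized_counts genes x samples matrix of normalized counts.
#' @param baseline_sample_ids samples forming the baseline geometric mean.
#' @param sort_sample_ids samples whose mean relative expression keys the
#'   row order (default: all non-baseline samples).
#' @param pseudocount added inside the logs (default 1; use 0 only when
#'   all involved values are positive).
#' @return numeric matrix (same columns, rows reordered) with the sort key
#'   in `attr(, "sort_key")`.
#' @export
build_heatmap_matrix <- function(normalized_counts, baseline_sample_ids,
                                 sort_sample_ids = NULL, pseudocount = 1) {
  x <- as.matrix(normalized_counts)
  stopifnot(pseudocount >= 0)
  if (length(baseline_sample_ids) == 0) stop("baseline sample set is empty")
  if (!all(baseline_sample_ids %in% colnames(x)))
    stop("unknown baseline sample id")
  lx <- log2(x + pseudocount)
  rel <- lx - rowMeans(lx[, baseline_sample_ids, drop = FALSE])
  if (is.null(sort_sample_ids))
    sort_sample_ids <- setdiff(colnames(x), baseline_sample_ids)
  key <- rowMeans(rel[, sort_sample_ids, drop = FALSE])
  out <- rel[order(key, decreasing = TRUE), , drop = FALSE]
  attr(out, "sort_key") <- sort(key, decreasing = TRUE)
  out
}

#' Pearson concordance of log2 fold changes between two experiments
#'
#' @param resultA,resultB contrast data.frames from [fit_contrasts()].
#' @param gene_subset optional gene ids to restrict to (e.g. a significant
#'   set); defaults to all genes tested in both.
#' @return list with `r` (Pearson correlation), `n_used`, `n_excluded`
#'   (genes not tested in either experiment).
#' @export
logfc_concordance <- function(resultA, resultB, gene_subset = NULL) {
  common <- intersect(resultA$gene_id, resultB$gene_id)
  if (!is.null(gene_subset)) common <- intersect(common, gene_subset)
  a <- resultA$log2fc[match(common, resultA$gene_id)]
  b <- resultB$log2fc[match(common, resultB$gene_id)]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) stop("need >= 3 genes with finite log2fc in both")
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0)
    stop("zero variance in a fold-change vector")
  list(r = cor(a[ok], b[ok]), n_used = sum(ok), n_excluded = sum(!ok))
}

#' Rank genes by their residual from the between-tumor best-fit line
#'
#' Regresses `log2(B + 1)` on `log2(A + 1)` by ordinary least squares and
#' ranks genes by absolute residual — the screen used to spot genes (such
#' as CCL5) whose induction in the regressing tumor far exceeds the trend
#' shared with the non-regressing one.
#'
#' @param mean_expr_A,mean_expr_B named numeric vectors of mean normalized
#'   expression per gene (names are gene ids, shared).
#' @return data.frame `gene_id`, `residual` (signed, log2 units), `rank`
#'   (1 = largest absolute residual), sorted by rank.
#' @export
rank_outliers <- function(mean_expr_A, mean_expr_B) {
  genes <- intersect(names(mean_expr_A), names(mean_expr_B))
  if (length(genes) < 3) stop("need >= 3 shared genes")
  a <- log2(mean_expr_A[genes] + 1)
  b <- log2(mean_expr_B[genes] + 1)
  if (sd(a) == 0) stop("zero variance in the predictor expression vector")
  fit <- lm(b ~ a)
  res <- stats::resid(fit)
  ord <- order(abs(res), decreasing = TRUE)
  data.frame(gene_id = genes[ord], residual = unname(res[ord]),
             rank = seq_along(ord), row.names = NULL)
}

#' Mean z-score signature enrichment with a rank-sum group comparison
#'
#' Per-sample enrichment score = mean over the signature genes of each
#' gene's within-gene z-score across samples; two sample groups are
#' compared by a two-sided Wilcoxon rank-sum test. This is a generic
#' signature score (the field reports "relative enrichment" without a
#' formula); treat it as a screening statistic.
#'
#' @param expr_matrix genes x samples expression matrix (any monotone
#'   scale; log-scale recommended).
#' @param gene_set character vector of signature gene ids.
#' @param sample_groups factor/character vector over columns with exactly
#'   two levels, each with >= 2 samples, or `NULL` to skip the test.
#' @return list with `scores` (named per-sample), `p` (rank-sum p or `NA`),
#'   `n_genes_used`.
#' @export
signature_enrichment <- function(expr_matrix, gene_set, sample_groups = NULL) {
  x <- as.matrix(expr_matrix)
  if (length(gene_set) == 0) stop("empty gene set")
  gs <- intersect(gene_set, rownames(x))
  if (length(gs) == 0) stop("gene set shares no genes with the matrix")
  sub <- x[gs, , drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1, sd)
  keep <- sdv > 0
  if (!any(keep)) stop("all signature genes are constant across samples")
  z <- (sub[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  scores <- colMeans(z)
  p <- NA_real_
  if (!is.null(sample_groups)) {
    g <- factor(sample_groups)
    if (nlevels(g) != 2 || any(table(g) < 2))
      stop("sample_groups needs two levels with >= 2 samples each")
    p <- wilcox.test(scores[g == levels(g)[1]],
                     scores[g == levels(g)[2]], exact = TRUE)$p.value
  }
  list(scores = scores, p = p, n_genes_used = sum(keep))
}
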