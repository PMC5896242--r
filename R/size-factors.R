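#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median across reference
#' genes of the ratio between a sample's count and the gene's geometric mean
#' across samples. The reference set is the genes with a positive count in
#' every sample; if that set is empty the function falls back, with a
#' warning, to genes positive in at least half of the samples (their
#' geometric means taken over positive entries). Factors are rescaled to
#' have geometric mean one, so normalized counts `counts / factor` stay on
#' the raw count scale.
#'
#' @param counts non-negative integer matrix, genes x samples, with sample
#'   column names.
#' @return named numeric vector of positive size factors, geometric mean 1.
#' @examples
#' m <- cbind(A = c(1, 2, 4), B = c(2, 4, 8))
#' estimate_size_factors(m) # c(1/sqrt(2), sqrt(2))
#' @export
estimate_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0)) stop("cannot estimate size factors from an all-zero matrix")
  if (any(colSums(counts) == 0)) stop("every sample needs at least one nonzero count")
  ref <- rowSums(counts > 0) == ncol(counts)
  if (any(ref)) {
    logc <- log(counts[ref, , drop = FALSE])
    logratio <- logc - rowMeans(logc)
    sf <- exp(apply(logratio, 2, median))
  } else {
    warning("no gene is positive in all samples; falling back to genes ",
            "positive in >= 50% of samples")
    ref <- rowSums(counts > 0) >= ncol(counts) / 2
    if (!any(ref)) stop("no usable reference genes for size-factor estimation")
    logc <- log(counts[ref, , drop = FALSE])
    logc[!is.finite(logc)] <- NA
    logratio <- logc - rowMeans(logc, na.rm = TRUE)
    sf <- exp(apply(logratio, 2, median, na.rm = TRUE))
  }
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(counts)
  sf
}

#' Remove low-expression genes by total-count quantile
#'
#' Drops the genes whose total count across all samples falls in the lowest
#' `quantile` of the row-sum distribution: a gene is retained iff its row
#' sum is at least the empirical quantile value (so when all row sums tie
#' at the cutoff, everything is retained). Removed genes must be excluded
#' from all downstream tests and from adjusted-p denominators.
#'
#' @param counts non-negative integer matrix, genes x samples, rownames are
#'   gene ids.
#' @param quantile fraction in `[0, 1)`; default 0.40.
#' @return character vector of retained gene ids (row names), in input order.
#' @export
filter_low_expression <- function(counts, quantile = 0.40) {
  stopifnot(is.numeric(quantile), length(quantile) == 1L,
            quantile >= 0, quantile < 1)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must carry gene ids as rownames")
  rs <- rowSums(counts)
  cut <- stats::quantile(rs, quantile, names = FALSE)
  rownames(counts)[rs >= cut]
}
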