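#' Meta-gene methylation profiles (7 features x 20 bins) per biopsy
#'
#' For every gene, each of its seven feature regions is split into
#' `n_bins` equal bins along transcription and the length-weighted mean
#' track signal is taken per bin, giving a 7 x 20 = 140-value vector per
#' gene per biopsy. Absent features (single- or two-exon genes) carry
#' `NA` and are excluded from list-level means, never imputed as zero.
#'
#' @param gene_models exon data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`) covering the requested genes.
#' @param gene_ids genes to profile.
#' @param tracks named list of methylation tracks, one per biopsy (names
#'   e.g. `"B1"`, `"B2"`, `"B3"`).
#' @param n_bins bins per feature (default 20).
#' @param flank flank length for the 2 kb features.
#' @param normalize scale each track to mean genome signal 1 first
#'   (default `TRUE`; set `FALSE` when signals are already comparable).
#' @return long data.frame `gene_id`, `biopsy`, `feature`, `bin`, `value`
#'   (`NA` for absent features), with `feature` ordered as
#'   [META_FEATURES].
#' @export
metagene_profile <- function(gene_models, gene_ids, tracks, n_bins = 20L,
                             flank = 2000, normalize = TRUE) {
  if (length(gene_ids) == 0) stop("empty gene list")
  missing_ids <- setdiff(gene_ids, unique(gene_models$gene_id))
  if (length(missing_ids) > 0)
    stop("unknown gene id(s): ", paste(head(missing_ids, 5), collapse = ", "))
  if (is.null(names(tracks)) || any(names(tracks) == ""))
    stop("tracks must be a named list (one per biopsy)")
  if (normalize) tracks <- lapply(tracks, normalize_track)
  # pre-split each track into sorted per-chromosome vectors once
  indexed <- lapply(tracks, function(tr) {
    validate_track(tr)
    tr <- tr[order(tr$chrom, tr$start), , drop = FALSE]
    lapply(split(tr[, c("start", "end", "value")], tr$chrom), as.list)
  })

  by_gene <- split(gene_models, gene_models$gene_id)
  rows <- vector("list", length(gene_ids))
  nf <- length(META_FEATURES)
  for (gi in seq_along(gene_ids)) {
    g <- gene_ids[gi]
    ex <- by_gene[[g]]
    fr <- derive_feature_regions(ex, flank = flank)
    chrom <- attr(fr, "chrom")
    strand <- attr(fr, "strand")
    binsets <- lapply(fr, bin_feature, strand = strand, n_bins = n_bins)
    # flatten every bin sub-interval of every feature into one query
    # batch so the track index is consulted once per gene and biopsy
    ps <- numeric(0); pe <- numeric(0); pkey <- integer(0)
    for (fi in seq_len(nf)) {
      bs <- binsets[[fi]]
      if (is.null(bs)) next
      for (bi in seq_len(n_bins)) {
        ps <- c(ps, bs[[bi]]$start)
        pe <- c(pe, bs[[bi]]$end)
        pkey <- c(pkey, rep.int((fi - 1L) * n_bins + bi,
                                length(bs[[bi]]$start)))
      }
    }
    per_biopsy <- lapply(names(indexed), function(b) {
      ix <- indexed[[b]][[chrom]]
      vals <- rep(NA_real_, nf * n_bins)
      if (!is.null(ix) && length(ps) > 0) {
        lo <- findInterval(ps, ix$end) + 1L
        hi <- findInterval(pe, ix$start)
        tot <- numeric(length(ps))
        for (p in seq_along(tot)) {
          if (hi[p] >= lo[p]) {
            idx <- lo[p]:hi[p]
            ov <- pmin.int(ix$end[idx], pe[p]) - pmax.int(ix$start[idx], ps[p])
            ov[ov < 0] <- 0
            tot[p] <- sum(ov * ix$value[idx])
          }
        }
        num <- rowsum(tot, pkey)
        den <- rowsum(pe - ps, pkey)
        keys <- as.integer(rownames(num))
        vals[keys] <- num[, 1] / den[, 1]
      }
      data.frame(gene_id = g, biopsy = b,
                 feature = factor(rep(META_FEATURES, each = n_bins),
                                  levels = META_FEATURES),
                 bin = rep(seq_len(n_bins), nf),
                 value = vals, row.names = NULL)
    })
    rows[[gi]] <- do.call(rbind, per_biopsy)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Subtract the non-expressed-gene baseline from profiles
#'
#' For every biopsy and bin, the arithmetic mean profile over the
#' non-expressed genes (genes with zero counts in all biopsies — the
#' methylation background unrelated to expression change) is subtracted
#' from each gene's profile. A `median` baseline variant is available.
#'
#' @param profiles long profile data.frame from [metagene_profile()].
#' @param non_expressed_profiles same-format profiles of the
#'   non-expressed gene set (same biopsies and bin grid).
#' @param stat `"mean"` (default) or `"median"` baseline.
#' @return `profiles` with `value` replaced by the baseline-subtracted
#'   value.
#' @export
baseline_subtract <- function(profiles, non_expressed_profiles,
                              stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (nrow(non_expressed_profiles) == 0) stop("empty non-expressed set")
  if (!setequal(unique(profiles$biopsy), unique(non_expressed_profiles$biopsy)))
    stop("profiles and baseline cover different biopsies")
  fun <- if (stat == "mean") function(x) mean(x, na.rm = TRUE)
         else function(x) median(x, na.rm = TRUE)
  key <- function(d) interaction(d$biopsy, d$feature, d$bin, drop = FALSE)
  base <- tapply(non_expressed_profiles$value, key(non_expressed_profiles), fun)
  profiles$value <- profiles$value - as.numeric(base[as.character(key(profiles))])
  profiles
}

#' Per-gene demethylation scores and boxplot statistics
#'
#' The demethylation score of a gene at a biopsy is minus the mean of its
#' baseline-subtracted bin values within one feature, so *lower*
#' methylation than the non-expressed background gives a *higher* score.
#' Boxplot statistics use linear-interpolation quartiles with whiskers at
#' the most extreme points within 1.5 interquartile ranges of the box.
#'
#' @param normalized_profiles baseline-subtracted profiles from
#'   [baseline_subtract()].
#' @param gene_list gene ids to summarize.
#' @param feature one of [META_FEATURES].
#' @param biopsy biopsy name to summarize (one of the profile's biopsies).
#' @return list with `scores` (data.frame `gene_id`, `score`) and `stats`
#'   (median, q1, q3, lo_whisker, hi_whisker, n).
#' @export
demethylation_scores <- function(normalized_profiles, gene_list, feature,
                                 biopsy) {
  stopifnot(feature %in% META_FEATURES)
  sub <- normalized_profiles[
    normalized_profiles$gene_id %in% gene_list &
      normalized_profiles$feature == feature &
      normalized_profiles$biopsy == biopsy, , drop = FALSE]
  if (nrow(sub) == 0) stop("no profile rows for that gene list/feature/biopsy")
  sc <- tapply(sub$value, sub$gene_id, function(v) -mean(v))
  sc <- sc[!is.na(sc)]
  if (length(sc) == 0) stop("no gene in the list has feature '", feature, "'")
  scores <- data.frame(gene_id = names(sc), score = as.numeric(sc),
                       row.names = NULL)
  list(scores = scores, stats = boxplot_stats(scores$score))
}

#' Boxplot statistics (interpolated quartiles, 1.5 IQR whiskers)
#'
#' @param x numeric vector.
#' @return named numeric vector: `median`, `q1`, `q3`, `lo_whisker`,
#'   `hi_whisker`, `n`. Whiskers are the most extreme data points within
#'   `1.5 * IQR` of the quartiles.
#' @export
boxplot_stats <- function(x) {
  x <- x[is.finite(x)]
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- min(x[x >= q[1] - 1.5 * iqr])
  hi <- max(x[x <= q[3] + 1.5 * iqr])
  c(median = q[2], q1 = q[1], q3 = q[3],
    lo_whisker = lo, hi_whisker = hi, n = length(x))
}

#' Genes with zero counts in every scoped sample
#'
#' The strict-zero definition of "not expressed in any of the biopsies",
#' used to build the methylation baseline set. A counts-per-million
#' threshold variant is available for noisy data.
#'
#' @param counts raw counts, genes x samples.
#' @param samples sample ids defining the scope (default all columns).
#' @param cpm_threshold if > 0, genes are non-expressed when their CPM is
#'   below this value in every scoped sample (default 0 = strict zeros).
#' @return character vector of gene ids.
#' @export
define_non_expressed <- function(counts, samples = colnames(counts),
                                 cpm_threshold = 0) {
  m <- as.matrix(counts)[, samples, drop = FALSE]
  if (cpm_threshold > 0) {
    cpm <- sweep(m, 2, colSums(m) / 1e6, "/")
    rownames(m)[rowSums(cpm >= cpm_threshold) == 0]
  } else {
    rownames(m)[rowSums(m) == 0]
  }
}
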