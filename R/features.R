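# Gene-feature decomposition for meta-gene methylation profiles.
# Coordinates are 0-based half-open throughout; a gene model is a
# data.frame of exons (gene_id, chrom, start, end, strand) sorted by
# genomic position, non-overlapping.

#' The seven ordered meta-gene features
#'
#' Transcription-ordered features used for methylation profiling:
#' up to 2 kb upstream of the first exon; first exon; first intron;
#' internal exons; internal introns; last exon; up to 2 kb downstream of
#' the last exon.
#' @export
META_FEATURES <- c("upstream2kb", "first_exon", "first_intron",
                   "internal_exons", "internal_introns", "last_exon",
                   "downstream2kb")

#' Decompose one gene model into the seven meta-gene feature regions
#'
#' First/last are by *transcription* order (strand-aware): on the minus
#' strand the first exon is the genomically last one and the upstream
#' flank lies at higher coordinates. Single-exon genes define only the
#' upstream flank, the (only) exon as `first_exon`, and the downstream
#' flank; two-exon genes lack internal exons and internal introns. Flanks
#' are clipped at chromosome bounds and never exceed 2 kb.
#'
#' @param exons data.frame with columns `chrom`, `start`, `end`, `strand`
#'   (one gene; 0-based half-open, non-overlapping).
#' @param flank flank length in bp (default 2000).
#' @param chrom_length optional chromosome length for clipping the
#'   downstream/upstream flank (default unbounded).
#' @return named list over [META_FEATURES]: each element either `NULL`
#'   (feature absent) or a data.frame `start`,`end` with rows in
#'   transcription order; attributes `chrom` and `strand`.
#' @export
derive_feature_regions <- function(exons, flank = 2000, chrom_length = Inf) {
  stopifnot(nrow(exons) >= 1, length(unique(exons$strand)) == 1,
            length(unique(exons$chrom)) == 1)
  ex <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  if (any(ex$end <= ex$start)) stop("empty exon interval")
  if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)]))
    stop("overlapping exons")
  strand <- as.character(exons$strand[1])
  stopifnot(strand %in% c("+", "-"))
  n <- nrow(ex)
  introns <- if (n > 1)
    data.frame(start = ex$end[-n], end = ex$start[-1]) else NULL
  m <- if (is.null(introns)) 0L else nrow(introns)

  # transcription order indices
  tx <- function(df) if (strand == "+") df else df[rev(seq_len(nrow(df))), , drop = FALSE]
  ex_tx <- tx(ex)
  in_tx <- if (m > 0) tx(introns) else NULL

  gstart <- ex$start[1]
  gend <- ex$end[n]
  up <- if (strand == "+")
    data.frame(start = max(0, gstart - flank), end = gstart)
  else data.frame(start = gend, end = min(chrom_length, gend + flank))
  down <- if (strand == "+")
    data.frame(start = gend, end = min(chrom_length, gend + flank))
  else data.frame(start = max(0, gstart - flank), end = gstart)
  if (up$end <= up$start) up <- NULL
  if (down$end <= down$start) down <- NULL

  out <- list(
    upstream2kb = up,
    first_exon = ex_tx[1, , drop = FALSE],
    first_intron = if (m >= 1) in_tx[1, , drop = FALSE] else NULL,
    internal_exons = if (n >= 3) ex_tx[2:(n - 1), , drop = FALSE] else NULL,
    internal_introns = if (m >= 2) in_tx[2:m, , drop = FALSE] else NULL,
    last_exon = if (n >= 2) ex_tx[n, , drop = FALSE] else NULL,
    downstream2kb = down)
  out <- out[META_FEATURES]
  out <- lapply(out, function(d) { if (!is.null(d)) rownames(d) <- NULL; d })
  attr(out, "chrom") <- as.character(exons$chrom[1])
  attr(out, "strand") <- strand
  out
}

#' Split a feature region into equal bins along transcription
#'
#' The concatenated feature length `L` (summed over its intervals in
#' transcription order) is divided into `n_bins` bins of exactly
#' `L / n_bins` — boundaries are real-valued and mapped back through the
#' interval concatenation, so a bin may straddle an interval junction and
#' features shorter than `n_bins` bp get fractional-base bins. Bin 1 is
#' the 5'-most bin of the feature.
#'
#' @param region data.frame `start`,`end` in transcription order (as from
#'   [derive_feature_regions()]), or `NULL`.
#' @param strand `"+"` or `"-"`; on the minus strand transcription runs
#'   from each interval's `end` down to its `start`.
#' @param n_bins number of bins (default 20).
#' @return `NULL` if the region is absent/empty; otherwise a list of
#'   `n_bins` data.frames of genomic sub-intervals (`start`,`end`,
#'   real-valued), with the per-bin length in `attr(, "bin_length")`.
#' @export
bin_feature <- function(region, strand, n_bins = 20L) {
  if (is.null(region) || nrow(region) == 0) return(NULL)
  len <- region$end - region$start
  L <- sum(len)
  if (L <= 0) return(NULL)
  offs <- cumsum(c(0, len[-length(len)]))   # feature-coordinate offsets
  bl <- L / n_bins
  piece <- function(k, u, v) {
    # feature coords [u, v) within interval k -> genomic sub-interval
    if (strand == "+") {
      s <- region$start[k] + (u - offs[k]); e <- region$start[k] + (v - offs[k])
    } else {
      s <- region$end[k] - (v - offs[k]); e <- region$end[k] - (u - offs[k])
    }
    c(s, e)
  }
  bins <- vector("list", n_bins)
  for (i in seq_len(n_bins)) {
    a <- (i - 1) * bl
    b <- if (i == n_bins) L else i * bl
    ks <- which(offs < b & offs + len > a)
    ps <- t(vapply(ks, function(k)
      piece(k, max(a, offs[k]), min(b, offs[k] + len[k])), numeric(2)))
    # plain-list data.frame construction: this runs tens of thousands of
    # times per meta-gene profile, so avoid data.frame() overhead
    bins[[i]] <- structure(list(start = ps[, 1], end = ps[, 2]),
                           class = "data.frame",
                           row.names = seq_len(nrow(ps)))
  }
  attr(bins, "bin_length") <- bl
  bins
}
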