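# Piecewise-constant methylation tracks: data.frames with columns
# `chrom`, `start`, `end`, `value` (0-based half-open, sorted,
# non-overlapping within a chromosome). Positions not covered by any
# interval carry signal 0.

validate_track <- function(track) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(track)))
  if (any(track$end <= track$start)) stop("empty track interval")
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, ]
    tr <- tr[order(tr$start), ]
    if (nrow(tr) > 1 && any(tr$start[-1] < tr$end[-nrow(tr)]))
      stop("overlapping track intervals on ", ch)
  }
  if (any(!is.finite(track$value))) stop("non-finite track values")
  invisible(track)
}

# weighted signal integral over [a, b) for one chromosome's sorted track
# (real-valued endpoints allowed); gaps contribute 0
track_integral <- function(starts, ends, values, a, b) {
  if (b <= a) return(0)
  lo <- findInterval(a, ends) + 1L          # first interval with end > a
  hi <- findInterval(b, starts)             # last interval with start <= b
  if (hi < lo) return(0)
  idx <- lo:hi
  ov <- pmin(ends[idx], b) - pmax(starts[idx], a)
  sum(pmax(ov, 0) * values[idx])
}

#' Length-weighted mean signal over feature bins
#'
#' For each bin (a set of genomic sub-intervals from [bin_feature()],
#' possibly fractional-base) computes the length-weighted mean of the
#' piecewise-constant track signal across the bin's extent; genomic
#' stretches not covered by the track contribute signal 0.
#'
#' @param track methylation track data.frame (see package docs).
#' @param bins output of [bin_feature()] (or `NULL`).
#' @param chrom chromosome the bins live on.
#' @return numeric vector, one mean per bin (`NULL` bins give `NULL`).
#' @export
mean_signal <- function(track, bins, chrom) {
  if (is.null(bins)) return(NULL)
  tr <- track[track$chrom == chrom, , drop = FALSE]
  tr <- tr[order(tr$start), , drop = FALSE]
  mean_signal_sorted(tr$start, tr$end, tr$value, bins)
}

# fast path over pre-sorted per-chromosome vectors
mean_signal_sorted <- function(starts, ends, values, bins) {
  vapply(bins, function(bn) {
    bs <- bn$start; be <- bn$end
    tot <- 0; len <- 0
    for (r in seq_along(bs)) {
      tot <- tot + track_integral(starts, ends, values, bs[r], be[r])
      len <- len + (be[r] - bs[r])
    }
    if (len <= 0) NA_real_ else tot / len
  }, numeric(1))
}

#' Scale a track to mean genome signal one
#'
#' Divides every interval's value by the track's length-weighted mean
#' signal over its covered extent, putting samples sequenced to different
#' depths on a common scale before profiling.
#'
#' @param track methylation track data.frame.
#' @return rescaled track; the scaling divisor is in `attr(, "mean_signal")`.
#' @export
normalize_track <- function(track) {
  w <- track$end - track$start
  m <- sum(w * track$value) / sum(w)
  if (m <= 0) stop("track has non-positive mean signal; cannot normalize")
  track$value <- track$value / m
  attr(track, "mean_signal") <- m
  track
}
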