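#' Simulate per-biopsy methylation tracks with planted feature-local
#' demethylation
#'
#' Produces one piecewise-constant coverage track per biopsy spanning
#' every gene's body plus 2 kb flanks, in 50 bp steps with values drawn
#' as `Normal(base_level, base_sd)` (floored at 0.01) independently per
#' step and biopsy. For genes in a target list, the signal within the
#' list's target feature is additionally reduced by
#' `demeth_effect * (biopsy - 1) / (n_biopsies - 1)` — a linear ramp
#' reaching the full planted effect at the final biopsy, emulating
#' progressive feature-localized demethylation of responding genes.
#' Genes in the `non_expressed` list (and unlisted genes) are never
#' shifted.
#'
#' @param gene_models exon data.frame from [simulate_gene_models()].
#' @param gene_lists named list of gene-id vectors; recognized names are
#'   `early`, `progressive`, `late`, `non_expressed`. Lists must not
#'   contain unknown gene ids.
#' @param config a [sim_config()] (uses `demeth_effect` and `seed`).
#' @param targets named list mapping each shifted list to its target
#'   feature (defaults: early at the first exon, late at the last exon,
#'   progressive at internal exons).
#' @param n_biopsies number of biopsy tracks (default
#'   `config$biopsies_per_dog`).
#' @param base_level,base_sd mean and SD of the background step signal.
#' @return list with `tracks` (named list `B1`, `B2`, ... of track
#'   data.frames) and `truth` (data.frame `gene_id`, `list`, `feature`,
#'   `final_shift`).
#' @export
simulate_methylation <- function(gene_models, gene_lists, config,
                                 targets = list(early = "first_exon",
                                                late = "last_exon",
                                                progressive = "internal_exons"),
                                 n_biopsies = config$biopsies_per_dog,
                                 base_level = 10, base_sd = 2) {
  stopifnot(inherits(config, "sim_config"))
  all_ids <- unique(gene_models$gene_id)
  for (nm in names(gene_lists)) {
    unknown <- setdiff(gene_lists[[nm]], all_ids)
    if (length(unknown) > 0)
      stop("unknown gene id in list '", nm, "': ",
           paste(head(unknown, 3), collapse = ", "))
  }
  stopifnot(all(unlist(targets) %in% META_FEATURES))
  withr::with_seed(config$seed + 1L, {
    step <- 50L
    # which list (if any) shifts each gene, and at which feature
    shift_of <- list()
    for (nm in intersect(names(targets), names(gene_lists)))
      for (g in gene_lists[[nm]])
        shift_of[[g]] <- list(list = nm, feature = targets[[nm]])
    by_gene <- split(gene_models, gene_models$gene_id)
    by_gene <- by_gene[order(vapply(by_gene, function(e) min(e$start),
                                    numeric(1)))]
    tracks <- vector("list", n_biopsies)
    names(tracks) <- paste0("B", seq_len(n_biopsies))
    shifted <- list()
    for (b in seq_len(n_biopsies)) {
      ramp <- if (n_biopsies > 1) (b - 1) / (n_biopsies - 1) else 0
      # gene spans are separated by >= 4 kb, so per-gene local tracks
      # (span +/- 2 kb) never overlap and concatenate directly
      segs <- lapply(by_gene, function(ex) {
        lo <- max(0, min(ex$start) - 2000)
        hi <- max(ex$end) + 2000
        brk <- seq(lo, hi, by = step)
        if (brk[length(brk)] < hi) brk <- c(brk, hi)
        tr <- data.frame(chrom = ex$chrom[1],
                         start = brk[-length(brk)], end = brk[-1])
        tr$value <- pmax(rnorm(nrow(tr), base_level, base_sd), 0.01)
        g <- ex$gene_id[1]
        sh <- shift_of[[g]]
        if (!is.null(sh) && ramp > 0) {
          fr <- derive_feature_regions(ex)
          reg <- fr[[sh$feature]]
          if (!is.null(reg))
            tr <- track_shift_region(tr, ex$chrom[1], reg,
                                     -config$demeth_effect * ramp)
        }
        if (b == 1L && !is.null(sh)) {
          fr <- derive_feature_regions(ex)
          if (!is.null(fr[[sh$feature]]))
            shifted[[length(shifted) + 1L]] <<-
              data.frame(gene_id = g, list = sh$list, feature = sh$feature,
                         final_shift = -config$demeth_effect)
        }
        tr
      })
      tr <- do.call(rbind, segs)
      tr <- tr[order(tr$chrom, tr$start), ]
      rownames(tr) <- NULL
      tracks[[b]] <- tr
    }
    truth <- if (length(shifted)) do.call(rbind, shifted)
             else data.frame(gene_id = character(), list = character(),
                             feature = character(), final_shift = numeric())
    list(tracks = tracks, truth = truth)
  })
}

# add `amount` to the track value within the given regions (splitting
# intervals at region boundaries); values floored at 0
track_shift_region <- function(track, chrom, regions, amount) {
  if (amount == 0) return(track)
  for (r in seq_len(nrow(regions))) {
    a <- min(regions$start[r], regions$end[r])
    b <- max(regions$start[r], regions$end[r])
    sel <- which(track$chrom == chrom & track$start < b & track$end > a)
    if (length(sel) == 0) next
    pieces <- lapply(sel, function(i) {
      s <- track$start[i]; e <- track$end[i]; v <- track$value[i]
      cuts <- sort(unique(c(s, e, max(s, a), min(e, b))))
      data.frame(chrom = chrom, start = cuts[-length(cuts)], end = cuts[-1],
                 value = ifelse(cuts[-length(cuts)] >= a & cuts[-1] <= b,
                                pmax(v + amount, 0), v))
    })
    track <- rbind(track[-sel, , drop = FALSE], do.call(rbind, pieces))
  }
  track[order(track$chrom, track$start), , drop = FALSE]
}
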