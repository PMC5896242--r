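#' Assign a transcript to host or tumor origin from somatic-site pileups
#'
#' The tumor genome carries millions of somatic substitutions, so the
#' allele observed in RNA reads at a somatic site indicates whether the
#' transcript came from tumor or host cells. A site is *informative* when
#' its depth reaches `min_depth`; an informative site votes TUMOR when the
#' tumor-allele fraction is at least `majority`, HOST when the host
#' fraction is, and abstains otherwise. The gene is called only when at
#' least `min_variants` informative sites exist, at least one site casts a
#' vote, and all votes agree (unanimity — conservative by design);
#' anything else is AMBIGUOUS.
#'
#' @param pileup data.frame for a single gene with columns `gene_id`,
#'   `pos`, `depth`, `tumor_count`, `host_count` (and optionally `other`);
#'   zero rows give an AMBIGUOUS call with zero informative sites.
#' @param min_variants minimum informative sites for a call (default 2:
#'   a transcript needs at least two mutations).
#' @param min_depth minimum depth for a site to be informative (default 8).
#' @param majority per-site allele-fraction threshold (default 0.8).
#' @return one-row data.frame: `gene_id`, `call`
#'   (`HOST`/`TUMOR`/`AMBIGUOUS`), `n_informative`, `mean_tumor_fraction`.
#' @export
assign_origin <- function(pileup, min_variants = 2L, min_depth = 8L,
                          majority = 0.8) {
  stopifnot(min_variants >= 1, min_depth >= 0, majority > 0.5, majority <= 1)
  gid <- if (nrow(pileup) > 0) unique(as.character(pileup$gene_id)) else NA_character_
  if (length(gid) > 1) stop("pileup mixes sites from multiple genes")
  if (nrow(pileup) == 0)
    return(data.frame(gene_id = gid, call = "AMBIGUOUS",
                      n_informative = 0L, mean_tumor_fraction = NA_real_))
  stopifnot(all(pileup$tumor_count + pileup$host_count <= pileup$depth))
  inf <- pileup$depth >= min_depth & pileup$depth > 0
  n_inf <- sum(inf)
  tf <- pileup$tumor_count[inf] / pileup$depth[inf]
  hf <- pileup$host_count[inf] / pileup$depth[inf]
  vote <- ifelse(tf >= majority, "TUMOR", ifelse(hf >= majority, "HOST", NA))
  votes <- vote[!is.na(vote)]
  call <- "AMBIGUOUS"
  if (n_inf >= min_variants && length(votes) > 0 &&
      length(unique(votes)) == 1L)
    call <- votes[1]
  data.frame(gene_id = gid, call = call, n_informative = n_inf,
             mean_tumor_fraction = if (n_inf > 0) mean(tf) else NA_real_,
             row.names = NULL)
}

#' Call origin for every gene in a pileup table
#'
#' @param pileups data.frame of sites across genes (columns as in
#'   [assign_origin()]).
#' @param ... thresholds passed to [assign_origin()].
#' @return data.frame with one row per gene.
#' @export
assign_origin_all <- function(pileups, ...) {
  out <- lapply(split(pileups, pileups$gene_id), assign_origin, ...)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Is a gene a host-tissue marker?
#'
#' Genes deleted or truncated by a premature stop codon in the tumor
#' genome cannot be expressed by tumor cells, so their transcripts mark
#' host tissue.
#'
#' @param gene_id character vector of gene ids.
#' @param host_marker_set character vector of marker gene ids (e.g. read
#'   with `readLines()` from a one-id-per-line file).
#' @return logical vector: `TRUE` where the gene is a host marker.
#' @export
host_marker_lookup <- function(gene_id, host_marker_set) {
  as.character(gene_id) %in% as.character(host_marker_set)
}
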