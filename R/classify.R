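#' Classify significant genes by when they first exceed the fold cutoff
#'
#' Temporal classes over the three phase contrasts (S/P, R/S, R/P), from
#' directed significant sets produced by [call_significant()]:
#' * **EARLY**: significant in S versus P (regardless of later behavior);
#' * **LATE**: significant in R versus S but *not* in S versus P;
#' * **PROGRESSIVE**: significant in R versus P but in neither R versus S
#'   nor S versus P.
#' The three classes are disjoint by construction. The direction suffix
#' (`_UP` / `_DOWN`) comes from the qualifying contrast of the class
#' definition; if the gene carries a different direction in another
#' contrast it keeps its qualifying-contrast label and is flagged in
#' `conflict`.
#'
#' @param sig_SP,sig_RS,sig_RP directed gene sets (data.frames with
#'   `gene_id`, `direction`, `log2fc`) for the S/P, R/S and R/P contrasts.
#' @return data.frame `gene_id`, `class` (one of `EARLY_UP`, `EARLY_DOWN`,
#'   `LATE_UP`, `LATE_DOWN`, `PROG_UP`, `PROG_DOWN`), `qualifying_contrast`,
#'   `log2fc` (from the qualifying contrast), `conflict` (logical). Genes
#'   in no set are omitted (class `NONE` implicitly).
#' @export
classify_temporal <- function(sig_SP, sig_RS, sig_RP) {
  for (s in list(sig_SP, sig_RS, sig_RP))
    stopifnot(all(c("gene_id", "direction") %in% names(s)))
  early <- sig_SP$gene_id
  late <- setdiff(sig_RS$gene_id, sig_SP$gene_id)
  prog <- setdiff(sig_RP$gene_id, union(sig_RS$gene_id, sig_SP$gene_id))

  row_for <- function(g, set, prefix, contrast) {
    i <- match(g, set$gene_id)
    dir <- set$direction[i]
    data.frame(gene_id = g,
               class = paste0(prefix, ifelse(dir > 0, "_UP", "_DOWN")),
               qualifying_contrast = contrast,
               log2fc = if ("log2fc" %in% names(set)) set$log2fc[i] else NA_real_,
               row.names = NULL)
  }
  out <- rbind(
    if (length(early)) row_for(early, sig_SP, "EARLY", "S_vs_P"),
    if (length(late)) row_for(late, sig_RS, "LATE", "R_vs_S"),
    if (length(prog)) row_for(prog, sig_RP, "PROG", "R_vs_P"))
  if (is.null(out))
    return(data.frame(gene_id = character(), class = character(),
                      qualifying_contrast = character(), log2fc = numeric(),
                      conflict = logical()))
  # flag genes whose direction differs between contrasts they appear in
  dirs <- rbind(data.frame(gene_id = sig_SP$gene_id, d = sig_SP$direction),
                data.frame(gene_id = sig_RS$gene_id, d = sig_RS$direction),
                data.frame(gene_id = sig_RP$gene_id, d = sig_RP$direction))
  ndir <- tapply(dirs$d, dirs$gene_id, function(x) length(unique(x)))
  out$conflict <- ndir[out$gene_id] > 1
  rownames(out) <- NULL
  out
}
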