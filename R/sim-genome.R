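#' Simulate non-overlapping gene models on a synthetic chromosome
#'
#' Genes are placed left to right on one synthetic chromosome (`"chrS"`)
#' with gaps of at least 4 kb, so 2 kb flanks never collide. Each gene has
#' 1-10 exons of 40-400 bp separated by introns of 60-2000 bp, on a
#' random strand. Coordinates are 0-based half-open.
#'
#' @param n_genes number of genes (>= 1).
#' @param seed integer seed; the output is deterministic given the seed.
#' @return exon data.frame (`gene_id`, `chrom`, `start`, `end`, `strand`),
#'   chromosome length in `attr(, "chrom_length")`.
#' @export
simulate_gene_models <- function(n_genes, seed = 1L) {
  stopifnot(n_genes >= 1)
  withr::with_seed(seed, {
    rows <- vector("list", n_genes)
    cursor <- 3000
    for (g in seq_len(n_genes)) {
      n_ex <- sample(1:10, 1)
      ex_len <- sample(40:400, n_ex, replace = TRUE)
      in_len <- if (n_ex > 1) sample(60:2000, n_ex - 1, replace = TRUE) else integer(0)
      starts <- cursor + cumsum(c(0, ex_len[-n_ex] + in_len))
      ends <- starts + ex_len
      strand <- sample(c("+", "-"), 1)
      rows[[g]] <- data.frame(gene_id = sprintf("gene%04d", g),
                              chrom = "chrS",
                              start = starts, end = ends, strand = strand)
      cursor <- ends[n_ex] + 4000 + sample(0:2000, 1)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "chrom_length") <- cursor + 3000
    out
  })
}
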