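# Shared fixture builders and independent oracles.

# Brute-force Benjamini-Hochberg: for each gene, the adjusted p is the
# smallest FDR level at which any step-up threshold would reject it —
# computed by direct enumeration over all rejection cut ranks.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  padj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    # smallest level q such that exists k >= rank_i with p_(k) <= q k/m
    padj[i] <- min(vapply(rank_i:m, function(k) p[ord[k]] * m / k, numeric(1)))
  }
  pmin(padj, 1)
}

# Per-base brute-force mean signal over [a, b) (real endpoints): exact
# integration of the piecewise-constant track, looping base by base with
# fractional end pieces.
mean_signal_bruteforce <- function(track, a, b) {
  val_at <- function(x) {
    i <- which(track$start <= x & track$end > x)
    if (length(i) == 0) 0 else track$value[i[1]]
  }
  total <- 0
  x <- a
  while (x < b) {
    nx <- min(floor(x) + 1, b)
    total <- total + val_at(x) * (nx - x)
    x <- nx
  }
  total / (b - a)
}

# A small paired two-cohort sample sheet.
toy_design <- function(n_reg = 2, n_non = 0, biopsies = 2) {
  dogs <- c(if (n_reg > 0) paste0("R", seq_len(n_reg)),
            if (n_non > 0) paste0("N", seq_len(n_non)))
  status <- ifelse(grepl("^R", dogs), "REGRESSIVE", "NON_REGRESSIVE")
  data.frame(
    sample_id = paste0(rep(dogs, each = biopsies), "_B",
                       rep(seq_len(biopsies), length(dogs))),
    dog = rep(dogs, each = biopsies),
    biopsy = rep(seq_len(biopsies), length(dogs)),
    regression_status = rep(status, each = biopsies))
}

# A directed gene set in the call_significant() output shape.
directed_set <- function(ids, direction = 1, log2fc = direction * 4) {
  data.frame(gene_id = ids,
             direction = rep_len(direction, length(ids)),
             log2fc = rep_len(log2fc, length(ids)),
             padj = rep(0.001, length(ids)))
}
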