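#' Simulate somatic variant sites and RNA allele-count pileups
#'
#' Each gene receives `k` biallelic somatic sites (`k` drawn from
#' `sites_per_transcript_range`) at distinct exonic positions, with
#' distinct tumor and host alleles. A fraction `frac_tumor_origin` of
#' genes is of tumor origin; at each site the read depth is drawn from
#' `depth_per_site_range` and the tumor-allele count is binomial with
#' success probability `1 - allele_error_rate` for tumor-origin genes and
#' `allele_error_rate` for host-origin genes (host count = depth - tumor
#' count).
#'
#' @param gene_models exon data.frame from [simulate_gene_models()].
#' @param config a [sim_config()].
#' @return list with `sites` (`gene_id`, `chrom`, `pos`, `tumor_allele`,
#'   `host_allele`), `pileups` (`gene_id`, `pos`, `depth`, `tumor_count`,
#'   `host_count`), and `truth` (`gene_id`, `origin`).
#' @export
simulate_variant_pileups <- function(gene_models, config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 2L, {
    ids <- unique(gene_models$gene_id)
    G <- length(ids)
    n_tumor <- round(config$frac_tumor_origin * G)
    origin <- rep("HOST", G)
    if (n_tumor > 0) origin[sample.int(G, n_tumor)] <- "TUMOR"
    names(origin) <- ids
    bases <- c("A", "C", "G", "T")
    k_rng <- config$sites_per_transcript_range
    d_rng <- config$depth_per_site_range
    err <- config$allele_error_rate
    out_sites <- vector("list", G)
    out_pile <- vector("list", G)
    for (i in seq_len(G)) {
      ex <- gene_models[gene_models$gene_id == ids[i], , drop = FALSE]
      exonic <- unlist(lapply(seq_len(nrow(ex)),
                              function(r) seq(ex$start[r], ex$end[r] - 1L)))
      k <- if (k_rng[1] == k_rng[2]) k_rng[1] else
        sample(seq(k_rng[1], k_rng[2]), 1)
      pos <- sort(sample(exonic, min(k, length(exonic))))
      alle <- t(vapply(pos, function(p) sample(bases, 2), character(2)))
      depth <- if (d_rng[1] == d_rng[2]) rep(d_rng[1], length(pos)) else
        sample(seq(d_rng[1], d_rng[2]), length(pos), replace = TRUE)
      p_tumor <- if (origin[i] == "TUMOR") 1 - err else err
      tc <- rbinom(length(pos), depth, p_tumor)
      out_sites[[i]] <- data.frame(gene_id = ids[i], chrom = ex$chrom[1],
                                   pos = pos, tumor_allele = alle[, 1],
                                   host_allele = alle[, 2])
      out_pile[[i]] <- data.frame(gene_id = ids[i], pos = pos, depth = depth,
                                  tumor_count = tc, host_count = depth - tc)
    }
    list(sites = do.call(rbind, out_sites),
         pileups = do.call(rbind, out_pile),
         truth = data.frame(gene_id = ids, origin = unname(origin),
                            row.names = NULL))
  })
}
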