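#' Simulation configuration for the synthetic serial-biopsy study
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the study design the package targets: a handful of
#' dogs with two or three serial biopsies each, negative-binomial counts
#' with a paired dog effect, and planted early / late / progressive
#' expression trajectories that respond only in regressive animals.
#'
#' @param n_genes number of genes.
#' @param n_dogs_regressive,n_dogs_nonregressive dogs per regression arm.
#' @param biopsies_per_dog 2 or 3 serial biopsies per dog.
#' @param baseline_log_mean_range natural-log range of baseline expected
#'   counts; baselines are drawn uniformly on this range.
#' @param dispersion NB dispersion alpha (variance = mu + alpha * mu^2).
#' @param frac_early,frac_late,frac_progressive fractions of genes planted
#'   in each temporal class (sum must be <= 1).
#' @param planted_log2fc planted log2 fold change magnitude (> 0). Each
#'   planted gene is randomly up or down; early genes shift at biopsies 2
#'   and 3, late genes at biopsy 3 only, progressive genes by half at
#'   biopsy 2 and in full at biopsy 3. Shifts apply in regressive dogs
#'   only, so the regressive-versus-non-regressive interaction has signal.
#' @param frac_tumor_origin fraction of genes whose transcripts originate
#'   from the tumor (the rest are host).
#' @param sites_per_transcript_range integer range of informative somatic
#'   sites per transcript.
#' @param depth_per_site_range integer range of pileup depths per site.
#' @param allele_error_rate per-read probability of reporting the wrong
#'   allele at a site.
#' @param demeth_effect methylation-signal drop (track units) planted at
#'   the target feature of listed genes, reached at the final biopsy via a
#'   linear ramp across biopsies.
#' @param seed integer seed; a fixed seed makes every generator output
#'   bit-identical.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_dogs_regressive = 3L,
                       n_dogs_nonregressive = 3L,
                       biopsies_per_dog = 3L,
                       baseline_log_mean_range = log(c(5, 2000)),
                       dispersion = 0.05,
                       frac_early = 0.05,
                       frac_late = 0.05,
                       frac_progressive = 0.05,
                       planted_log2fc = 4,
                       frac_tumor_origin = 0.5,
                       sites_per_transcript_range = c(2L, 5L),
                       depth_per_site_range = c(10L, 60L),
                       allele_error_rate = 0.01,
                       demeth_effect = 2,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_dogs_regressive = as.integer(n_dogs_regressive),
              n_dogs_nonregressive = as.integer(n_dogs_nonregressive),
              biopsies_per_dog = as.integer(biopsies_per_dog),
              baseline_log_mean_range = as.numeric(baseline_log_mean_range),
              dispersion = as.numeric(dispersion),
              frac_early = as.numeric(frac_early),
              frac_late = as.numeric(frac_late),
              frac_progressive = as.numeric(frac_progressive),
              planted_log2fc = as.numeric(planted_log2fc),
              frac_tumor_origin = as.numeric(frac_tumor_origin),
              sites_per_transcript_range = as.integer(sites_per_transcript_range),
              depth_per_site_range = as.integer(depth_per_site_range),
              allele_error_rate = as.numeric(allele_error_rate),
              demeth_effect = as.numeric(demeth_effect),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes >= 1L,
              n_dogs_regressive >= 0L, n_dogs_nonregressive >= 0L,
              n_dogs_regressive + n_dogs_nonregressive >= 1L,
              biopsies_per_dog %in% 2:3,
              length(baseline_log_mean_range) == 2L,
              baseline_log_mean_range[1] <= baseline_log_mean_range[2],
              dispersion > 0,
              frac_early >= 0, frac_late >= 0, frac_progressive >= 0,
              planted_log2fc > 0,
              frac_tumor_origin >= 0, frac_tumor_origin <= 1,
              sites_per_transcript_range[1] <= sites_per_transcript_range[2],
              sites_per_transcript_range[1] >= 1L,
              depth_per_site_range[1] <= depth_per_site_range[2],
              depth_per_site_range[1] >= 0L,
              allele_error_rate >= 0, allele_error_rate <= 0.5,
              length(seed) == 1L)
  })
  if (cfg$frac_early + cfg$frac_late + cfg$frac_progressive > 1)
    stop("planted class fractions must sum to <= 1")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  %d genes; %d regressive + %d non-regressive dogs x %d biopsies\n",
              x$n_genes, x$n_dogs_regressive, x$n_dogs_nonregressive,
              x$biopsies_per_dog))
  cat(sprintf("  NB dispersion %.3g; planted |log2FC| %.3g (early/late/progressive = %.2g/%.2g/%.2g)\n",
              x$dispersion, x$planted_log2fc,
              x$frac_early, x$frac_late, x$frac_progressive))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
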