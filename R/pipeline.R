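#' Pipeline configuration
#'
#' Builds and validates the configuration driving [run_pipeline()]. All
#' thresholds default to the study's printed settings: fold change > 10 at
#' BH-adjusted p < 0.01 for the main significance cut, raw p < 0.05 for
#' the regression-status interaction, lowest-40%-quantile expression
#' filter, 20 bins over 7 gene features with 2 kb flanks for methylation
#' profiling, and >= 2 informative sites at depth >= 8 with a 0.8 per-site
#' majority for origin calls. Configurations round-trip through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param out_dir output directory (created if missing).
#' @param seed single integer; every stochastic stage derives its seed
#'   from this one.
#' @param stages character vector of stages to run, in dependency order
#'   from `simulate`, `de`, `classify`, `signature`, `origin`,
#'   `methylome`, `qpcr`.
#' @param fc_threshold,alpha,interaction_alpha,filter_quantile DE stage
#'   thresholds.
#' @param n_bins,flank methylome stage geometry.
#' @param min_variants,min_depth,majority origin-caller thresholds.
#' @param sim named list of [sim_config()] overrides for the synthetic
#'   study (e.g. `list(n_genes = 500)`).
#' @param n_profile_genes genes per list profiled in the methylome stage.
#' @return validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            stages = c("simulate", "de", "classify",
                                       "signature", "origin", "methylome",
                                       "qpcr"),
                            fc_threshold = 10,
                            alpha = 0.01,
                            interaction_alpha = 0.05,
                            filter_quantile = 0.40,
                            n_bins = 20L,
                            flank = 2000,
                            min_variants = 2L,
                            min_depth = 8L,
                            majority = 0.8,
                            sim = list(),
                            n_profile_genes = 25L) {
  all_stages <- c("simulate", "de", "classify", "signature", "origin",
                  "methylome", "qpcr")
  stopifnot(all(stages %in% all_stages),
            fc_threshold > 1, alpha > 0, alpha < 1,
            interaction_alpha > 0, interaction_alpha < 1,
            filter_quantile >= 0, filter_quantile < 1,
            n_bins >= 1, flank >= 0,
            min_variants >= 1, min_depth >= 0,
            majority > 0.5, majority <= 1)
  need <- list(de = "simulate", classify = "de", signature = "de",
               origin = "simulate", methylome = "simulate",
               qpcr = "simulate")
  for (s in stages) {
    dep <- need[[s]]
    if (!is.null(dep) && !dep %in% stages)
      stop("stage '", s, "' requires stage '", dep, "'")
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 stages = intersect(all_stages, stages),
                 fc_threshold = fc_threshold, alpha = alpha,
                 interaction_alpha = interaction_alpha,
                 filter_quantile = filter_quantile,
                 n_bins = as.integer(n_bins), flank = flank,
                 min_variants = as.integer(min_variants),
                 min_depth = as.integer(min_depth), majority = majority,
                 sim = sim, n_profile_genes = as.integer(n_profile_genes)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

#' Run the synthetic end-to-end analysis pipeline
#'
#' Executes the enabled stages in dependency order. The `simulate` stage
#' writes a complete synthetic study (counts TSV + sample sheet, gene
#' models GTF, per-biopsy bedGraph methylation tracks, somatic-site VCF +
#' pileup TSV, qPCR Ct TSV, truth JSON) under `out_dir/inputs/`; every
#' later stage reads its inputs back from those files, so the on-disk
#' formats are exercised on every run. Outputs (per-contrast result TSVs,
#' significant sets, temporal classification, heatmap matrix, Venn JSON,
#' origin and burden TSVs, demethylation boxplot statistics, PCA
#' coordinates) land under `out_dir/`, and a machine-readable run report
#' is written to `out_dir/run_report.json`. Identical configurations give
#' identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return the run report (list), invisibly also written as JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  out_dir <- config$out_dir
  in_dir <- file.path(out_dir, "inputs")
  dir.create(in_dir, recursive = TRUE, showWarnings = FALSE)
  ver <- tryCatch(as.character(utils::packageVersion("ctvtsig")),
                  error = function(e) "dev")
  report <- list(version = ver,
                 seed = config$seed,
                 parameters = unclass(config)[setdiff(names(unclass(config)),
                                                      c("out_dir", "sim"))],
                 stages = list())
  warn <- character()
  note <- function(stage, ...) {
    report$stages[[stage]] <<- c(report$stages[[stage]], list(...))
  }

  scfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))

  if ("simulate" %in% config$stages) {
    sim <- simulate_counts(scfg)
    write_counts_tsv(sim$counts, file.path(in_dir, "counts.tsv"))
    write_sample_sheet(sim$design, file.path(in_dir, "samples.tsv"))
    truth <- sim$truth

    np <- config$n_profile_genes
    early_ids <- head(truth$gene_id[truth$class == "EARLY" & truth$direction > 0], np)
    late_ids <- head(truth$gene_id[truth$class == "LATE" & truth$direction > 0], np)
    prog_ids <- head(truth$gene_id[truth$class == "PROGRESSIVE" & truth$direction > 0], np)
    null_ids <- head(truth$gene_id[truth$class == "NULL"], np)
    prof_ids <- c(early_ids, late_ids, prog_ids, null_ids)
    gm_all <- simulate_gene_models(scfg$n_genes, seed = scfg$seed)
    gm <- gm_all[gm_all$gene_id %in% prof_ids, , drop = FALSE]
    lists <- list(early = early_ids, late = late_ids,
                  progressive = prog_ids, non_expressed = null_ids)
    meth <- simulate_methylation(gm, lists, scfg)
    write_gene_models_gtf(gm, file.path(in_dir, "gene_models.gtf"))
    for (b in names(meth$tracks))
      write_track_bedgraph(meth$tracks[[b]],
                           file.path(in_dir, paste0("meth_", b, ".bedGraph")))
    vp <- simulate_variant_pileups(gm, scfg)
    if (requireNamespace("VariantAnnotation", quietly = TRUE))
      write_sites_vcf(vp$sites, file.path(in_dir, "sites.vcf"))
    write_tsv(vp$pileups, file.path(in_dir, "pileups.tsv"))
    qp <- simulate_qpcr(scfg)
    write_tsv(qp$ct_table, file.path(in_dir, "ct.tsv"))
    jsonlite::write_json(list(genes = truth, gene_lists = lists,
                              origins = vp$truth, burden = qp$truth),
                         file.path(in_dir, "truth.json"), dataframe = "rows")
    note("simulate", n_genes = scfg$n_genes, n_samples = nrow(sim$design),
         profiled_genes = length(prof_ids))
  }

  read_inputs <- function(...) {
    paths <- file.path(in_dir, c(...))
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0)
      stop("missing pipeline input(s): ", paste(missing, collapse = ", "))
    paths
  }

  de <- NULL
  if ("de" %in% config$stages) {
    read_inputs("counts.tsv", "samples.tsv")
    counts <- read_counts_tsv(file.path(in_dir, "counts.tsv"))
    design <- read_sample_sheet(file.path(in_dir, "samples.tsv"))
    keep <- filter_low_expression(counts, config$filter_quantile)
    kept <- counts[keep, , drop = FALSE]
    reg <- design[design$regression_status == "REGRESSIVE", , drop = FALSE]
    res <- withCallingHandlers(
      fit_contrasts(kept[, reg$sample_id, drop = FALSE], reg),
      warning = function(w) {
        warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
      })
    for (cn in names(res))
      write_tsv(res[[cn]], file.path(out_dir, paste0("de_", cn, ".tsv")))
    inter <- NULL
    if (length(unique(design$regression_status)) == 2) {
      inter <- withCallingHandlers(
        interaction_test(kept, design),
        warning = function(w) {
          warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
        })
      write_tsv(inter, file.path(out_dir, "de_interaction.tsv"))
    }
    pca <- sample_pca(sweep(kept, 2, estimate_size_factors(kept), "/"))
    write_tsv(data.frame(sample_id = rownames(pca$coords), pca$coords,
                         check.names = FALSE),
              file.path(out_dir, "sample_pca.tsv"))
    de <- list(results = res, interaction = inter, counts = counts,
               kept = keep, design = design)
    note("de", n_total = nrow(counts), n_retained = length(keep),
         n_removed = nrow(counts) - length(keep),
         pca_variance = unname(pca$variance_fraction[1:2]))
  }

  cls <- NULL
  if ("classify" %in% config$stages) {
    if (is.null(de)) stop("classify stage requires the de stage")
    r <- de$results
    if (!all(c("S_vs_P", "R_vs_S", "R_vs_P") %in% names(r)))
      stop("temporal classification needs a three-biopsy design")
    sig <- lapply(r, call_significant, fc_threshold = config$fc_threshold,
                  alpha = config$alpha)
    cls <- classify_temporal(sig$S_vs_P, sig$R_vs_S, sig$R_vs_P)
    write_tsv(cls, file.path(out_dir, "temporal_classification.tsv"))
    note("classify", n_labeled = nrow(cls),
         by_class = as.list(table(cls$class)))
  }

  if ("signature" %in% config$stages) {
    if (is.null(de)) stop("signature stage requires the de stage")
    r <- de$results
    main <- if ("R_vs_P" %in% names(r)) "R_vs_P" else names(r)[1]
    sig_reg <- call_significant(r[[main]], config$fc_threshold, config$alpha)
    norm <- sweep(de$counts[de$kept, , drop = FALSE], 2,
                  estimate_size_factors(de$counts[de$kept, , drop = FALSE]), "/")
    base_ids <- de$design$sample_id[de$design$biopsy == 1]
    hm <- build_heatmap_matrix(norm[rownames(norm) %in% sig_reg$gene_id, ,
                                    drop = FALSE], base_ids)
    write_tsv(data.frame(gene_id = rownames(hm), hm, check.names = FALSE),
              file.path(out_dir, "heatmap_matrix.tsv"))
    venn <- NULL
    core <- NULL
    if (!is.null(de$interaction)) {
      sig_int <- call_interaction(de$interaction, config$interaction_alpha)
      nonreg <- de$design[de$design$regression_status == "NON_REGRESSIVE", ,
                          drop = FALSE]
      r_non <- withCallingHandlers(
        fit_contrasts(de$counts[de$kept, nonreg$sample_id, drop = FALSE],
                      nonreg, contrasts = main),
        warning = function(w) {
          warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning")
        })
      sig_non <- call_significant(r_non[[main]], config$fc_threshold,
                                  config$alpha)
      core <- core_signature(sig_reg, sig_int, sig_reg, sig_non)
      venn <- set_overlap(sig_reg$gene_id, sig_int$gene_id)
      jsonlite::write_json(venn, file.path(out_dir, "venn.json"),
                           auto_unbox = TRUE)
      write_tsv(core$core, file.path(out_dir, "core_signature.tsv"))
    }
    note("signature", n_significant = nrow(sig_reg),
         n_core = if (is.null(core)) NA else nrow(core$core))
  }

  if ("origin" %in% config$stages) {
    read_inputs("pileups.tsv")
    pile <- read_tsv(file.path(in_dir, "pileups.tsv"))
    calls <- assign_origin_all(pile, min_variants = config$min_variants,
                               min_depth = config$min_depth,
                               majority = config$majority)
    write_tsv(calls, file.path(out_dir, "origin_calls.tsv"))
    note("origin", n_genes = nrow(calls),
         by_call = as.list(table(calls$call)))
  }

  if ("methylome" %in% config$stages) {
    read_inputs("gene_models.gtf", "truth.json")
    gm <- read_gene_models_gtf(file.path(in_dir, "gene_models.gtf"))
    truth <- jsonlite::read_json(file.path(in_dir, "truth.json"),
                                 simplifyVector = TRUE)
    lists <- truth$gene_lists
    track_files <- list.files(in_dir, pattern = "^meth_.*\\.bedGraph$",
                              full.names = TRUE)
    if (length(track_files) == 0) stop("missing pipeline input(s): bedGraph tracks")
    tracks <- lapply(track_files, read_track_bedgraph)
    names(tracks) <- sub("^meth_(.*)\\.bedGraph$", "\\1", basename(track_files))
    tracks <- tracks[order(names(tracks))]
    prof <- metagene_profile(gm, unlist(lists[c("early", "late", "progressive")]),
                             tracks, n_bins = config$n_bins,
                             flank = config$flank)
    base <- metagene_profile(gm, lists$non_expressed, tracks,
                             n_bins = config$n_bins, flank = config$flank)
    normp <- baseline_subtract(prof, base)
    write_tsv(normp, file.path(out_dir, "metagene_profiles.tsv"))
    stats_rows <- list()
    for (lname in c("early", "late", "progressive"))
      for (feat in META_FEATURES)
        for (b in names(tracks)) {
          sc <- tryCatch(demethylation_scores(normp, lists[[lname]], feat, b),
                         error = function(e) NULL)
          if (is.null(sc)) next
          stats_rows[[length(stats_rows) + 1L]] <-
            data.frame(list = lname, feature = feat, biopsy = b,
                       t(sc$stats))
        }
    write_tsv(do.call(rbind, stats_rows),
              file.path(out_dir, "demethylation_boxstats.tsv"))
    note("methylome", n_profiled = length(unique(prof$gene_id)),
         n_baseline = length(lists$non_expressed))
  }

  if ("qpcr" %in% config$stages) {
    read_inputs("ct.tsv")
    ct <- read_tsv(file.path(in_dir, "ct.tsv"))
    qb <- quantify_burden(ct)
    write_tsv(qb$burden, file.path(out_dir, "tumor_burden.tsv"))
    note("qpcr",
         efficiency = vapply(qb$curves, function(x) x$efficiency, numeric(1)),
         r_squared = vapply(qb$curves, function(x) x$r_squared, numeric(1)))
  }

  report$warnings <- warn
  report$wall_time_sec <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}

#' Sample-level principal-component QC
#'
#' PCA on `log2(normalized + 1)` with genes centered; used to confirm
#' that serial biopsies separate along the regression axis.
#'
#' @param normalized_counts genes x samples normalized counts.
#' @param n_components components to return (default 2).
#' @return list with `coords` (samples x components) and
#'   `variance_fraction` (per component, sums to <= 1).
#' @export
sample_pca <- function(normalized_counts, n_components = 2L) {
  x <- log2(as.matrix(normalized_counts) + 1)
  if (ncol(x) < 3) stop("PCA needs >= 3 samples")
  keep <- apply(x, 1, sd) > 0
  if (!any(keep)) stop("constant matrix; PCA undefined")
  pc <- prcomp(t(x[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = pc$x[, seq_len(k), drop = FALSE],
       variance_fraction = vf[seq_len(k)])
}
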