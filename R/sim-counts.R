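#' Simulate a paired serial-biopsy count matrix with planted trajectories
#'
#' Counts follow `NB(mu_gs, alpha)` with
#' `log mu_gs = baseline_g + dog_offset_d + trajectory_g(biopsy) + log sf_s`.
#' Baselines are uniform on `baseline_log_mean_range`; dog offsets are
#' `Normal(0, 0.3)` on the natural-log scale (the paired factor); size
#' factors are uniform on `[0.5, 2]`. Planted trajectories (in units of
#' `planted_log2fc * log 2`, each gene randomly up or down):
#' early = full shift at biopsies 2 and 3; late = full shift at biopsy 3
#' only; progressive = half shift at biopsy 2, full at biopsy 3 (with
#' `planted_log2fc = 4` a progressive gene therefore crosses the 10-fold
#' line only in the R-versus-P comparison). Trajectories apply in
#' regressive dogs only. For two-biopsy designs the biopsy-3 shift lands
#' on biopsy 2 (the "after" sample), preserving each class's endpoint
#' effect.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (integer matrix, genes x samples), `design`
#'   (sample sheet), and `truth` (per-gene data.frame: `gene_id`, `class`
#'   in EARLY/LATE/PROGRESSIVE/NULL, `direction`, per-contrast true log2
#'   fold changes, `baseline_log_mean`; per-sample true size factors in
#'   `attr(truth, "size_factors")`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, simulate_counts_impl(config))
}

simulate_counts_impl <- function(cfg) {
  G <- cfg$n_genes
  B <- cfg$biopsies_per_dog
  dogs <- c(if (cfg$n_dogs_regressive > 0)
              paste0("R", seq_len(cfg$n_dogs_regressive)),
            if (cfg$n_dogs_nonregressive > 0)
              paste0("N", seq_len(cfg$n_dogs_nonregressive)))
  status <- ifelse(grepl("^R", dogs), "REGRESSIVE", "NON_REGRESSIVE")
  design <- data.frame(
    sample_id = paste0(rep(dogs, each = B), "_B", rep(seq_len(B), length(dogs))),
    dog = rep(dogs, each = B),
    biopsy = rep(seq_len(B), length(dogs)),
    regression_status = rep(status, each = B))

  # planted class assignment: first genes get the planted classes so the
  # counts per class are exactly round(frac * n_genes); order is then fixed
  # (gene ids are arbitrary labels, so no shuffle is needed)
  n_early <- round(cfg$frac_early * G)
  n_late <- round(cfg$frac_late * G)
  n_prog <- round(cfg$frac_progressive * G)
  class <- rep("NULL", G)
  if (n_early > 0) class[seq_len(n_early)] <- "EARLY"
  if (n_late > 0) class[n_early + seq_len(n_late)] <- "LATE"
  if (n_prog > 0) class[n_early + n_late + seq_len(n_prog)] <- "PROGRESSIVE"
  direction <- ifelse(class == "NULL", 0,
                      sample(c(-1, 1), G, replace = TRUE))

  fc <- cfg$planted_log2fc
  # per-class shift (log2 units) at each biopsy, regressive dogs only
  shift_at <- function(cls, biopsy) {
    ramp <- switch(cls,
      EARLY = c(0, 1, 1),
      LATE = c(0, 0, 1),
      PROGRESSIVE = c(0, 0.5, 1),
      `NULL` = c(0, 0, 0))
    if (B == 2L) ramp <- ramp[c(1, 3)]   # endpoint effect on the B2 sample
    ramp[biopsy]
  }

  baseline <- runif(G, cfg$baseline_log_mean_range[1],
                    cfg$baseline_log_mean_range[2])
  dog_offset <- setNames(rnorm(length(dogs), 0, 0.3), dogs)
  sf <- setNames(runif(nrow(design), 0.5, 2), design$sample_id)

  n <- nrow(design)
  logmu <- matrix(baseline, G, n) +
    matrix(dog_offset[design$dog], G, n, byrow = TRUE) +
    matrix(log(sf), G, n, byrow = TRUE)
  regressive <- design$regression_status == "REGRESSIVE"
  for (s in which(regressive)) {
    sh <- vapply(class, shift_at, numeric(1), biopsy = design$biopsy[s])
    logmu[, s] <- logmu[, s] + direction * sh * fc * log(2)
  }
  mu <- exp(logmu)
  counts <- matrix(rnbinom(G * n, mu = mu, size = 1 / cfg$dispersion),
                   G, n, dimnames = list(sprintf("gene%04d", seq_len(G)),
                                         design$sample_id))
  storage.mode(counts) <- "integer"

  ramp3 <- function(cls) vapply(cls, function(k) shift_at(k, if (B == 2L) 2L else 3L),
                                numeric(1))
  ramp2 <- function(cls) vapply(cls, function(k) shift_at(k, 2L), numeric(1))
  truth <- data.frame(
    gene_id = rownames(counts),
    class = class,
    direction = direction,
    log2fc_S_vs_P = direction * fc * ramp2(class),
    log2fc_R_vs_P = direction * fc * ramp3(class),
    baseline_log_mean = baseline,
    row.names = NULL)
  truth$log2fc_R_vs_S <- truth$log2fc_R_vs_P - truth$log2fc_S_vs_P
  attr(truth, "size_factors") <- sf
  attr(truth, "dog_offsets") <- dog_offset
  list(counts = counts, design = design, truth = truth)
}
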