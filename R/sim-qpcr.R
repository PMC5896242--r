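#' Simulate a qPCR Ct table (standard curves plus biopsy samples)
#'
#' Emits, for each target, a dilution-series standard curve
#' (`Ct = intercept + slope * log10(quantity) + Normal(0, sigma)`) and
#' unknown wells for every dog's B1/B2 biopsies, all in triplicate.
#' Targets mirror the tumor-burden assay: two tumor-specific markers
#' (`LINE_MYC`, `DLA_tumor`), one marker shared by host and tumor
#' (`DLA_common`) and the reference gene (`ACTB`). Tumor-marker input
#' scales with the dog's tumor burden: burden 1 at B1 everywhere;
#' at B2 regressive dogs fall to `b2_burden_regressive` (default 0.02,
#' near-complete loss of tumor DNA) while non-regressive dogs stay at 1.
#'
#' @param config a [sim_config()] (arms and seed).
#' @param standards vector of >= 3 positive known relative quantities.
#' @param slope,intercept true curve parameters (defaults: 100%
#'   efficiency, `-1/log10(2)` cycles per 10-fold; intercept 20 cycles).
#' @param sigma Gaussian Ct noise SD in cycles (default 0, noiseless).
#' @param b2_burden_regressive tumor-DNA fraction remaining at B2 in
#'   regressive dogs.
#' @return list with `ct_table` (`target`, `sample_id`, `role`,
#'   `quantity`, `replicate`, `ct`) and `truth` (`dog`, `burden_B2`).
#' @export
simulate_qpcr <- function(config, standards = 10^seq(0, -3),
                          slope = -1 / log10(2), intercept = 20,
                          sigma = 0, b2_burden_regressive = 0.02) {
  stopifnot(inherits(config, "sim_config"))
  if (any(standards <= 0)) stop("standard quantities must be positive")
  if (length(unique(standards)) < 3)
    stop("need >= 3 distinct standard concentrations")
  targets <- c("LINE_MYC", "DLA_tumor", "DLA_common", "ACTB")
  tumor_specific <- c("LINE_MYC", "DLA_tumor")
  withr::with_seed(config$seed + 3L, {
    dogs <- c(if (config$n_dogs_regressive > 0)
                paste0("R", seq_len(config$n_dogs_regressive)),
              if (config$n_dogs_nonregressive > 0)
                paste0("N", seq_len(config$n_dogs_nonregressive)))
    regressive <- grepl("^R", dogs)
    burden_b2 <- ifelse(regressive, b2_burden_regressive, 1)
    rows <- list()
    emit <- function(target, sample_id, role, quantity, true_q) {
      ct <- intercept + slope * log10(true_q) + rnorm(3, 0, sigma)
      rows[[length(rows) + 1L]] <<- data.frame(
        target = target, sample_id = sample_id, role = role,
        quantity = ifelse(role == "standard", quantity, NA_real_),
        replicate = 1:3, ct = ct)
    }
    for (tg in targets) {
      for (q in standards) emit(tg, "STD", "standard", q, q)
      for (d in seq_along(dogs)) for (b in 1:2) {
        burden <- if (b == 1) 1 else burden_b2[d]
        input <- if (tg %in% tumor_specific) 0.5 * burden else 0.5
        emit(tg, paste0(dogs[d], "_B", b), "unknown", NA_real_, input)
      }
    }
    ct_table <- do.call(rbind, rows)
    rownames(ct_table) <- NULL
    list(ct_table = ct_table,
         truth = data.frame(dog = dogs, burden_B2 = burden_b2,
                            row.names = NULL))
  })
}

#' Quantify tumor burden from a qPCR Ct table
#'
#' Fits a standard curve per target, averages triplicate Cts per unknown
#' well, inverts them to relative quantities, normalizes each target to
#' the reference gene within sample, and reports the B2/B1 burden change
#' per dog per tumor marker.
#'
#' @param ct_table long Ct table as produced by [simulate_qpcr()] (or read
#'   from TSV): columns `target`, `sample_id`, `role`, `quantity`,
#'   `replicate`, `ct`.
#' @param reference reference target (default `"ACTB"`).
#' @return list with `curves` (per-target [fit_standard_curve()] fits),
#'   `ratios` (`sample_id`, `target`, `ratio`) and `burden`
#'   (`dog`, `target`, `burden_change`).
#' @export
quantify_burden <- function(ct_table, reference = "ACTB") {
  stopifnot(reference %in% ct_table$target)
  targets <- unique(ct_table$target)
  curves <- lapply(setNames(targets, targets), function(tg) {
    std <- ct_table[ct_table$target == tg & ct_table$role == "standard", ]
    if (nrow(std) == 0) stop("no standards for target ", tg)
    fit_standard_curve(std)
  })
  unk <- ct_table[ct_table$role == "unknown", ]
  mean_ct <- stats::aggregate(ct ~ target + sample_id, unk, mean)
  mean_ct$q <- mapply(function(tg, ct) relative_quantity(ct, curves[[tg]]),
                      mean_ct$target, mean_ct$ct)
  ref <- mean_ct[mean_ct$target == reference, c("sample_id", "q")]
  ratios <- merge(mean_ct[mean_ct$target != reference, ],
                  ref, by = "sample_id", suffixes = c("", "_ref"))
  ratios$ratio <- normalize_to_reference(ratios$q, ratios$q_ref)
  # burden change B2/B1 per dog per target
  sid <- strsplit(ratios$sample_id, "_")
  ratios$dog <- vapply(sid, `[`, "", 1)
  ratios$biopsy <- vapply(sid, `[`, "", 2)
  b1 <- ratios[ratios$biopsy == "B1", c("dog", "target", "ratio")]
  b2 <- ratios[ratios$biopsy == "B2", c("dog", "target", "ratio")]
  burden <- merge(b2, b1, by = c("dog", "target"),
                  suffixes = c("_B2", "_B1"))
  burden$burden_change <- burden_change(burden$ratio_B2, burden$ratio_B1)
  list(curves = curves,
       ratios = ratios[, c("sample_id", "target", "ratio")],
       burden = burden[, c("dog", "target", "burden_change")])
}
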