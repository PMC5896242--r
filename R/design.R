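#' Validate a sample sheet for the paired serial-biopsy design
#'
#' @param design data.frame with columns `sample_id`, `dog`, `biopsy`
#'   (integer 1, 2, 3 in collection order), `regression_status`
#'   (`"REGRESSIVE"` or `"NON_REGRESSIVE"`).
#' @return the validated data.frame with normalized column types; factors
#'   are stored as character, `biopsy` as integer.
#' @export
sample_design <- function(design) {
  need <- c("sample_id", "dog", "biopsy", "regression_status")
  if (!all(need %in% names(design)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  design <- as.data.frame(design)[, need]
  design$sample_id <- as.character(design$sample_id)
  design$dog <- as.character(design$dog)
  design$biopsy <- as.integer(design$biopsy)
  design$regression_status <- as.character(design$regression_status)
  if (anyDuplicated(design$sample_id)) stop("duplicate sample ids")
  if (!all(design$regression_status %in% c("REGRESSIVE", "NON_REGRESSIVE")))
    stop("regression_status must be REGRESSIVE or NON_REGRESSIVE")
  if (!all(design$biopsy %in% 1:3)) stop("biopsy index must be 1, 2 or 3")
  tab <- table(design$dog)
  if (any(tab < 2)) stop("each dog needs >= 2 biopsies: ",
                         paste(names(tab)[tab < 2], collapse = ", "))
  if (any(tapply(design$regression_status, design$dog,
                 function(x) length(unique(x))) != 1))
    stop("a dog cannot change regression status")
  design
}

# Design matrix for the within-cohort paired model  ~ dog + biopsy.
# Dog columns absorb the pairing; biopsy columns carry the time effects
# whose linear combinations form the S/P, R/S, R/P contrasts.
design_matrix_paired <- function(design) {
  dog <- factor(design$dog)
  biopsy <- factor(design$biopsy)
  X <- model.matrix(~ dog + biopsy)
  rownames(X) <- design$sample_id
  X
}

# Design matrix for the two-cohort interaction model
#   ~ regression + regression:dog_nested + regression:biopsy
# with dogs re-indexed within status so the pairing columns are estimable
# in both arms (the usual nested encoding for individuals within groups).
design_matrix_interaction <- function(design) {
  status <- factor(design$regression_status,
                   levels = c("NON_REGRESSIVE", "REGRESSIVE"))
  if (nlevels(droplevels(status)) < 2)
    stop("interaction design needs both regression statuses")
  # nested dog index within status
  dogN <- integer(nrow(design))
  for (s in levels(status)) {
    sel <- design$regression_status == s
    dogN[sel] <- as.integer(factor(design$dog[sel]))
  }
  if (any(tapply(dogN, design$regression_status, max) < 2))
    stop("each regression-status arm needs >= 2 dogs")
  dogN <- factor(dogN)
  biopsy <- factor(design$biopsy)
  X <- model.matrix(~ status + status:dogN + status:biopsy)
  # drop aliased all-zero columns introduced by the nesting
  X <- X[, colSums(abs(X)) > 0, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("non-estimable design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  rownames(X) <- design$sample_id
  X
}

# Contrast vector (on model coefficients) for a named pairwise comparison
# in the paired design. Biopsies 1/2/3 correspond to the P/S/R phases of a
# fully regressing three-biopsy tumor.
paired_contrast <- function(X, name) {
  cn <- colnames(X)
  v <- setNames(numeric(ncol(X)), cn)
  has2 <- "biopsy2" %in% cn
  has3 <- "biopsy3" %in% cn
  switch(name,
    S_vs_P = , B2_vs_B1 = {
      if (!has2) stop("contrast ", name, " needs biopsy 2 samples")
      v["biopsy2"] <- 1
    },
    R_vs_S = {
      if (!has2 || !has3) stop("contrast R_vs_S needs biopsies 2 and 3")
      v["biopsy3"] <- 1; v["biopsy2"] <- -1
    },
    R_vs_P = , B3_vs_B1 = {
      if (!has3) stop("contrast ", name, " needs biopsy 3 samples")
      v["biopsy3"] <- 1
    },
    stop("unknown contrast: ", name)
  )
  v
}
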