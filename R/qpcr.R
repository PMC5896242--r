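#' Fit a qPCR standard curve
#'
#' Least-squares fit of `Ct = slope * log10(quantity) + intercept` over a
#' dilution series of known relative DNA quantities. The amplification
#' efficiency implied by the slope is `10^(-1/slope) - 1` (a slope of
#' -1/log10(2) = -3.3219 is 100% efficiency: one extra cycle per
#' two-fold dilution).
#'
#' @param standards data.frame with columns `quantity` (> 0, at least 3
#'   distinct values) and `ct`; replicate wells may appear as extra rows.
#' @return object of class `"standard_curve"`: list with `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `n`.
#' @examples
#' sc <- fit_standard_curve(data.frame(quantity = c(1, 0.1, 0.01),
#'                                     ct = c(20, 23.3219, 26.6439)))
#' sc$slope # -3.3219...
#' @export
fit_standard_curve <- function(standards) {
  stopifnot(all(c("quantity", "ct") %in% names(standards)))
  q <- standards$quantity
  ct <- standards$ct
  if (any(q <= 0)) stop("standard quantities must be positive")
  if (length(unique(q)) < 3)
    stop("need >= 3 distinct standard quantities")
  fit <- lm(ct ~ log10(q))
  slope <- unname(coef(fit)[2])
  sstot <- sum((ct - mean(ct))^2)
  r2 <- if (sstot == 0) 1 else 1 - sum(stats::resid(fit)^2) / sstot
  structure(list(slope = slope,
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 efficiency = 10^(-1 / slope) - 1,
                 n = length(ct)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("qPCR standard curve: Ct = %.4f * log10(q) + %.4f  (R^2 = %.4f, efficiency = %.1f%%)\n",
              x$slope, x$intercept, x$r_squared, 100 * x$efficiency))
  invisible(x)
}

#' Invert a standard curve: Ct to relative quantity
#'
#' Triplicate Cts for one reaction should be arithmetically averaged
#' before inversion.
#'
#' @param ct observed cycle threshold(s).
#' @param curve a [fit_standard_curve()] result.
#' @return relative quantity `10^((ct - intercept) / slope)`.
#' @export
relative_quantity <- function(ct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  10^((ct - curve$intercept) / curve$slope)
}

#' Normalize a target quantity to a reference gene
#'
#' @param q_target,q_ref relative quantities (reference, e.g. ACTB,
#'   must be positive).
#' @return ratio `q_target / q_ref`.
#' @export
normalize_to_reference <- function(q_target, q_ref) {
  if (any(q_ref <= 0)) stop("reference quantity must be positive")
  q_target / q_ref
}

#' Fraction of tumor DNA remaining between two biopsies
#'
#' @param ratio_B2,ratio_B1 reference-normalized tumor-marker ratios at
#'   the post- and pre-treatment biopsies.
#' @return `ratio_B2 / ratio_B1`; `NA` with a warning where
#'   `ratio_B1 == 0`.
#' @export
burden_change <- function(ratio_B2, ratio_B1) {
  out <- ratio_B2 / ratio_B1
  bad <- ratio_B1 == 0
  if (any(bad)) {
    warning("pre-treatment ratio is zero; burden change undefined")
    out[bad] <- NA_real_
  }
  out
}
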