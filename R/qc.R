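#' Genotype quality-control thresholds
#'
#' Defaults follow standard GWAS practice for imputed case-control data:
#' variants are removed when call rate < 98%, Hardy-Weinberg equilibrium
#' P in controls < 1e-4, minor-allele frequency < 0.05, or imputation
#' quality R-squared <= 0.3 (the retention rule is strictly "> 0.3").
#'
#' @param min_call_rate Minimum fraction of non-missing calls (kept when
#'   call rate >= this value).
#' @param hwe_p_min Minimum HWE P in controls.
#' @param maf_min Minimum minor-allele frequency (kept when MAF >= this
#'   value; the removal rule is strictly "< maf_min").
#' @param imp_r2_min Imputation-quality floor (kept when R2 > this value).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.98, hwe_p_min = 1e-4,
                          maf_min = 0.05, imp_r2_min = 0.3) {
  vals <- c(min_call_rate, hwe_p_min, maf_min, imp_r2_min)
  if (any(vals < 0 | vals > 1)) stopf("all thresholds must lie in [0, 1]")
  structure(list(min_call_rate = min_call_rate, hwe_p_min = hwe_p_min,
                 maf_min = maf_min, imp_r2_min = imp_r2_min),
            class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit of observed genotype counts
#' against the expectation from the sample allele frequency, without
#' continuity correction. Monomorphic variants return P = 1 by
#' convention.
#'
#' @param nAA,nAa,naa Genotype counts (0, 1, 2 copies of the effect
#'   allele); vectorized.
#' @return P-value(s) in (0, 1\].
#' @examples
#' hwe_chisq(25, 50, 25)   # exact HWE proportions: P = 1
#' hwe_chisq(50, 0, 50)    # chi-square 100
#' @export
hwe_chisq <- function(nAA, nAa, naa) {
  if (any(c(nAA, nAa, naa) < 0)) stopf("genotype counts must be nonnegative")
  n <- nAA + nAa + naa
  if (any(n <= 0)) stopf("total genotype count must be positive")
  q <- (2 * naa + nAa) / (2 * n)   # effect-allele frequency
  p <- 1 - q
  eAA <- n * p^2; eAa <- 2 * n * p * q; eaa <- n * q^2
  chi <- ifelse(q == 0 | q == 1, 0,
                (nAA - eAA)^2 / eAA + (nAa - eAa)^2 / eAa +
                  (naa - eaa)^2 / eaa)
  pchisq(chi, df = 1, lower.tail = FALSE)
}

#' Apply genotype QC filters to a panel
#'
#' Removes variants failing any of: call rate below
#' `thr$min_call_rate`; HWE chi-square P **in controls** below
#' `thr$hwe_p_min`; minor-allele frequency strictly below `thr$maf_min`;
#' imputation R-squared not strictly above `thr$imp_r2_min` (skipped when
#' the panel carries no imputation quality). The attached
#' `"qc_tally"` attribute counts, per filter, how many variants violated
#' it (a variant can violate several).
#'
#' @param panel A [genotype_panel()].
#' @param controls_mask Logical vector over samples marking controls
#'   (used for the HWE test); `NULL` evaluates HWE in all samples.
#' @param thr A [qc_thresholds()].
#' @return The filtered `genotype_panel`, with attribute `qc_tally`.
#' @export
qc_filter <- function(panel, controls_mask = NULL, thr = qc_thresholds()) {
  stopifnot(inherits(panel, "genotype_panel"))
  d <- panel$dosages
  if (is.null(controls_mask)) controls_mask <- rep(TRUE, nrow(d))
  if (length(controls_mask) != nrow(d))
    stopf("controls_mask length does not match sample count")

  call_rate <- colMeans(!is.na(d))
  f <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  hc <- dosage_hard_calls(d[controls_mask, , drop = FALSE])
  hwe_p <- hwe_chisq(hc[, "n0"], hc[, "n1"], hc[, "n2"])

  bad_call <- call_rate < thr$min_call_rate
  bad_maf <- maf < thr$maf_min
  bad_hwe <- hwe_p < thr$hwe_p_min
  bad_imp <- if (is.null(panel$imputation_r2)) rep(FALSE, ncol(d)) else
    !(panel$imputation_r2 > thr$imp_r2_min)
  tally <- c(call_rate = sum(bad_call), hwe = sum(bad_hwe),
             maf = sum(bad_maf), imputation_r2 = sum(bad_imp))
  keep <- !(bad_call | bad_maf | bad_hwe | bad_imp)
  if (!any(keep)) warnf("all %d variants removed by QC", ncol(d))
  out <- subset_panel(panel, variants = which(keep))
  attr(out, "qc_tally") <- tally
  out
}
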