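#' Construct a genotype panel
#'
#' A samples-by-variants dosage container shared by the reference-panel and
#' cohort roles. Dosages are expected counts of the effect (alt) allele in
#' \[0, 2\]; `NA` encodes a missing call.
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param variants Data frame with at least `chrom`, `pos`, `ref`, `alt`,
#'   `rsid` (one row per variant, unique rsid and (chrom, pos)).
#' @param dosages Numeric matrix, `length(sample_ids)` rows by
#'   `nrow(variants)` columns, values in \[0, 2\] or `NA`.
#' @param imputation_r2 Optional per-variant imputation quality in \[0, 1\].
#' @param hard_calls Optional variants-by-3 integer matrix of genotype
#'   counts (`n0`, `n1`, `n2` copies of the alt allele); computed from
#'   rounded dosages when omitted.
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(sample_ids, variants, dosages,
                           imputation_r2 = NULL, hard_calls = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stopf("duplicated sample ids")
  need <- c("chrom", "pos", "ref", "alt", "rsid")
  if (!all(need %in% names(variants)))
    stopf("variants must have columns %s", paste(need, collapse = ", "))
  if (any(variants$pos < 1)) stopf("variant positions must be >= 1")
  if (any(variants$ref == variants$alt)) stopf("ref and alt alleles equal")
  if (anyDuplicated(variants$rsid)) stopf("duplicated variant rsid")
  if (anyDuplicated(paste(variants$chrom, variants$pos)))
    stopf("duplicated (chrom, pos) variant key")
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != length(sample_ids) || ncol(dosages) != nrow(variants))
    stopf("dosage dimensions do not match samples x variants")
  if (length(dosages) && !all(is.na(dosages))) {
    rng <- range(dosages, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) stopf("dosages must lie in [0, 2]")
  }
  dimnames(dosages) <- list(sample_ids, variants$rsid)
  if (!is.null(imputation_r2)) {
    if (length(imputation_r2) != nrow(variants) ||
        any(imputation_r2 < 0 | imputation_r2 > 1, na.rm = TRUE))
      stopf("imputation_r2 must be per-variant values in [0, 1]")
  }
  if (is.null(hard_calls)) hard_calls <- dosage_hard_calls(dosages)
  structure(list(sample_ids = sample_ids,
                 variants = as.data.frame(variants),
                 dosages = dosages,
                 imputation_r2 = imputation_r2,
                 hard_calls = hard_calls),
            class = "genotype_panel")
}

# genotype counts (0/1/2 alt copies) from rounded dosages, per variant
dosage_hard_calls <- function(dosages) {
  hc <- vapply(seq_len(ncol(dosages)), function(j) {
    g <- pmin(2L, pmax(0L, as.integer(round(dosages[, j]))))
    c(n0 = sum(g == 0L, na.rm = TRUE),
      n1 = sum(g == 1L, na.rm = TRUE),
      n2 = sum(g == 2L, na.rm = TRUE))
  }, integer(3))
  t(hc)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d samples x %d variants on %d chromosome(s)\n",
              length(x$sample_ids), nrow(x$variants),
              length(unique(x$variants$chrom))))
  invisible(x)
}

#' Subset a genotype panel
#'
#' @param x A [genotype_panel()].
#' @param samples,variants Indices (logical, integer, or character ids)
#'   selecting samples / variants; `NULL` keeps all.
#' @param ... Unused.
#' @return A `genotype_panel`.
#' @export
subset_panel <- function(x, samples = NULL, variants = NULL, ...) {
  stopifnot(inherits(x, "genotype_panel"))
  si <- if (is.null(samples)) seq_along(x$sample_ids) else samples
  if (is.character(si)) si <- match(si, x$sample_ids)
  vi <- if (is.null(variants)) seq_len(nrow(x$variants)) else variants
  if (is.character(vi)) vi <- match(vi, x$variants$rsid)
  genotype_panel(x$sample_ids[si],
                 x$variants[vi, , drop = FALSE],
                 x$dosages[si, vi, drop = FALSE],
                 imputation_r2 = x$imputation_r2[vi])
}
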