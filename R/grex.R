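STRAND_AMBIGUOUS <- c("A/T", "T/A", "C/G", "G/C")

#' Harmonize a weight model's predictors to a genotype panel
#'
#' Predictors are matched to panel variants on (chrom, pos). Outcomes per
#' predictor:
#' \describe{
#'   \item{`matched`}{same ref/alt alleles; cohort dosage used as-is.}
#'   \item{`flipped`}{ref/alt swapped; dosage enters as `2 - d`.}
#'   \item{`ambiguous`}{model allele pair is strand-ambiguous (A/T or
#'     C/G); dropped.}
#'   \item{`mismatch`}{position matches but the allele pair is
#'     irreconcilable (e.g. A/C vs A/G); dropped with a warning.}
#'   \item{`missing`}{no panel variant at that position.}
#' }
#'
#' @param model A `weight_model`.
#' @param panel A [genotype_panel()].
#' @return Data frame, one row per model predictor: `rsid`, `weight`,
#'   `ref_maf`, `status`, `panel_col` (column index into the panel's
#'   dosages, `NA` unless matched/flipped), `flip` (logical).
#' @export
harmonize <- function(model, panel) {
  stopifnot(inherits(model, "weight_model"),
            inherits(panel, "genotype_panel"))
  p <- model$predictors
  out <- data.frame(rsid = p$rsid, weight = p$weight, ref_maf = p$ref_maf,
                    status = "missing", panel_col = NA_integer_,
                    flip = FALSE, stringsAsFactors = FALSE)
  if (!nrow(p)) return(out)
  key <- paste(panel$variants$chrom, panel$variants$pos)
  hit <- match(paste(p$chrom, p$pos), key)
  for (i in seq_len(nrow(p))) {
    pair <- paste0(p$ref[i], "/", p$alt[i])
    if (pair %in% STRAND_AMBIGUOUS) {
      out$status[i] <- "ambiguous"
      next
    }
    j <- hit[i]
    if (is.na(j)) next
    pr <- panel$variants$ref[j]; pa <- panel$variants$alt[j]
    if (pr == p$ref[i] && pa == p$alt[i]) {
      out$status[i] <- "matched"; out$panel_col[i] <- j
    } else if (pr == p$alt[i] && pa == p$ref[i]) {
      out$status[i] <- "flipped"; out$panel_col[i] <- j; out$flip[i] <- TRUE
    } else {
      out$status[i] <- "mismatch"
      warnf("gene %s predictor %s: allele pair %s/%s vs panel %s/%s; dropped",
            model$gene_id, p$rsid[i], p$ref[i], p$alt[i], pr, pa)
    }
  }
  out
}

#' Compute genetically regulated expression (GReX) for one gene
#'
#' GReX is the weighted sum of harmonized effect-allele dosages over the
#' model's predictors. Predictors missing from the panel (or dropped at
#' harmonization) contribute their weight times the population-mean
#' dosage `2 * ref_maf` under the default `"mean"` policy, preserving the
#' linear form; `"omit"` simply drops the term.
#'
#' @param model A `weight_model`.
#' @param panel A [genotype_panel()] (typically after [qc_filter()]).
#' @param missing_policy `"mean"` (default) or `"omit"`.
#' @return Numeric vector over panel samples with attribute
#'   `"provenance"` (counts: matched, flipped, dropped, missing), or
#'   `NULL` when no predictor could be matched.
#' @examples
#' # weights {0.5, -1} on dosages {2, 1} give 0.5*2 - 1*1 = 0
#' @export
compute_grex <- function(model, panel,
                         missing_policy = c("mean", "omit")) {
  missing_policy <- match.arg(missing_policy)
  h <- harmonize(model, panel)
  use <- h$status %in% c("matched", "flipped")
  prov <- c(matched = sum(h$status == "matched"),
            flipped = sum(h$status == "flipped"),
            dropped = sum(h$status %in% c("ambiguous", "mismatch")),
            missing = sum(h$status == "missing"))
  if (!any(use)) {
    message(sprintf("gene %s: no predictor matched the panel; GReX absent",
                    model$gene_id))
    return(NULL)
  }
  x <- panel$dosages[, h$panel_col[use], drop = FALSE]
  flip <- h$flip[use]
  if (any(flip)) x[, flip] <- 2 - x[, flip]
  g <- drop(x %*% h$weight[use])
  if (missing_policy == "mean") {
    unused <- which(!use)
    if (length(unused)) {
      maf <- h$ref_maf[unused]
      known <- is.finite(maf)
      if (any(!known))
        warnf("gene %s: %d unmatched predictor(s) lack ref_maf; omitted",
              model$gene_id, sum(!known))
      g <- g + sum(h$weight[unused][known] * 2 * maf[known])
    }
  }
  attr(g, "provenance") <- prov
  g
}

#' Compute a GReX matrix for many models
#'
#' @param models Named list of `weight_model`s.
#' @param panel A [genotype_panel()].
#' @param missing_policy Passed to [compute_grex()].
#' @return A `grex_matrix`: list with `values` (genes x samples matrix)
#'   and `provenance` (data frame gene, n_variants, matched, flipped,
#'   dropped, missing). Genes with no matched predictor are absent from
#'   `values` and flagged in `provenance`.
#' @export
compute_grex_all <- function(models, panel,
                             missing_policy = c("mean", "omit")) {
  missing_policy <- match.arg(missing_policy)
  vals <- list(); prov <- list()
  for (m in models) {
    g <- compute_grex(m, panel, missing_policy)
    pv <- if (is.null(g)) c(matched = 0L, flipped = 0L, dropped = 0L,
                            missing = m$n_variants) else
      attr(g, "provenance")
    prov[[m$gene_id]] <- data.frame(gene = m$gene_id,
                                    n_variants = m$n_variants,
                                    matched = pv["matched"],
                                    flipped = pv["flipped"],
                                    dropped = pv["dropped"],
                                    missing = pv["missing"],
                                    row.names = NULL)
    if (!is.null(g)) vals[[m$gene_id]] <- as.numeric(g)
  }
  values <- if (length(vals))
    do.call(rbind, vals) else
      matrix(numeric(0), 0, length(panel$sample_ids))
  colnames(values) <- panel$sample_ids
  structure(list(values = values, provenance = do.call(rbind, prov)),
            class = "grex_matrix")
}

#' @export
print.grex_matrix <- function(x, ...) {
  cat(sprintf("<grex_matrix> %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
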