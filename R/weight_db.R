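#' Write a weight database (PredictDB-style TSV dialect)
#'
#' Two tab-separated tables are written to `dir`:
#' \describe{
#'   \item{`weights.tsv`}{one row per (gene, predictor):
#'     `gene, rsid, chrom, pos, ref_allele, eff_allele, weight, ref_maf`.
#'     `ref_maf` (effect-allele frequency in the training reference) backs
#'     the mean-dosage policy for predictors missing from a cohort.}
#'   \item{`extra.tsv`}{one summary row per gene:
#'     `gene, genename, pred_perf_r2, n_snps_in_model, chrom, tss`.}
#' }
#' The round trip `read_weight_db(write_weight_db(m))` is lossless.
#'
#' @param models Named list of `weight_model`s.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [read_weight_db()]
#' @export
write_weight_db <- function(models, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- do.call(rbind, lapply(models, function(m) {
    if (!m$n_variants) return(NULL)
    data.frame(gene = m$gene_id, rsid = m$predictors$rsid,
               chrom = m$predictors$chrom, pos = m$predictors$pos,
               ref_allele = m$predictors$ref,
               eff_allele = m$predictors$alt,
               weight = sprintf("%.17g", m$predictors$weight),
               ref_maf = sprintf("%.17g", m$predictors$ref_maf),
               stringsAsFactors = FALSE)
  }))
  if (is.null(wt))
    wt <- data.frame(gene = character(0), rsid = character(0),
                     chrom = character(0), pos = integer(0),
                     ref_allele = character(0), eff_allele = character(0),
                     weight = character(0), ref_maf = character(0))
  ex <- do.call(rbind, lapply(models, function(m) {
    data.frame(gene = m$gene_id, genename = m$gene_id,
               pred_perf_r2 = sprintf("%.17g", m$pred_r2),
               n_snps_in_model = m$n_variants,
               chrom = m$chrom, tss = sprintf("%.0f", m$tss),
               stringsAsFactors = FALSE)
  }))
  write.table(wt, file.path(dir, "weights.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ex, file.path(dir, "extra.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a weight database written by [write_weight_db()]
#'
#' Validates the tables: allele strings must be A/C/G/T, a duplicated
#' (gene, rsid) weight row or a weights row without a matching summary row
#' is a hard error naming the offender.
#'
#' @param dir Directory holding `weights.tsv` and `extra.tsv`.
#' @return Named list of `weight_model`s, in `extra.tsv` order.
#' @export
read_weight_db <- function(dir) {
  wf <- file.path(dir, "weights.tsv")
  ef <- file.path(dir, "extra.tsv")
  if (!file.exists(wf) || !file.exists(ef))
    stopf("weight database at '%s' is missing weights.tsv or extra.tsv", dir)
  wt <- read.delim(wf, colClasses = c(pos = "numeric", weight = "numeric",
                                      ref_maf = "numeric"))
  ex <- read.delim(ef, colClasses = c(pred_perf_r2 = "numeric",
                                      tss = "numeric"))
  ok_allele <- function(a) a %in% c("A", "C", "G", "T")
  bad <- which(!ok_allele(wt$ref_allele) | !ok_allele(wt$eff_allele))
  if (length(bad))
    stopf("unknown allele characters in weights.tsv row(s) %s",
          paste(head(bad, 5), collapse = ", "))
  key <- paste(wt$gene, wt$rsid)
  dup <- which(duplicated(key))
  if (length(dup))
    stopf("duplicated (gene, rsid) row in weights.tsv: %s", key[dup[1]])
  orphan <- setdiff(unique(wt$gene), ex$gene)
  if (length(orphan))
    stopf("gene '%s' has weights but no summary row in extra.tsv",
          orphan[1])
  out <- lapply(seq_len(nrow(ex)), function(i) {
    rows <- wt[wt$gene == ex$gene[i], , drop = FALSE]
    pred <- data.frame(rsid = rows$rsid, chrom = rows$chrom,
                       pos = rows$pos, ref = rows$ref_allele,
                       alt = rows$eff_allele, weight = rows$weight,
                       ref_maf = rows$ref_maf, stringsAsFactors = FALSE)
    rownames(pred) <- NULL
    if (nrow(pred) != ex$n_snps_in_model[i])
      stopf("gene '%s': %d weight rows but n_snps_in_model = %d",
            ex$gene[i], nrow(pred), ex$n_snps_in_model[i])
    weight_model(ex$gene[i], ex$chrom[i], ex$tss[i], pred,
                 ex$pred_perf_r2[i])
  })
  names(out) <- ex$gene
  out
}
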