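PHENO_HEADER <- c("sample_id", "case", "age", "sex", "center", "batch",
                  "pc1", "pc2", "pc3", "pc4", "site")

#' Write / read a dosage TSV
#'
#' Rows are variants: `chrom, pos, rsid, ref, alt` (plus `imputation_r2`
#' when available), then one dosage column per sample.
#'
#' @param panel A [genotype_panel()].
#' @param path File path.
#' @return `path` invisibly (writer); a `genotype_panel` (reader).
#' @export
write_dosage_tsv <- function(panel, path) {
  v <- panel$variants[, c("chrom", "pos", "rsid", "ref", "alt")]
  if (!is.null(panel$imputation_r2)) v$imputation_r2 <- panel$imputation_r2
  tab <- cbind(v, as.data.frame(t(panel$dosages)))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  meta_cols <- intersect(c("chrom", "pos", "rsid", "ref", "alt",
                           "imputation_r2"), names(tab))
  v <- tab[, meta_cols, drop = FALSE]
  d <- t(as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE]))
  genotype_panel(rownames(d), v, d,
                 imputation_r2 = if ("imputation_r2" %in% meta_cols)
                   v$imputation_r2 else NULL)
}

#' Write a genotype panel as VCF v4.2 with per-sample DS dosages
#'
#' Emits one biallelic record per variant with `FORMAT` field `DS`
#' (effect-allele dosage) and, when available, an `R2` INFO tag carrying
#' imputation quality.
#'
#' @param panel A [genotype_panel()].
#' @param path Output file (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=grextas",
    "##INFO=<ID=R2,Number=1,Type=Float,Description=\"Imputation quality\">",
    paste0("##FORMAT=<ID=DS,Number=1,Type=Float,",
           "Description=\"Estimated alternate allele dosage\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", panel$sample_ids), collapse = "\t")
  ), con)
  v <- panel$variants
  info <- if (is.null(panel$imputation_r2)) rep(".", nrow(v)) else
    sprintf("R2=%.6g", panel$imputation_r2)
  body <- vapply(seq_len(nrow(v)), function(i) {
    ds <- format(panel$dosages[, i], trim = TRUE, digits = 10)
    ds[is.na(panel$dosages[, i])] <- "."
    paste(c(v$chrom[i], v$pos[i], v$rsid[i], v$ref[i], v$alt[i], ".",
            "PASS", info[i], "DS", ds), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read dosages from a VCF with a DS FORMAT field
#'
#' Multi-allelic records are skipped with a warning; the `R2` INFO tag,
#' when present, populates `imputation_r2`.
#'
#' @param path VCF file (plain or bgzipped).
#' @return A [genotype_panel()].
#' @export
read_vcf_dosages <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    warnf("skipping %d multi-allelic record(s)", sum(multi))
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  r2 <- suppressWarnings(
    as.numeric(vcfR::extract.info(vcf, element = "R2")))
  v <- data.frame(chrom = fix$CHROM, pos = as.numeric(fix$POS),
                  rsid = fix$ID, ref = fix$REF, alt = fix$ALT,
                  stringsAsFactors = FALSE)
  genotype_panel(colnames(ds), v, t(ds),
                 imputation_r2 = if (all(is.na(r2))) NULL else r2)
}

#' Write / read an expression TSV (genes x samples)
#'
#' @param expression Genes x samples matrix with dimnames.
#' @param path File path.
#' @return `path` invisibly (writer); the matrix (reader).
#' @export
write_expression_tsv <- function(expression, path) {
  tab <- data.frame(gene_id = rownames(expression),
                    expression, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  tab <- read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$gene_id
  m
}

#' Write / read the phenotype table
#'
#' The header is exactly
#' `sample_id, case, age, sex, center, batch, pc1, pc2, pc3, pc4, site`.
#'
#' @param pheno Phenotype data frame.
#' @param path File path.
#' @return `path` invisibly (writer); the data frame (reader).
#' @export
write_phenotype_tsv <- function(pheno, path) {
  if (!all(PHENO_HEADER %in% names(pheno)))
    stopf("phenotype table must have columns %s",
          paste(PHENO_HEADER, collapse = ", "))
  write.table(pheno[, PHENO_HEADER], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!identical(names(tab), PHENO_HEADER))
    stopf("phenotype header must be exactly: %s",
          paste(PHENO_HEADER, collapse = ", "))
  if (anyNA(tab$case)) stopf("missing case status")
  bad <- (tab$site != "control") != (tab$case == 1)
  if (any(bad)) stopf("site must be 'control' exactly for controls")
  tab
}

#' Write / read a gene annotation TSV
#'
#' Columns: `gene_id, chrom, tss, strand`.
#'
#' @param annotation Data frame.
#' @param path File path.
#' @return `path` invisibly (writer); the data frame (reader).
#' @export
write_gene_annotation_tsv <- function(annotation, path) {
  write.table(annotation[, c("gene_id", "chrom", "tss", "strand")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_annotation_tsv
#' @export
read_gene_annotation_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read an index-variant list (rsid, chrom, pos)
#'
#' @param path TSV with header `rsid, chrom, pos`.
#' @return Data frame.
#' @export
read_index_variants <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("rsid", "chrom", "pos") %in% names(tab)))
    stopf("index-variant file needs columns rsid, chrom, pos")
  tab
}

#' Write simulation ground truth as TSV files
#'
#' Writes `truth_genes.tsv` (gene_id, chrom, tss, h2, realized_h2,
#' log_or) and `truth_weights.tsv` (gene_id, rsid, weight) to `dir`.
#'
#' @param truth A `truth_table`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_truth_tsv <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.table(truth$genes, file.path(dir, "truth_genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(truth$weights, file.path(dir, "truth_weights.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
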