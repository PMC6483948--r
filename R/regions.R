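#' Build merged GWAS risk regions around index variants
#'
#' Each index variant defines a window `[pos - flank, pos + flank]`
#' (floored at 1); per chromosome, windows that overlap (closed 1-based
#' intervals; sharing a single bp counts) are merged transitively into a
#' region spanning the minimum and maximum coordinates, carrying every
#' member index variant.
#'
#' @param index_variants Data frame with columns `rsid`, `chrom`, `pos`.
#' @param flank Half-window in bp; default 1 Mb.
#' @return Data frame of regions: `chrom, start, end, n_index,
#'   index_rsids` (comma-separated); regions on one chromosome are
#'   pairwise disjoint and sorted.
#' @examples
#' iv <- data.frame(rsid = c("a", "b", "c"), chrom = "chr1",
#'                  pos = c(1e6, 2.5e6, 5e6))
#' build_regions(iv)
#' @export
build_regions <- function(index_variants, flank = 1e6) {
  need <- c("rsid", "chrom", "pos")
  if (!all(need %in% names(index_variants)))
    stopf("index variants need columns %s", paste(need, collapse = ", "))
  if (flank <= 0) stopf("'flank' must be positive")
  if (any(index_variants$pos < 1)) stopf("positions must be >= 1")
  out <- list()
  for (ch in unique(index_variants$chrom)) {
    v <- index_variants[index_variants$chrom == ch, , drop = FALSE]
    v <- v[order(v$pos), , drop = FALSE]
    start <- pmax(1, v$pos - flank)
    end <- v$pos + flank
    cur_s <- start[1]; cur_e <- end[1]; members <- v$rsid[1]
    flush <- function(s, e, m)
      data.frame(chrom = ch, start = s, end = e, n_index = length(m),
                 index_rsids = paste(m, collapse = ","),
                 stringsAsFactors = FALSE)
    for (i in seq_len(nrow(v))[-1]) {
      if (start[i] <= cur_e) {            # closed intervals: touching merges
        cur_e <- max(cur_e, end[i])
        members <- c(members, v$rsid[i])
      } else {
        out[[length(out) + 1L]] <- flush(cur_s, cur_e, members)
        cur_s <- start[i]; cur_e <- end[i]; members <- v$rsid[i]
      }
    }
    out[[length(out) + 1L]] <- flush(cur_s, cur_e, members)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Summarize genes and association evidence within one risk region
#'
#' Counts annotated genes whose TSS falls inside the region (endpoints
#' inclusive), genes with a prediction model per tissue, their overlap,
#' and genes reaching nominal association in either tissue; the percent
#' reduction of the candidate list is `100 * (1 - n_assoc / n_ccds)`.
#'
#' @param region One-row data frame (or list) with `chrom`, `start`,
#'   `end`.
#' @param gene_annotation Data frame `gene_id, chrom, tss`.
#' @param models_ct,models_wb Gene ids with imputable expression in the
#'   two tissue models (character vectors, or named lists of
#'   `weight_model`s).
#' @param assoc_results Data frame with columns `gene`, `tissue`
#'   (`"ct"`/`"wb"`), `p`.
#' @param p_cut Nominal association cutoff (inclusive, `p <= p_cut`);
#'   default 0.05.
#' @return One-row data frame: `chrom, start, end, n_ccds, n_models_ct,
#'   n_models_wb, n_overlap, pct_overlap, n_assoc, pct_reduced`
#'   (`pct_reduced` is `NA` when the region holds no annotated gene).
#' @export
summarize_region <- function(region, gene_annotation, models_ct,
                             models_wb, assoc_results, p_cut = 0.05) {
  ids <- function(x) if (is.list(x)) names(x) else as.character(x)
  inreg <- gene_annotation$chrom == region$chrom &
    gene_annotation$tss >= region$start & gene_annotation$tss <= region$end
  genes <- gene_annotation$gene_id[inreg]
  ct <- intersect(genes, ids(models_ct))
  wb <- intersect(genes, ids(models_wb))
  both <- intersect(ct, wb)
  uni <- union(ct, wb)
  sig <- assoc_results$gene[is.finite(assoc_results$p) &
                              assoc_results$p <= p_cut]
  n_assoc <- length(intersect(uni, unique(sig)))
  n_ccds <- length(genes)
  data.frame(chrom = region$chrom, start = region$start, end = region$end,
             n_ccds = n_ccds,
             n_models_ct = length(ct), n_models_wb = length(wb),
             n_overlap = length(both),
             pct_overlap = if (length(uni)) 100 * length(both) / length(uni)
               else NA_real_,
             n_assoc = n_assoc,
             pct_reduced = if (n_ccds) 100 * (1 - n_assoc / n_ccds)
               else NA_real_,
             stringsAsFactors = FALSE)
}

#' Summarize every region of a region table
#'
#' @param regions Data frame from [build_regions()].
#' @inheritParams summarize_region
#' @return Data frame with one [summarize_region()] row per region.
#' @export
summarize_regions <- function(regions, gene_annotation, models_ct,
                              models_wb, assoc_results, p_cut = 0.05) {
  do.call(rbind, lapply(seq_len(nrow(regions)), function(i)
    summarize_region(regions[i, ], gene_annotation, models_ct, models_wb,
                     assoc_results, p_cut)))
}

#' LD r-squared between two dosage vectors
#'
#' Squared Pearson correlation of allele dosages.
#'
#' @param dosage_a,dosage_b Equal-length numeric vectors (>= 3), each
#'   with positive variance.
#' @return Value in \[0, 1\]; `NA` with a warning when either vector has
#'   zero variance.
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  if (length(dosage_a) != length(dosage_b) || length(dosage_a) < 3)
    stopf("need equal-length dosage vectors of length >= 3")
  if (sd(dosage_a) == 0 || sd(dosage_b) == 0) {
    warnf("zero-variance dosage vector: LD undefined")
    return(NA_real_)
  }
  cor(dosage_a, dosage_b)^2
}

#' Screen a gene model for novelty against known GWAS index variants
#'
#' A finding is novel iff every variant predictor of the model is at
#' least `distance_min` bp from every known index variant on the same
#' chromosome, **and** no predictor is in LD (`r^2 >= r2_max`) with any
#' index variant present in the LD panel. Predictor-index pairs absent
#' from the LD panel are treated as unlinked (and noted).
#'
#' @param model A `weight_model`.
#' @param known Data frame of index variants: `rsid, chrom, pos`.
#' @param ld_panel A [genotype_panel()] covering (some of) the
#'   predictors and index variants; matched on (chrom, pos).
#' @param r2_max LD threshold; a pair at or above it voids novelty.
#'   Default 0.2.
#' @param distance_min Distance threshold in bp; default 1 Mb.
#' @return List with `novel` (logical), `evidence` (the worst offending
#'   predictor-index pair, or `NULL`), and `n_unscored_pairs` (pairs
#'   lacking LD data).
#' @export
novelty_check <- function(model, known, ld_panel, r2_max = 0.2,
                          distance_min = 1e6) {
  stopifnot(inherits(model, "weight_model"))
  p <- model$predictors
  worst <- NULL
  unscored <- 0L
  key <- paste(ld_panel$variants$chrom, ld_panel$variants$pos)
  pcol <- match(paste(p$chrom, p$pos), key)
  kcol <- match(paste(known$chrom, known$pos), key)
  for (i in seq_len(nrow(p))) {
    same <- which(known$chrom == p$chrom[i])
    for (j in same) {
      d <- abs(known$pos[j] - p$pos[i])
      r2 <- if (!is.na(pcol[i]) && !is.na(kcol[j])) {
        if (pcol[i] == kcol[j]) 1 else
          suppressWarnings(ld_r2(ld_panel$dosages[, pcol[i]],
                                 ld_panel$dosages[, kcol[j]]))
      } else {
        unscored <- unscored + 1L
        NA_real_
      }
      viol_dist <- d < distance_min
      viol_ld <- is.finite(r2) && r2 >= r2_max
      if (viol_dist || viol_ld) {
        cand <- list(predictor = p$rsid[i], index = known$rsid[j],
                     distance = d, r2 = r2)
        if (is.null(worst) ||
            (is.finite(r2) && (!is.finite(worst$r2) || r2 > worst$r2)) ||
            (!is.finite(worst$r2) && d < worst$distance))
          worst <- cand
      }
    }
  }
  list(novel = is.null(worst), evidence = worst,
       n_unscored_pairs = unscored)
}

#' Novelty screen over many models
#'
#' @param models Named list of `weight_model`s.
#' @inheritParams novelty_check
#' @return Named logical vector over genes.
#' @export
novelty_screen <- function(models, known, ld_panel, r2_max = 0.2,
                           distance_min = 1e6) {
  vapply(models, function(m)
    novelty_check(m, known, ld_panel, r2_max, distance_min)$novel,
    logical(1))
}

#' Write regions as a BED file
#'
#' Internally coordinates are 1-based closed; BED output converts to
#' 0-based half-open.
#'
#' @param regions Data frame from [build_regions()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
regions_to_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = as.integer(regions$start) - 1L,
                    end = as.integer(regions$end),
                    name = regions$index_rsids)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
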