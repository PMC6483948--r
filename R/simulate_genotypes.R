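# Deterministic genome layout for a configuration: genes are spread over
# chromosomes 1..22 with transcription start sites 3 Mb apart, so that the
# +/- 1 Mb cis windows of neighbouring genes never overlap; each gene gets
# m_cis variants evenly spaced across +/- 500 kb around its TSS. Block MAF
# and per-variant imputation quality are drawn under the config seed, so
# the same configuration always describes the same genome.
build_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(sub_seed(config$seed, 1L), {
    g <- seq_len(config$n_genes)
    chrom <- paste0("chr", ((g - 1L) %% 22L) + 1L)
    tss <- 2e6 + ((g - 1L) %/% 22L) * 3e6
    genes <- data.frame(gene_id = sprintf("G%04d", g),
                        chrom = chrom, tss = tss, strand = "+",
                        stringsAsFactors = FALSE)
    m <- config$m_cis
    # non-strand-ambiguous allele pairs only, so harmonization keeps them
    pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"),
                    ncol = 2, byrow = TRUE)
    block_maf <- runif(config$n_genes, config$maf_range[1], config$maf_range[2])
    offset <- round(seq(-5e5, 5e5, length.out = m))
    variants <- do.call(rbind, lapply(g, function(i) {
      pick <- pairs[sample.int(4L, m, replace = TRUE), , drop = FALSE]
      data.frame(gene_id = genes$gene_id[i],
                 chrom = genes$chrom[i],
                 pos = genes$tss[i] + offset,
                 ref = pick[, 1], alt = pick[, 2],
                 maf = block_maf[i],
                 stringsAsFactors = FALSE)
    }))
    variants$rsid <- sprintf("rs%d", seq_len(nrow(variants)))
    variants$imputation_r2 <- runif(nrow(variants), 0.3, 1)
    list(genes = genes, variants = variants)
  })
}

# One haplotype block: stationary binary Markov chain over m markers with
# common allele frequency p and exact adjacent correlation rho, so that
# corr(marker i, marker j) = rho^|i-j|.
sim_haplotype_block <- function(n_hap, m, p, rho) {
  a <- matrix(0L, n_hap, m)
  a[, 1] <- rbinom(n_hap, 1L, p)
  if (m > 1L) {
    p11 <- p + rho * (1 - p)   # P(1 | previous 1)
    p10 <- p * (1 - rho)       # P(1 | previous 0)
    for (j in 2:m) {
      pr <- ifelse(a[, j - 1] == 1L, p11, p10)
      a[, j] <- rbinom(n_hap, 1L, pr)
    }
  }
  a
}

#' Simulate LD-structured genotype dosages
#'
#' Draws `n` individuals at the configuration's genome: per gene cis block,
#' two independent haplotypes from a stationary Markov chain whose adjacent
#' allelic correlation is `rho` (so LD decays as `rho^distance` in marker
#' index), thresholded at the block's minor-allele frequency. The dosage is
#' the sum of the two haplotypes; hard-call genotype counts and per-variant
#' imputation quality (drawn in (0.3, 1\]) are attached.
#'
#' @param config A [sim_config()].
#' @param n Number of individuals (>= 2).
#' @param seed Seed for the genotype draw; the genome layout itself depends
#'   only on `config$seed`, so panels drawn with different `seed` share
#'   variants and allele frequencies (reference vs cohort roles).
#' @param genome Optional genome description (as from the internal layout
#'   builder, carried in a [simulate_expression()] truth table) to reuse.
#' @param id_prefix Prefix for sample identifiers.
#' @return A [genotype_panel()]; its `variants` include `gene_id` and the
#'   target `maf`.
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 2, m_cis = 5)
#' panel <- simulate_genotypes(cfg, n = 50)
#' panel
#' @export
simulate_genotypes <- function(config, n, seed = sub_seed(config$seed, 2L),
                               genome = NULL, id_prefix = "S") {
  stopifnot(inherits(config, "sim_config"))
  if (!is_count(n) || n < 2) stopf("'n' must be an integer >= 2")
  genome <- genome %||% build_genome(config)
  v <- genome$variants
  dos <- with_seed(seed, {
    blocks <- lapply(split(seq_len(nrow(v)), v$gene_id)[unique(v$gene_id)],
                     function(idx) {
                       p <- v$maf[idx[1]]
                       m <- length(idx)
                       sim_haplotype_block(n, m, p, config$rho) +
                         sim_haplotype_block(n, m, p, config$rho)
                     })
    do.call(cbind, blocks)
  })
  # blocks come back in gene order of first appearance == variant order
  storage.mode(dos) <- "double"
  genotype_panel(sprintf("%s%05d", id_prefix, seq_len(n)), v, dos,
                 imputation_r2 = v$imputation_r2)
}
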