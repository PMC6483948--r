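#' Simulate cis-regulated gene expression with known ground truth
#'
#' For each gene, `k_causal_eqtl` variants of its cis block receive true
#' eQTL weights; the genetic score is rescaled so that its in-sample
#' variance equals `h2_per_gene`, and independent Gaussian noise with
#' variance `1 - h2_per_gene` is added, giving
#' var(genetic) / var(total) = h2 in expectation (expression is on a
#' unit-variance scale, as after residualization).
#'
#' @param panel Reference [genotype_panel()] from [simulate_genotypes()].
#' @param config The [sim_config()] used to build `panel`.
#' @param seed Seed for weight and noise draws.
#' @return A list with elements
#'   \describe{
#'     \item{expression}{genes x samples numeric matrix.}
#'     \item{annotation}{data frame `gene_id`, `chrom`, `tss`, `strand`.}
#'     \item{truth}{a `truth_table`: per-gene true weights, true cis h2,
#'       causal-gene log-odds ratios, the genome layout, and the
#'       configuration (the disease-model intercept is solved later by
#'       [simulate_cohort()]).}
#'   }
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 3, m_cis = 5, n_ref = 100)
#' ref <- simulate_genotypes(cfg, cfg$n_ref)
#' sim <- simulate_expression(ref, cfg)
#' dim(sim$expression)
#' @export
simulate_expression <- function(panel, config,
                                seed = sub_seed(config$seed, 3L)) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "sim_config"))
  if (config$k_causal_eqtl > config$m_cis)
    stopf("k_causal_eqtl exceeds m_cis")
  genome <- list(genes = unique(panel$variants[, c("gene_id", "chrom")]),
                 variants = panel$variants)
  # recover tss from variant midpoints if annotation absent; prefer layout
  layout <- build_genome(config)
  genes <- layout$genes
  if (!identical(genes$gene_id, unique(panel$variants$gene_id)))
    stopf("panel variants do not match the configuration's genome")
  n <- length(panel$sample_ids)
  h2 <- config$h2_per_gene
  causal <- config$causal_genes

  out <- with_seed(seed, {
    expr <- matrix(NA_real_, config$n_genes, n,
                   dimnames = list(genes$gene_id, panel$sample_ids))
    wts <- vector("list", config$n_genes)
    realized_h2 <- numeric(config$n_genes)
    for (i in seq_len(config$n_genes)) {
      idx <- which(panel$variants$gene_id == genes$gene_id[i])
      k <- config$k_causal_eqtl
      pick <- sort(sample(idx, k))
      w_raw <- rnorm(k)
      g_raw <- drop(panel$dosages[, pick, drop = FALSE] %*% w_raw)
      sd_g <- sd(g_raw)
      if (h2 > 0 && sd_g > 0) {
        scale <- sqrt(h2) / sd_g
        w <- w_raw * scale
        genetic <- (g_raw - mean(g_raw)) * scale
      } else {
        w <- rep(0, k)
        genetic <- rep(0, n)
      }
      noise <- if (h2 < 1) rnorm(n, sd = sqrt(1 - h2)) else rep(0, n)
      expr[i, ] <- genetic + noise
      vg <- var(genetic)
      realized_h2[i] <- if (vg + var(noise) > 0) vg / (vg + var(noise)) else 0
      wts[[i]] <- data.frame(gene_id = genes$gene_id[i],
                             rsid = panel$variants$rsid[pick],
                             weight = w, stringsAsFactors = FALSE)
    }
    list(expr = expr, wts = do.call(rbind, wts), realized_h2 = realized_h2)
  })

  genes$h2 <- h2
  genes$realized_h2 <- out$realized_h2
  genes$log_or <- 0
  if (!is.null(causal)) {
    miss <- setdiff(causal$gene_id, genes$gene_id)
    if (length(miss))
      stopf("causal gene(s) not simulated: %s", paste(miss, collapse = ", "))
    genes$log_or[match(causal$gene_id, genes$gene_id)] <- causal$log_or
  }
  truth <- structure(list(genes = genes, weights = out$wts,
                          variants = panel$variants,
                          config = config, intercept = NA_real_),
                     class = "truth_table")
  list(expression = out$expr,
       annotation = layout$genes,
       truth = truth)
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("<truth_table> %d genes (%d causal), %d true eQTL weights\n",
              nrow(x$genes), sum(x$genes$log_or != 0), nrow(x$weights)))
  invisible(x)
}
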