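#' Simulation configuration for a synthetic TWAS study
#'
#' Bundles every tunable of the synthetic-data generator: the reference
#' panel used to train expression models, the case-control discovery
#' cohort, and the replication cohorts. Identical configurations (including
#' `seed`) yield bit-identical simulated data.
#'
#' Defaults mirror the study this generator emulates, scaled to desk size:
#' a transcriptome reference panel of 169 individuals, a discovery cohort
#' of 1219 cases / 1472 controls (one tenth of 12186/14718), three
#' replication cohorts totalling roughly 2.7x the discovery sample, about
#' 22 cis variants per gene, and anatomic-site proportions
#' 4454:3580:2936:1216 among cases.
#'
#' @param seed Integer seed; fixes all randomness downstream.
#' @param n_ref Reference-panel size (individuals with expression).
#' @param n_cases,n_controls Discovery-cohort case and control counts.
#' @param n_genes Number of simulated genes.
#' @param m_cis Variants per gene cis block.
#' @param maf_range Length-2 numeric in (0, 0.5]; each gene block draws its
#'   minor-allele frequency uniformly from this range.
#' @param rho Adjacent-variant allelic correlation in \[0, 1); LD decays as
#'   `rho^distance` in marker index.
#' @param h2_per_gene Cis heritability of expression in \[0, 1\]: the
#'   expected fraction of expression variance explained by the gene's true
#'   eQTL weights.
#' @param k_causal_eqtl Causal eQTL variants per gene (<= `m_cis`).
#' @param causal_genes `NULL`, or a data frame with columns `gene_id` and
#'   `log_or` giving the disease log-odds ratio per standard deviation of
#'   each causal gene's true genetic expression score.
#' @param covariate_effects Named numeric log-odds effects of the
#'   covariates (`age` per year on age - 60, `sex`, `center`, `batch`).
#' @param site_proportions Named proportions (summing to 1) used to assign
#'   cases to proximal/distal/rectal/unspecified anatomic sites.
#' @param prevalence Target disease prevalence in the source population;
#'   the disease-model intercept is solved numerically to hit it.
#' @param n_replication_cohorts Number of independent replication cohorts.
#' @param rep_n_cases,rep_n_controls Case/control counts per replication
#'   cohort.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_genotypes()], [simulate_expression()],
#'   [simulate_cohort()], [simulate_study()]
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 10, n_ref = 100)
#' cfg
#' @export
sim_config <- function(seed = 1L,
                       n_ref = 169L,
                       n_cases = 1219L,
                       n_controls = 1472L,
                       n_genes = 300L,
                       m_cis = 22L,
                       maf_range = c(0.05, 0.5),
                       rho = 0.8,
                       h2_per_gene = 0.3,
                       k_causal_eqtl = 3L,
                       causal_genes = NULL,
                       covariate_effects = c(age = 0.01, sex = 0.10,
                                             center = 0.05, batch = 0.05),
                       site_proportions = c(proximal = 4454, distal = 3580,
                                            rectal = 2936,
                                            unspecified = 1216) / 12186,
                       prevalence = 0.10,
                       n_replication_cohorts = 3L,
                       rep_n_cases = 1094L,
                       rep_n_controls = 1331L) {
  counts <- c(n_ref = n_ref, n_cases = n_cases, n_controls = n_controls,
              n_genes = n_genes, m_cis = m_cis,
              k_causal_eqtl = k_causal_eqtl,
              n_replication_cohorts = n_replication_cohorts,
              rep_n_cases = rep_n_cases, rep_n_controls = rep_n_controls)
  for (nm in names(counts)) {
    if (!is_count(counts[[nm]])) stopf("'%s' must be a positive integer", nm)
  }
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stopf("'maf_range' must be an increasing pair within (0, 0.5]")
  if (!is.numeric(rho) || rho < 0 || rho >= 1)
    stopf("'rho' must lie in [0, 1)")
  if (!is.numeric(h2_per_gene) || h2_per_gene < 0 || h2_per_gene > 1)
    stopf("'h2_per_gene' must lie in [0, 1]")
  if (k_causal_eqtl > m_cis)
    stopf("'k_causal_eqtl' (%d) exceeds 'm_cis' (%d)", k_causal_eqtl, m_cis)
  if (abs(sum(site_proportions) - 1) > 1e-8)
    stopf("'site_proportions' must sum to 1")
  if (is.null(names(site_proportions)) ||
      !all(c("proximal", "distal", "rectal", "unspecified") %in%
             names(site_proportions)))
    stopf("'site_proportions' needs names proximal/distal/rectal/unspecified")
  if (prevalence <= 0 || prevalence >= 1)
    stopf("'prevalence' must lie in (0, 1)")
  if (!is.null(causal_genes)) {
    if (!is.data.frame(causal_genes) ||
        !all(c("gene_id", "log_or") %in% names(causal_genes)))
      stopf("'causal_genes' must be a data frame with gene_id and log_or")
    if (anyDuplicated(causal_genes$gene_id))
      stopf("duplicated gene_id in 'causal_genes'")
    if (any(causal_genes$log_or != 0) && h2_per_gene == 0)
      stopf("causal genes need h2_per_gene > 0 for a defined per-SD effect")
  }

  structure(list(
    seed = as.integer(seed), n_ref = as.integer(n_ref),
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    n_genes = as.integer(n_genes), m_cis = as.integer(m_cis),
    maf_range = as.numeric(maf_range), rho = as.numeric(rho),
    h2_per_gene = as.numeric(h2_per_gene),
    k_causal_eqtl = as.integer(k_causal_eqtl),
    causal_genes = causal_genes,
    covariate_effects = covariate_effects,
    site_proportions = site_proportions,
    prevalence = as.numeric(prevalence),
    n_replication_cohorts = as.integer(n_replication_cohorts),
    rep_n_cases = as.integer(rep_n_cases),
    rep_n_controls = as.integer(rep_n_controls)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  seed %d | %d genes x %d cis variants | n_ref %d\n",
              x$seed, x$n_genes, x$m_cis, x$n_ref))
  cat(sprintf("  discovery %d/%d, %d replication cohort(s) of %d/%d\n",
              x$n_cases, x$n_controls, x$n_replication_cohorts,
              x$rep_n_cases, x$rep_n_controls))
  cat(sprintf("  maf [%.2f, %.2f], rho %.2f, h2 %.2f, %d causal eQTL/gene\n",
              x$maf_range[1], x$maf_range[2], x$rho, x$h2_per_gene,
              x$k_causal_eqtl))
  nc <- if (is.null(x$causal_genes)) 0L else nrow(x$causal_genes)
  cat(sprintf("  %d causal gene(s), prevalence %.2f\n", nc, x$prevalence))
  invisible(x)
}
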