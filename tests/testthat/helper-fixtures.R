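# small deterministic fixtures shared across test files

tiny_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_genes = 5L, m_cis = 8L, n_ref = 200L,
             n_cases = 120L, n_controls = 120L, h2_per_gene = 0.4,
             n_replication_cohorts = 2L,
             rep_n_cases = 120L, rep_n_controls = 120L, ...)
}

# hand-built panel: explicit variants and dosages, no simulation
manual_panel <- function(dosages, chrom = "chr1",
                         pos = seq_len(ncol(dosages)) * 1000,
                         ref = rep("A", ncol(dosages)),
                         alt = rep("G", ncol(dosages)),
                         imputation_r2 = NULL) {
  genotype_panel(sprintf("s%02d", seq_len(nrow(dosages))),
                 data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                            rsid = sprintf("v%d", seq_len(ncol(dosages))),
                            stringsAsFactors = FALSE),
                 dosages, imputation_r2 = imputation_r2)
}

manual_model <- function(weights, chrom = "chr1",
                         pos = seq_along(weights) * 1000,
                         ref = rep("A", length(weights)),
                         alt = rep("G", length(weights)),
                         ref_maf = rep(0.25, length(weights)),
                         gene_id = "GX", tss = 1000, pred_r2 = 0.5) {
  weight_model(gene_id, chrom, tss,
               data.frame(rsid = sprintf("v%d", seq_along(weights)),
                          chrom = chrom, pos = pos, ref = ref, alt = alt,
                          weight = weights, ref_maf = ref_maf,
                          stringsAsFactors = FALSE),
               pred_r2)
}

# a cached medium study so several files can share one simulation
shared_cache <- new.env(parent = emptyenv())

shared_study <- function() {
  if (is.null(shared_cache$study)) {
    cfg <- sim_config(seed = 42L, n_genes = 8L, m_cis = 10L, n_ref = 300L,
                      n_cases = 500L, n_controls = 500L, h2_per_gene = 0.5,
                      causal_genes = data.frame(gene_id = "G0001",
                                                log_or = 0.3),
                      n_replication_cohorts = 2L,
                      rep_n_cases = 400L, rep_n_controls = 400L)
    shared_cache$study <- list(config = cfg,
                               study = simulate_study(cfg))
  }
  shared_cache$study
}

shared_models <- function() {
  if (is.null(shared_cache$models)) {
    sh <- shared_study()
    st <- sh$study
    shared_cache$models <- filter_models(
      train_models(st$reference$panel, st$reference$expression,
                   st$reference$annotation,
                   training_config(seed = sh$config$seed)))
  }
  shared_cache$models
}
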