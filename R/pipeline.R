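#' Simulate a complete two-stage TWAS study
#'
#' Generates, under one configuration: the reference panel with
#' expression and ground truth, the discovery cohort, and the replication
#' cohorts.
#'
#' @param config A [sim_config()].
#' @param replication Simulate replication cohorts too (default `TRUE`).
#' @return List with `reference` (`panel`, `expression`, `annotation`),
#'   `truth`, `cohort` (`panel`, `pheno`), and `replication` (list of
#'   cohorts, possibly empty).
#' @export
simulate_study <- function(config, replication = TRUE) {
  ref_panel <- simulate_genotypes(config, config$n_ref)
  sim <- simulate_expression(ref_panel, config)
  cohort <- simulate_cohort(config, sim$truth)
  sim$truth$intercept <- cohort$intercept
  reps <- if (replication) simulate_replication_cohorts(config, sim$truth)
    else list()
  list(reference = list(panel = ref_panel, expression = sim$expression,
                        annotation = sim$annotation),
       truth = sim$truth, cohort = cohort, replication = reps)
}

#' Run the full TWAS pipeline on a simulated study
#'
#' Trains cis elastic-net models on the reference panel, filters them at
#' predictive R-squared >= `r2_min`, imputes GReX into the discovery
#' cohort, runs the covariate-adjusted association scan with BH FDR,
#' computes the genomic inflation factor, screens hits for novelty when
#' known index variants are supplied, and — when any gene is carried —
#' imputes and tests GReX in each replication cohort and assembles the
#' two-stage report.
#'
#' @param config A [sim_config()].
#' @param training A [training_config()]; its seed defaults to the
#'   simulation seed.
#' @param r2_min Model-inclusion threshold on predictive R-squared.
#' @param fdr Discovery FDR threshold (default 0.2).
#' @param alpha Replication family-wise level (default 0.05).
#' @param known_index Optional data frame of known index variants
#'   (`rsid, chrom, pos`) for the novelty screen (LD evaluated in the
#'   reference panel).
#' @param study Optional pre-simulated study from [simulate_study()];
#'   when supplied, `config` is taken from it.
#' @return List: `study`, `models` (kept), `n_trained`, `grex`,
#'   `association`, `inflation`, `novel`, `report` (two-stage report, or
#'   `NULL` when nothing was carried and no replication was run).
#' @export
run_twas_study <- function(config,
                           training = training_config(seed = config$seed),
                           r2_min = 0.01, fdr = 0.2, alpha = 0.05,
                           known_index = NULL, study = NULL) {
  study <- study %||% simulate_study(config, replication = FALSE)
  ref <- study$reference
  trained <- train_models(ref$panel, ref$expression, ref$annotation,
                          training)
  kept <- filter_models(trained, r2_min)
  grex <- compute_grex_all(kept, study$cohort$panel)
  assoc <- association_scan(grex, study$cohort$pheno)
  ok_p <- assoc$p[assoc$converged & is.finite(assoc$p)]
  infl <- if (length(ok_p) >= 10) genomic_lambda(ok_p) else NULL
  novel <- if (!is.null(known_index))
    novelty_screen(kept, known_index, ref$panel) else NULL

  is_novel <- if (is.null(novel)) rep(TRUE, nrow(assoc)) else {
    nv <- novel[assoc$gene]; nv[is.na(nv)] <- TRUE; nv
  }
  any_carried <- any(assoc$converged & is.finite(assoc$q_bh) &
                       assoc$q_bh <= fdr & is_novel)
  report <- NULL
  if (any_carried) {
    if (!length(study$replication))
      study$replication <- simulate_replication_cohorts(config, study$truth)
    rep_scans <- lapply(study$replication, function(coh) {
      g <- compute_grex_all(kept, coh$panel)
      association_scan(g, coh$pheno)
    })
    report <- two_stage(assoc, rep_scans, fdr = fdr, alpha = alpha,
                        novel = novel)
  }
  list(study = study, models = kept, n_trained = length(trained),
       grex = grex, association = assoc, inflation = infl,
       novel = novel, report = report)
}
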