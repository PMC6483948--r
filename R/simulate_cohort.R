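# samples x genes matrix of true genetic expression scores under the
# simulation's ground-truth weights
true_genetic_score <- function(truth, panel) {
  genes <- truth$genes$gene_id
  out <- matrix(0, length(panel$sample_ids), length(genes),
                dimnames = list(panel$sample_ids, genes))
  w <- truth$weights
  col <- match(w$rsid, panel$variants$rsid)
  if (anyNA(col)) stopf("panel lacks variants carrying true weights")
  for (g in genes) {
    rows <- which(w$gene_id == g)
    if (length(rows))
      out[, g] <- drop(panel$dosages[, col[rows], drop = FALSE] %*%
                         w$weight[rows])
  }
  out
}

# draw the non-genetic covariates of the disease model
draw_covariates <- function(n) {
  data.frame(age = rnorm(n, 60, 10),
             sex = rbinom(n, 1L, 0.5),
             center = sample(c("C1", "C2", "C3"), n, replace = TRUE),
             batch = sample(c("B1", "B2"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

covariate_eta <- function(cov, effects) {
  eta <- rep(0, nrow(cov))
  if (!is.na(effects["age"]))
    eta <- eta + effects["age"] * (cov$age - 60)
  if (!is.na(effects["sex"]))
    eta <- eta + effects["sex"] * cov$sex
  if (!is.na(effects["center"]))
    eta <- eta + effects["center"] * (match(cov$center, c("C1", "C2", "C3")) - 2)
  if (!is.na(effects["batch"]))
    eta <- eta + effects["batch"] * (match(cov$batch, c("B1", "B2")) - 1.5)
  unname(eta)
}

# linear predictor without intercept for one batch of individuals
disease_eta <- function(truth, panel, cov) {
  cfg <- truth$config
  eta <- covariate_eta(cov, cfg$covariate_effects)
  causal <- truth$genes[truth$genes$log_or != 0, , drop = FALSE]
  if (nrow(causal)) {
    gs <- true_genetic_score(truth, panel)[, causal$gene_id, drop = FALSE]
    # per-SD effects: the true genetic score has population SD sqrt(h2)
    sds <- sqrt(causal$h2)
    eta <- eta + drop(sweep(gs, 2, sds, "/") %*% causal$log_or)
  }
  eta
}

# solve the disease-model intercept so that mean prevalence over a
# calibration sample equals the configured target
solve_intercept <- function(truth, n_cal = 5000L) {
  cfg <- truth$config
  genome <- list(genes = NULL, variants = truth$variants)
  panel <- simulate_genotypes(cfg, n_cal, seed = sub_seed(cfg$seed, 4L),
                              genome = genome, id_prefix = "K")
  cov <- with_seed(sub_seed(cfg$seed, 5L), draw_covariates(n_cal))
  eta <- disease_eta(truth, panel, cov)
  f <- function(b0) mean(plogis(b0 + eta)) - cfg$prevalence
  uniroot(f, interval = c(-30, 30), tol = 1e-10)$root
}

# first four genotype principal components from a thinned variant set,
# standardized to unit variance (population-structure adjustment covariates)
genotype_pcs <- function(dosages, max_variants = 1000L) {
  keep <- unique(round(seq(1L, ncol(dosages),
                           length.out = min(max_variants, ncol(dosages)))))
  x <- dosages[, keep, drop = FALSE]
  sds <- apply(x, 2, sd)
  x <- scale(x[, sds > 0, drop = FALSE])
  cc <- crossprod(x) / (nrow(x) - 1)
  ev <- eigen(cc, symmetric = TRUE)
  k <- min(4L, ncol(x))
  scores <- x %*% ev$vectors[, seq_len(k), drop = FALSE]
  scores <- scale(scores)
  if (k < 4L) scores <- cbind(scores, matrix(0, nrow(x), 4L - k))
  colnames(scores) <- paste0("pc", 1:4)
  scores
}

#' Simulate a case-control cohort from the truth table's disease model
#'
#' Individuals are drawn from the same genotype distribution as the
#' reference panel; disease probability follows a logistic model
#' `logit(p) = b0 + sum_g beta_g * (true genetic score_g / SD) + covariates`
#' with the intercept `b0` solved numerically for the configured
#' population prevalence. Sampling proceeds in batches until the case and
#' control quotas are filled (rejection sampling); cases are then assigned
#' anatomic-site labels multinomially by `site_proportions`, and the first
#' four genotype principal components are appended as adjustment
#' covariates.
#'
#' @param config A [sim_config()].
#' @param truth A `truth_table` from [simulate_expression()] (must carry
#'   every causal gene).
#' @param n_cases,n_controls Quotas; default from `config`.
#' @param seed Seed for this cohort's draws.
#' @param id_prefix Sample-identifier prefix.
#' @param max_batches Safety bound on rejection-sampling batches; an error
#'   is raised if the case quota is unattainable within it.
#' @return A list with `panel` (a [genotype_panel()]) and `pheno` (a data
#'   frame with columns `sample_id`, `case`, `age`, `sex`, `center`,
#'   `batch`, `pc1`..`pc4`, `site`; `site` is `"control"` for controls).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 3, m_cis = 5, n_ref = 100,
#'                   n_cases = 30, n_controls = 30)
#' sim <- simulate_expression(simulate_genotypes(cfg, cfg$n_ref), cfg)
#' coh <- simulate_cohort(cfg, sim$truth)
#' table(coh$pheno$case)
#' @export
simulate_cohort <- function(config, truth,
                            n_cases = config$n_cases,
                            n_controls = config$n_controls,
                            seed = sub_seed(config$seed, 6L),
                            id_prefix = "P",
                            max_batches = 200L) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "truth_table"))
  causal <- truth$config$causal_genes
  if (!is.null(causal) &&
      !all(causal$gene_id %in% truth$genes$gene_id))
    stopf("truth table does not contain all causal genes")
  b0 <- if (is.finite(truth$intercept)) truth$intercept else
    solve_intercept(truth)
  genome <- list(genes = NULL, variants = truth$variants)

  batch_n <- min(4000L, max(1000L, as.integer(
    2 * (n_cases + n_controls) / min(config$prevalence,
                                     1 - config$prevalence))))
  kept_dos <- NULL
  kept_cov <- NULL
  kept_y <- integer(0)
  got_ca <- 0L; got_co <- 0L
  b <- 0L
  while ((got_ca < n_cases || got_co < n_controls)) {
    b <- b + 1L
    if (b > max_batches)
      stopf(paste0("case/control quota unattainable after %d sampling ",
                   "batches (disease probability too extreme)"), max_batches)
    pan <- simulate_genotypes(config, batch_n,
                              seed = sub_seed(seed, 100L + b),
                              genome = genome, id_prefix = "tmp")
    cov <- with_seed(sub_seed(seed, 500L + b), draw_covariates(batch_n))
    eta <- b0 + disease_eta(truth, pan, cov)
    y <- with_seed(sub_seed(seed, 900L + b),
                   rbinom(batch_n, 1L, plogis(eta)))
    need_ca <- n_cases - got_ca; need_co <- n_controls - got_co
    ica <- which(y == 1L)[seq_len(min(need_ca, sum(y == 1L)))]
    ico <- which(y == 0L)[seq_len(min(need_co, sum(y == 0L)))]
    take <- sort(c(ica, ico))
    if (length(take)) {
      kept_dos <- rbind(kept_dos, pan$dosages[take, , drop = FALSE])
      kept_cov <- rbind(kept_cov, cov[take, , drop = FALSE])
      kept_y <- c(kept_y, y[take])
      got_ca <- got_ca + length(ica)
      got_co <- got_co + length(ico)
    }
  }
  n <- length(kept_y)
  ids <- sprintf("%s%06d", id_prefix, seq_len(n))
  rownames(kept_dos) <- ids
  panel <- genotype_panel(ids, truth$variants, kept_dos,
                          imputation_r2 = truth$variants$imputation_r2)
  pcs <- genotype_pcs(panel$dosages)
  site <- rep("control", n)
  ncase <- sum(kept_y == 1L)
  site[kept_y == 1L] <- with_seed(
    sub_seed(seed, 7L),
    sample(names(config$site_proportions), ncase, replace = TRUE,
           prob = config$site_proportions))
  pheno <- data.frame(sample_id = ids, case = kept_y,
                      age = kept_cov$age, sex = kept_cov$sex,
                      center = kept_cov$center, batch = kept_cov$batch,
                      pc1 = pcs[, 1], pc2 = pcs[, 2],
                      pc3 = pcs[, 3], pc4 = pcs[, 4],
                      site = site, stringsAsFactors = FALSE)
  list(panel = panel, pheno = pheno, intercept = b0)
}

#' Simulate independent replication cohorts
#'
#' Draws `config$n_replication_cohorts` cohorts of
#' `rep_n_cases`/`rep_n_controls` from the same population and disease
#' model as the discovery cohort, each under its own seed stream.
#'
#' @inheritParams simulate_cohort
#' @return A list of cohorts as returned by [simulate_cohort()].
#' @export
simulate_replication_cohorts <- function(config, truth) {
  lapply(seq_len(config$n_replication_cohorts), function(i) {
    simulate_cohort(config, truth,
                    n_cases = config$rep_n_cases,
                    n_controls = config$rep_n_controls,
                    seed = sub_seed(config$seed, 60L + i),
                    id_prefix = sprintf("R%d_", i))
  })
}
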