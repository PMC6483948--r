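test_that("config validation rejects impossible study designs", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(rho = 1), "rho")
  expect_error(sim_config(h2_per_gene = 1.2), "h2_per_gene")
  expect_error(sim_config(m_cis = 3, k_causal_eqtl = 5), "exceeds")
  expect_error(sim_config(site_proportions = c(proximal = 0.5, distal = 0.2,
                                               rectal = 0.2,
                                               unspecified = 0.2)),
               "sum to 1")
  expect_error(sim_config(h2_per_gene = 0,
                          causal_genes = data.frame(gene_id = "G0001",
                                                    log_or = 0.1)),
               "h2_per_gene")
})

test_that("default site proportions reproduce the study's case strata", {
  cfg <- sim_config()
  expect_equal(unname(cfg$site_proportions[c("proximal", "distal", "rectal",
                                             "unspecified")]),
               c(4454, 3580, 2936, 1216) / 12186)
})

test_that("identical configurations give bit-identical simulations", {
  cfg <- tiny_config(seed = 7)
  a <- simulate_genotypes(cfg, 50)
  b <- simulate_genotypes(cfg, 50)
  expect_identical(a, b)
  ea <- simulate_expression(a, cfg)
  eb <- simulate_expression(b, cfg)
  expect_identical(ea$expression, eb$expression)
  ca <- simulate_cohort(cfg, ea$truth, n_cases = 50, n_controls = 50)
  cb <- simulate_cohort(cfg, eb$truth, n_cases = 50, n_controls = 50)
  expect_identical(ca$panel$dosages, cb$panel$dosages)
  expect_identical(ca$pheno, cb$pheno)
})

test_that("tight LD blocks give near-perfect adjacent dosage correlation", {
  cfg <- sim_config(seed = 3, n_genes = 2, m_cis = 6, rho = 0.99,
                    maf_range = c(0.2, 0.5))
  panel <- simulate_genotypes(cfg, 500)
  for (g in unique(panel$variants$gene_id)) {
    idx <- which(panel$variants$gene_id == g)
    for (j in idx[-length(idx)]) {
      r2 <- cor(panel$dosages[, j], panel$dosages[, j + 1])^2
      expect_gt(r2, 0.9)
    }
  }
})

test_that("unlinked common variants have mean dosage near one", {
  cfg <- sim_config(seed = 4, n_genes = 3, m_cis = 5, rho = 0,
                    maf_range = c(0.5, 0.5))
  panel <- simulate_genotypes(cfg, 2000)
  se <- sqrt(0.5 * 0.5 * 2 / 2000)  # var of mean dosage at maf .5
  expect_true(all(abs(colMeans(panel$dosages) - 1) < 3 * se))
})

test_that("hard-call frequencies follow Hardy-Weinberg expectation", {
  cfg <- sim_config(seed = 5, n_genes = 2, m_cis = 4,
                    maf_range = c(0.3, 0.3))
  panel <- simulate_genotypes(cfg, 2000)
  # independently computed HWE expectation at maf 0.3
  expected <- c(0.7^2, 2 * 0.7 * 0.3, 0.3^2)
  freqs <- panel$hard_calls / 2000
  for (k in 1:3) {
    se <- sqrt(expected[k] * (1 - expected[k]) / 2000)
    expect_true(all(abs(freqs[, k] - expected[k]) < 4 * se))
  }
})

test_that("empirical allele frequencies hit their targets", {
  cfg <- sim_config(seed = 6, n_genes = 10, m_cis = 5,
                    maf_range = c(0.05, 0.5))
  panel <- simulate_genotypes(cfg, 1000)
  maf <- panel$variants$maf
  emp <- colMeans(panel$dosages) / 2
  se <- sqrt(maf * (1 - maf) / (2 * 1000))
  expect_true(all(abs(emp - maf) <= 3.5 * se))
})

test_that("simulated genotypes reject degenerate requests", {
  cfg <- tiny_config()
  expect_error(simulate_genotypes(cfg, 1), "n")
})

test_that("expression without genetic control is uncorrelated with dosage", {
  cfg <- sim_config(seed = 8, n_genes = 20, m_cis = 4, h2_per_gene = 0)
  panel <- simulate_genotypes(cfg, 1000)
  sim <- simulate_expression(panel, cfg)
  frac_ok <- mean(vapply(seq_len(20), function(i) {
    idx <- which(panel$variants$gene_id == sim$annotation$gene_id[i])
    all(abs(cor(sim$expression[i, ], panel$dosages[, idx])) < 0.1)
  }, logical(1)))
  expect_gte(frac_ok, 0.95)
})

test_that("fully heritable single-eQTL expression is an affine dosage map", {
  cfg <- sim_config(seed = 9, n_genes = 3, m_cis = 4, h2_per_gene = 1,
                    k_causal_eqtl = 1)
  panel <- simulate_genotypes(cfg, 300)
  sim <- simulate_expression(panel, cfg)
  for (i in 1:3) {
    w <- sim$truth$weights[sim$truth$weights$gene_id ==
                             sim$annotation$gene_id[i], ]
    d <- panel$dosages[, w$rsid]
    expect_equal(abs(cor(sim$expression[i, ], d)), 1, tolerance = 1e-12)
  }
})

test_that("genetic variance fraction is calibrated to the target h2", {
  cfg <- sim_config(seed = 10, n_genes = 50, m_cis = 6, h2_per_gene = 0.5,
                    k_causal_eqtl = 2)
  panel <- simulate_genotypes(cfg, 1000)
  sim <- simulate_expression(panel, cfg)
  expect_lt(abs(mean(sim$truth$genes$realized_h2) - 0.5), 0.05)
  # regression of expression on the true genetic value: slope ~ 1, R2 ~ h2
  slopes <- r2s <- numeric(50)
  gs <- grextas:::true_genetic_score(sim$truth, panel)
  for (i in 1:50) {
    fit <- lm(sim$expression[i, ] ~ gs[, i])
    slopes[i] <- coef(fit)[2]
    r2s[i] <- summary(fit)$r.squared
  }
  expect_lt(abs(mean(slopes) - 1), 0.05)
  expect_lt(abs(mean(r2s) - 0.5), 0.05)
})

test_that("cohort sampling fills quotas, labels sites, and shares the genome", {
  sh <- shared_study()
  coh <- sh$study$cohort
  cfg <- sh$config
  expect_equal(sum(coh$pheno$case == 1), cfg$n_cases)
  expect_equal(sum(coh$pheno$case == 0), cfg$n_controls)
  expect_true(all(coh$pheno$site[coh$pheno$case == 0] == "control"))
  expect_true(all(coh$pheno$site[coh$pheno$case == 1] %in%
                    c("proximal", "distal", "rectal", "unspecified")))
  expect_identical(coh$panel$variants$rsid,
                   sh$study$reference$panel$variants$rsid)
  expect_true(all(c("pc1", "pc2", "pc3", "pc4") %in% names(coh$pheno)))
})

test_that("a causal gene's effect is recovered by regression on true GReX", {
  # parameter recovery: logistic fit on the TRUE genetic score should
  # cover the planted per-SD log-OR in most replicates
  cfg0 <- sim_config(seed = 11, n_genes = 4, m_cis = 6, h2_per_gene = 0.5,
                     causal_genes = data.frame(gene_id = "G0001",
                                               log_or = 0.25),
                     n_cases = 600, n_controls = 700)
  covered <- logical(10)
  for (r in 1:10) {
    cfg <- sim_config(seed = 100 + r, n_genes = 4, m_cis = 6,
                      h2_per_gene = 0.5,
                      causal_genes = data.frame(gene_id = "G0001",
                                                log_or = 0.25),
                      n_cases = 600, n_controls = 700)
    panel <- simulate_genotypes(cfg, 400)
    sim <- simulate_expression(panel, cfg)
    coh <- simulate_cohort(cfg, sim$truth)
    gs <- grextas:::true_genetic_score(sim$truth, coh$panel)[, "G0001"]
    gs <- gs / sqrt(cfg$h2_per_gene)   # per-SD scale as generated
    fit <- glm(coh$pheno$case ~ gs + coh$pheno$age + coh$pheno$sex,
               family = binomial())
    est <- summary(fit)$coefficients["gs", ]
    covered[r] <- abs(est["Estimate"] - 0.25) < 1.96 * est["Std. Error"]
  }
  expect_gte(mean(covered), 0.9)
})

test_that("an impossible case quota raises a bounded-sampling error", {
  cfg <- sim_config(seed = 12, n_genes = 2, m_cis = 4, prevalence = 0.5,
                    n_cases = 50, n_controls = 50)
  sim <- simulate_expression(simulate_genotypes(cfg, 100), cfg)
  sim$truth$intercept <- -50  # probability ~ 0: quota unattainable
  expect_error(simulate_cohort(cfg, sim$truth, max_batches = 3),
               "unattainable")
})

test_that("matched-control selection respects risk sets and matching", {
  base <- data.frame(year = 2000, ethnicity = "E", sex = 1)
  # one case, four exact-matching eligible controls: all four selected
  ev <- rbind(cbind(data.frame(sample_id = "case1", case = 1, time = 5), base),
              cbind(data.frame(sample_id = paste0("c", 1:4), case = 0,
                               time = 10), base))
  set.seed(1)
  out <- sample_matched_controls(ev, n_per_case = 4)
  expect_setequal(out$control_id, paste0("c", 1:4))
  expect_length(attr(out, "shortfall"), 0)

  # no eligible control: empty result, case flagged
  ev2 <- ev; ev2$sex[2:5] <- 0
  out2 <- sample_matched_controls(ev2, n_per_case = 1)
  expect_equal(nrow(out2), 0)
  expect_equal(attr(out2, "shortfall"), "case1")

  # subjects leaving follow-up before the event are not at risk
  ev3 <- ev; ev3$time[2:5] <- 2
  expect_equal(nrow(sample_matched_controls(ev3, 1)), 0)
})

test_that("controls are never reused across cases (without replacement)", {
  base <- data.frame(year = 2000, ethnicity = "E", sex = 1)
  ev <- rbind(cbind(data.frame(sample_id = paste0("case", 1:3), case = 1,
                               time = c(1, 2, 3)), base),
              cbind(data.frame(sample_id = paste0("c", 1:5), case = 0,
                               time = 10), base))
  # exhaustive check across RNG states
  for (s in 1:25) {
    set.seed(s)
    out <- sample_matched_controls(ev, n_per_case = 2)
    expect_false(any(duplicated(out$control_id)))
  }
})
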