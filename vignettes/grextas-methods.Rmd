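---
title: "Methods: genetically regulated expression and two-stage TWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genetically regulated expression and two-stage TWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`grextas` implements a transcriptome-wide association study (TWAS) of a
binary disease trait in the PrediXcan tradition. The analysis decomposes
into four statistical stages.

**1. Cis expression models.** On a reference panel with joint genotypes
and (residualized) expression, each gene's expression trait is modelled
additively from the dosages of variants within 1 Mb of its transcription
start site:

$$Y_g = \sum_k w_{k,g} X_k + \varepsilon,$$

where $X_k \in [0,2]$ is the effect-allele dosage of variant $k$ and
$\varepsilon$ collects all non-genetic variation. The weights are
estimated by the elastic net (glmnet) with mixing parameter
$\alpha = 0.5$, the penalty chosen by 10-fold cross-validation at
minimum mean squared error. Model quality is the *predictive
R-squared*: the signed squared Pearson correlation between observed
expression and the pooled out-of-fold predictions at the selected
penalty. Only genes with predictive $R^2 \ge 0.01$ (at least ~10%
correlation between predicted and observed expression) are carried
into association testing; the boundary is inclusive.

**2. GReX imputation.** Given a trained weight set, the genetically
regulated expression of gene $g$ in any genotyped cohort is the linear
score

$$\mathrm{GReX}_g = \sum_k w_{k,g} x_k,$$

computed after allele harmonization (match on chromosome and position;
swapped ref/alt dosages enter as $2-d$; strand-ambiguous A/T and C/G
pairs are dropped). Cohort variants first pass the usual GWAS filters:
call rate $\ge 98\%$, Hardy–Weinberg equilibrium in controls
$P \ge 10^{-4}$ (plain 1-df chi-square, no continuity correction),
MAF $\ge 0.05$, and imputation quality $R^2 > 0.3$.

**3. Association, FDR, and diagnostics.** Per gene,

$$\mathrm{logit}(p_{\mathrm{case}}) = \beta_0 + \beta_1\,\mathrm{GReX}
  + \beta_\mathrm{age}\,\mathrm{age} + \beta_\mathrm{sex}\,\mathrm{sex}
  + \beta_\mathrm{center} + \beta_\mathrm{batch}
  + \mathrm{PC}_{1..4},$$

fitted by IRLS (tolerance $10^{-8}$, 50 iterations), Wald tests, and
odds ratios with 95% CIs. Discovery uses a Benjamini–Hochberg FDR
threshold of 0.2. The genomic inflation factor
$\lambda = \mathrm{median}(\chi^2_{obs}) / 0.4549$ and QQ coordinates
diagnose miscalibration. Site-stratified analyses compare each case
stratum (proximal, distal, rectal; unspecified excluded) against all
controls, with Cochran's Q for heterogeneity.

**4. Replication and meta-analysis.** Genes passing discovery FDR that
are *novel* — no variant predictor within 1 Mb of, or in LD
($r^2 \ge 0.2$) with, a known GWAS index variant — are carried to
replication. Per-study effects are combined by fixed-effect
inverse-variance weighting
($\hat\beta = \sum w_i \beta_i / \sum w_i$, $w_i = 1/se_i^2$), and a
gene replicates when the two-sided meta P is below
$0.05 / (\text{number of genes carried})$ with a direction consistent
with discovery. The phrase "inverse variance weighting of Z scores" is
ambiguous between this estimator and a precision-weighted Stouffer
combination; both are implemented (`method = "ivw"` — the default —
and `method = "stouffer"`), and the choice is labelled in every
result.

GWAS risk regions are built by flanking each known index variant by
1 Mb (closed 1-based intervals) and merging transitively — windows
that share even a single base merge, since only "overlap" is defined.
Region summaries count CCDS-like annotated genes by TSS membership
(endpoints inclusive), genes with a model per tissue, their overlap as
$|CT \cap WB| / |CT \cup WB|$, and genes at nominal association
$P \le 0.05$ (inclusive; both conventions appear in practice, so the
cutoff is a parameter). The percent reduction of the candidate list is
$100\,(1 - n_{assoc}/n_{CCDS})$ — the complement form, which is what
published per-region tabulations actually show despite footnotes that
print the ratio itself.

# The synthetic-data generator

Every stage is exercised on data with known ground truth, generated by
`sim_config()` + `simulate_study()`.

**Genotypes.** Genes are laid out on chromosomes 1–22 with TSSs 3 Mb
apart, so neighbouring cis windows never overlap; each gene has
`m_cis` variants spread over ±500 kb. Haplotypes within a cis block
follow a stationary binary Markov chain whose adjacent-marker allelic
correlation is exactly `rho`, giving $corr(i,j) = \rho^{|i-j|}$ — an
AR(1) LD profile on the allele scale. We model LD directly on the
allele scale rather than thresholding a latent Gaussian because
thresholding attenuates correlation nonlinearly (at MAF 0.5 a latent
correlation of 0.99 yields an allelic correlation of only ~0.91), which
makes `rho` hard to interpret as an LD parameter; with the Markov
construction the dosage-scale LD between adjacent variants *is*
$\rho^2$ in $r^2$ terms. The construction requires a common allele
frequency within a block, so each gene draws one MAF from `maf_range`.
Dosages are the sum of two independent haplotypes (hence integers;
imputation uncertainty is emulated only through the per-variant
`imputation_r2` metadata drawn in (0.3, 1]).

**Expression.** Each gene receives `k_causal_eqtl` true weights drawn
from a standard normal and rescaled so the genetic score's in-sample
variance equals `h2_per_gene`; independent $N(0, 1-h^2)$ noise
completes a unit-variance trait, so var(genetic)/var(total) equals the
target heritability in expectation.

**Disease.** Case status follows a logistic model driven by the
standardized *true* genetic expression scores of the causal genes
(log odds ratio per SD), plus covariates (age $\sim N(60, 10)$, sex
$\sim$ Bernoulli(0.5), 3 centers and 2 batches with small log-odds
offsets). The intercept is solved numerically (uniroot on a 5000-draw
calibration sample) for a population prevalence of 0.1 — a
retrospective case-control design has no generative recipe, so we use
rejection sampling from this prospective model until the case and
control quotas fill. Cases receive anatomic-site labels multinomially
with proportions 4454 : 3580 : 2936 : 1216 (proximal : distal :
rectal : unspecified), independent of genotype by default (matching
the absence of site heterogeneity in the motivating data). The first
four genotype principal components (eigen-decomposition of a thinned
variant correlation matrix, scores standardized) are appended as
adjustment covariates.

**What the generator does not emulate:** real haplotype structure and
long-range LD, population admixture, non-integer imputed dosages,
genotype missingness patterns, PEER-style expression confounders, and
trans-eQTLs. Passing tests therefore demonstrate the correctness and
calibration of the *statistical machinery*, not performance on real
consortium data.

# Default parameters and why

| Parameter | Default | Rationale |
|---|---|---|
| `n_ref` | 169 | size of a single-tissue transcriptome reference panel typical for colon tissue |
| `n_cases`/`n_controls` | 1219/1472 | a 1:10 scale-down of a large discovery consortium (12186/14718) |
| replication | 3 cohorts of 1094/1331 | 1:10 scale-down of a 32825/39933 replication set split three ways |
| `m_cis` | 22 | mean predictors per gene in colon-tissue elastic-net models |
| `maf_range` | (0.05, 0.5] | common variants only, matching the MAF > 0.05 modelling filter |
| `rho` | 0.8 | moderately tight cis LD; adjacent dosage $r^2 \approx 0.64$ |
| `h2_per_gene` | 0.3 | a realistic cis heritability for well-predicted genes |
| `k_causal_eqtl` | 3 | sparse cis architecture |
| `prevalence` | 0.1 | source-population disease prevalence for intercept calibration (a placeholder, not an estimate) |
| QC | 0.98 / 1e-4 / 0.05 / 0.3 | standard GWAS variant filters |
| FDR / replication α | 0.2 / 0.05 | two-stage design: liberal discovery, Bonferroni replication |

# Numerical and design choices

- **Predictive R-squared convention.** Published TWAS model metrics are
  described only as "correlation between observed and predicted
  expression under 10-fold CV"; whether that is a squared correlation
  or a CV coefficient of determination is unstated. We use the signed
  squared Pearson correlation of pooled out-of-fold predictions:
  simple, monotone in the correlation, and negative for anti-predictive
  models so they cannot pass the 0.01 filter. Zero-variance predictions
  return 0 with a degenerate flag.
- **Penalty path.** 100 log-spaced penalties down to $10^{-4}$ of the
  largest; fold assignment is drawn once per gene from the training
  seed, so a fixed seed fixes the predictive R-squared exactly.
  Single-cis-variant genes are fitted by per-fold OLS (glmnet requires
  two columns, and with one predictor there is nothing to select).
- **Missing predictors at imputation** contribute
  $w_k \cdot 2\,\mathrm{MAF}_k$ (the population-mean dosage from the
  training reference) rather than renormalizing the remaining weights:
  this preserves the linear form of the score and is configurable to
  `"omit"`.
- **Matching key** is (chromosome, position, allele set), not rsid,
  because rs identifiers drift across builds.
- **Separation** in the logistic fit (|β| > 20 or IRLS non-convergence)
  flags the gene and removes it from the FDR rather than switching to a
  penalized estimator, keeping the reported estimator exactly the
  stated model.
- **GReX scale.** Association is on raw GReX (the conventional
  "continuous variable" treatment); per-SD effects can be recovered by
  multiplying β by the sample SD of GReX.
- **Novelty threshold** defaults to $r^2 < 0.2$; published analyses
  sometimes quote a stricter $r^2 \le 0.1$ confirmation for specific
  genes, so the threshold is an argument.
- **Coordinates** are 1-based inclusive everywhere internally; only BED
  export converts to 0-based half-open.
- **Heterogeneity from published CIs.** When only odds ratios and 95%
  CIs are available, `or_ci_to_logse()` back-transforms
  $se = (\log hi - \log lo)/(2 z_{0.975})$; Q computed from rounded CIs
  is itself approximate, which is why a published "Q-test P = 1.0" can
  legitimately recompute as ~0.86 from the printed intervals.

# Problem sizes used by the test suite

The statistical acceptance checks run at deliberately chosen desk-scale
conditions: null calibration on 500 genes (5 cis variants each,
$h^2 = 0.3$) in a 2000/2000 cohort; power/recovery on 20 genes
(3 causal at $|\log OR| = 0.15$ per SD, $h^2 = 0.5$) with a 2000/2000
discovery cohort and two 2000/2000 replication cohorts over 50
simulation seeds; elastic-net recovery across
$h^2 \in \{0, 0.1, 0.3, 0.5, 0.8\}$ at $n_{ref} = 500$ with 30 genes
per level. The causal effect size and heritability sit comfortably
inside the regime where a back-of-envelope power calculation
($z \approx \beta\,\rho_{pred}\,\sqrt{n_{ca}n_{co}/n}$, with
$\rho_{pred} \approx \sqrt{R^2_{pred}/h^2}$) predicts > 95% per-gene
discovery power, so the 80% all-three-discovered-and-two-replicated
criterion tests the pipeline, not luck.

# Known limitations

- The generator's integer dosages make the hard-call/dosage distinction
  trivial; QC call-rate behaviour on fractional dosages is tested only
  through hand-built fixtures.
- With one MAF per cis block, MAF-dependent LD feasibility is never
  binding, but cross-block MAF variation is still exercised.
- `two_stage()` treats novelty as an input label; it does not itself
  recompute LD, so the caller must supply a panel that covers both
  predictors and index variants for `novelty_screen()`.
- Fixed-effect meta-analysis assumes within-ancestry homogeneity;
  random-effects models are out of scope.

# A minimal worked run

```{r, eval = FALSE}
library(grextas)
cfg <- sim_config(seed = 1, n_genes = 20, m_cis = 20, n_ref = 500,
                  h2_per_gene = 0.5,
                  causal_genes = data.frame(gene_id = c("G0001", "G0002",
                                                        "G0003"),
                                            log_or = c(0.15, -0.15, 0.15)),
                  n_cases = 2000, n_controls = 2000,
                  n_replication_cohorts = 2,
                  rep_n_cases = 2000, rep_n_controls = 2000)
res <- run_twas_study(cfg)
res$inflation
subset(res$report, status != "not_carried")
```
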