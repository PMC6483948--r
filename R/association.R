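default_covariates <- c("age", "sex", "center", "batch",
                        "pc1", "pc2", "pc3", "pc4")

#' Per-gene logistic regression of case status on GReX
#'
#' Fits `case ~ GReX + covariates` by iteratively reweighted least
#' squares (convergence tolerance 1e-8, at most 50 iterations), with
#' GReX treated as a continuous variable on its natural scale. The
#' Wald standard error comes from the observed information; P is
#' two-sided normal. Covariates with a single observed level are dropped
#' ("when appropriate"); `center` and `batch` enter as factors.
#' Detected separation (|beta| > 20) or IRLS non-convergence flags the
#' result as non-converged, which excludes it from FDR downstream.
#'
#' @param grex Numeric GReX vector aligned to `pheno` rows.
#' @param pheno Phenotype data frame with a 0/1 `case` column and the
#'   covariate columns.
#' @param covariates Covariate names to adjust for (subset of `pheno`).
#' @param gene_id,stratum Labels copied into the result.
#' @return One-row data frame: `gene, stratum, n_cases, n_controls,
#'   beta, se, z, p, or, ci_lo, ci_hi, converged, reason` (estimates are
#'   `NA` with a reason for degenerate input such as zero-variance GReX).
#' @examples
#' ph <- data.frame(case = rep(c(1, 0), each = 50))
#' fit_gene_logistic(rep(c(0, 1), 50), ph, covariates = character(0))
#' @export
fit_gene_logistic <- function(grex, pheno,
                              covariates = default_covariates,
                              gene_id = NA_character_, stratum = "all") {
  empty <- function(reason, converged = FALSE) {
    data.frame(gene = gene_id, stratum = stratum,
               n_cases = sum(pheno$case == 1),
               n_controls = sum(pheno$case == 0),
               beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
               or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
               converged = converged, reason = reason,
               stringsAsFactors = FALSE)
  }
  if (length(grex) != nrow(pheno))
    stopf("GReX and phenotype lengths differ")
  if (sum(pheno$case == 1) < 1 || sum(pheno$case == 0) < 1)
    stopf("need at least one case and one control")
  if (anyNA(pheno$case)) stopf("missing case status")
  if (var(grex) == 0) return(empty("zero-variance GReX"))

  covariates <- intersect(covariates, names(pheno))
  dat <- data.frame(.case = pheno$case, .grex = grex,
                    pheno[, covariates, drop = FALSE])
  for (v in c("center", "batch"))
    if (v %in% covariates) dat[[v]] <- factor(dat[[v]])
  keep <- vapply(covariates, function(v) length(unique(dat[[v]])) > 1,
                 logical(1))
  covariates <- covariates[keep]
  fml <- stats::reformulate(c(".grex", covariates), response = ".case")
  fit <- suppressWarnings(
    glm(fml, family = binomial(),
        data = dat,
        control = glm.control(epsilon = 1e-8, maxit = 50L)))
  cf <- summary(fit)$coefficients
  if (!".grex" %in% rownames(cf)) return(empty("GReX aliased in design"))
  beta <- cf[".grex", "Estimate"]
  se <- cf[".grex", "Std. Error"]
  z <- beta / se
  converged <- fit$converged && abs(beta) <= 20
  data.frame(gene = gene_id, stratum = stratum,
             n_cases = sum(pheno$case == 1),
             n_controls = sum(pheno$case == 0),
             beta = beta, se = se, z = z,
             p = 2 * pnorm(-abs(z)),
             or = exp(beta),
             ci_lo = exp(beta - qnorm(0.975) * se),
             ci_hi = exp(beta + qnorm(0.975) * se),
             converged = converged,
             reason = if (converged) NA_character_ else
               "separation or non-convergence",
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up adjustment `q_(i) = min_{j >= i} m p_(j) / j`, returned in
#' input order (via [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of P-values in (0, 1\].
#' @return Adjusted values in (0, 1\].
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1))
    stopf("P-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Genomic inflation factor and QQ coordinates
#'
#' Lambda is the median of the 1-df chi-square statistics implied by the
#' P-values, divided by the null median (`qchisq(0.5, 1)` = 0.4549...).
#' QQ points are sorted (expected, observed) pairs on the -log10 scale.
#'
#' @param p_values At least 10 P-values in (0, 1\].
#' @return An `inflation_report`: list with `lambda_gc` and `qq_points`
#'   (data frame `expected`, `observed`).
#' @examples
#' genomic_lambda(rep(0.5, 20))$lambda_gc  # exactly 1
#' @export
genomic_lambda <- function(p_values) {
  p_values <- p_values[is.finite(p_values)]
  if (length(p_values) < 10) stopf("need at least 10 P-values")
  if (any(p_values <= 0 | p_values > 1)) stopf("P-values must lie in (0, 1]")
  chi <- qchisq(p_values, df = 1, lower.tail = FALSE)
  lambda <- median(chi) / qchisq(0.5, df = 1)
  m <- length(p_values)
  qq <- data.frame(expected = -log10(ppoints(m)),
                   observed = -log10(sort(p_values)))
  structure(list(lambda_gc = lambda, qq_points = qq),
            class = "inflation_report")
}

#' @export
print.inflation_report <- function(x, ...) {
  cat(sprintf("<inflation_report> lambda = %.3f over %d tests\n",
              x$lambda_gc, nrow(x$qq_points)))
  invisible(x)
}

#' Association scan over a GReX matrix
#'
#' Fits [fit_gene_logistic()] per gene and attaches Benjamini-Hochberg
#' q-values computed over the converged fits (non-converged or degenerate
#' genes get `q_bh = NA` and are excluded from the FDR).
#'
#' @param grex A `grex_matrix` (from [compute_grex_all()]) or a genes x
#'   samples matrix whose columns align to `pheno` rows.
#' @param pheno Phenotype data frame (see [fit_gene_logistic()]).
#' @param covariates Covariates to adjust for.
#' @param stratum Label stored on every row.
#' @return Data frame, one row per gene: the [fit_gene_logistic()]
#'   columns plus `q_bh`.
#' @export
association_scan <- function(grex, pheno,
                             covariates = default_covariates,
                             stratum = "all") {
  values <- if (inherits(grex, "grex_matrix")) grex$values else grex
  if (ncol(values) != nrow(pheno))
    stopf("GReX sample count does not match phenotype rows")
  rows <- lapply(rownames(values), function(g)
    fit_gene_logistic(values[g, ], pheno, covariates,
                      gene_id = g, stratum = stratum))
  out <- do.call(rbind, rows)
  out$q_bh <- NA_real_
  ok <- which(out$converged & is.finite(out$p))
  if (length(ok)) out$q_bh[ok] <- bh_fdr(out$p[ok])
  out
}

#' Site-stratified association for one gene
#'
#' Cases of each anatomic site (`proximal`, `distal`, `rectal`) are
#' compared against **all** controls; cases with unspecified site are
#' excluded. A stratum with no cases is omitted; one with fewer than 10
#' cases is fitted anyway and flagged in `reason`.
#'
#' @inheritParams fit_gene_logistic
#' @param strata Site labels to analyze.
#' @return Data frame with one row per available stratum.
#' @export
stratified_association <- function(grex, pheno,
                                   covariates = default_covariates,
                                   gene_id = NA_character_,
                                   strata = c("proximal", "distal",
                                              "rectal")) {
  if (!"site" %in% names(pheno)) stopf("phenotype table lacks 'site'")
  out <- list()
  for (s in strata) {
    idx <- which((pheno$case == 1 & pheno$site == s) | pheno$case == 0)
    n_ca <- sum(pheno$case[idx] == 1)
    if (n_ca == 0) {
      message(sprintf("stratum '%s': no cases; omitted", s))
      next
    }
    r <- fit_gene_logistic(grex[idx], pheno[idx, , drop = FALSE],
                           covariates, gene_id = gene_id, stratum = s)
    if (n_ca < 10 && is.na(r$reason))
      r$reason <- sprintf("only %d cases in stratum", n_ca)
    out[[s]] <- r
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Cochran's Q heterogeneity test
#'
#' Inverse-variance-weighted heterogeneity of effect estimates:
#' `Q = sum w_i (theta_i - theta_bar_w)^2` with `w_i = 1/se_i^2`,
#' compared to chi-square with k - 1 degrees of freedom.
#'
#' @param beta Effect estimates (e.g. log odds ratios).
#' @param se Standard errors (> 0), same length as `beta` (>= 2).
#' @return A `heterogeneity_result`: list with `q_stat`, `df`, `p`.
#' @examples
#' cochran_q(c(0.1, 0.1), c(0.05, 0.05))  # Q = 0, P = 1
#' @export
cochran_q <- function(beta, se) {
  if (length(beta) < 2 || length(beta) != length(se))
    stopf("need >= 2 (beta, se) pairs of equal length")
  if (any(se <= 0)) stopf("standard errors must be positive")
  w <- 1 / se^2
  bw <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - bw)^2)
  structure(list(q_stat = q, df = length(beta) - 1L,
                 p = pchisq(q, df = length(beta) - 1L, lower.tail = FALSE)),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("<heterogeneity_result> Q = %.3f on %d df, P = %.3g\n",
              x$q_stat, x$df, x$p))
  invisible(x)
}

#' Standard error of a log odds ratio from a reported 95% CI
#'
#' `(log(hi) - log(lo)) / (2 * 1.959964...)`; useful for heterogeneity
#' tests on published odds ratios.
#'
#' @param ci_lo,ci_hi Confidence-interval bounds on the odds-ratio scale.
#' @return Standard error on the log scale.
#' @export
or_ci_to_logse <- function(ci_lo, ci_hi) {
  if (any(ci_lo <= 0) || any(ci_hi <= ci_lo))
    stopf("need 0 < ci_lo < ci_hi")
  (log(ci_hi) - log(ci_lo)) / (2 * qnorm(0.975))
}
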