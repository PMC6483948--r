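#' Training configuration for cis elastic-net expression models
#'
#' @param alpha_mixing Elastic-net mixing parameter in \[0, 1\]
#'   (0 = ridge, 1 = lasso); default 0.5.
#' @param n_folds Cross-validation folds (>= 2); default 10.
#' @param cis_window Distance in bp from the gene's TSS within which
#'   variants are eligible predictors; default 1 Mb.
#' @param nlambda,lambda_min_ratio Penalty path: `nlambda` log-spaced
#'   values down to `lambda_min_ratio` times the largest penalty.
#' @param seed Integer; fixes fold assignment (and therefore the
#'   cross-validated predictive R-squared) exactly.
#' @return An object of class `training_config`.
#' @export
training_config <- function(alpha_mixing = 0.5, n_folds = 10L,
                            cis_window = 1e6, nlambda = 100L,
                            lambda_min_ratio = 1e-4, seed = 1L) {
  if (alpha_mixing < 0 || alpha_mixing > 1)
    stopf("'alpha_mixing' must lie in [0, 1]")
  if (!is_count(n_folds) || n_folds < 2) stopf("'n_folds' must be >= 2")
  if (cis_window <= 0) stopf("'cis_window' must be positive")
  structure(list(alpha_mixing = alpha_mixing, n_folds = as.integer(n_folds),
                 cis_window = cis_window, nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Cross-validated predictive R-squared
#'
#' Signed squared Pearson correlation between observed expression and
#' pooled out-of-fold predictions: `sign(r) * r^2`, so anti-predictive
#' models return a negative value and fail the model-inclusion filter.
#' If either vector has zero variance the value is 0 and the result
#' carries attribute `degenerate = TRUE`.
#'
#' @param observed,cv_predicted Equal-length numeric vectors (>= 3).
#' @return A single numeric; possibly with attribute `degenerate`.
#' @examples
#' cv_predictive_r2(1:10, 1:10)            # 1
#' cv_predictive_r2(1:10, rep(0, 10))      # 0, degenerate
#' @export
cv_predictive_r2 <- function(observed, cv_predicted) {
  if (length(observed) != length(cv_predicted))
    stopf("observed and predicted lengths differ")
  if (length(observed) < 3) stopf("need at least 3 observations")
  if (anyNA(observed) || anyNA(cv_predicted))
    stopf("missing values in observed/predicted expression")
  if (sd(observed) == 0 || sd(cv_predicted) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  r <- cor(observed, cv_predicted)
  sign(r) * r^2
}

# deterministic fold assignment for a gene under the training seed
gene_foldid <- function(n, n_folds, seed, gene) {
  h <- sum(utf8ToInt(gene)) %% 7919L
  with_seed(sub_seed(seed, 10000L + h),
            sample(rep_len(seq_len(n_folds), n)))
}

#' Train a cis elastic-net expression prediction model for one gene
#'
#' Variants within `cis_window` of the gene's TSS are offered to an
#' elastic net (via glmnet) with mixing parameter `alpha_mixing`; the
#' penalty is chosen by `n_folds`-fold cross-validation at minimum mean
#' squared error, and the model's predictive R-squared is the signed
#' squared correlation between observed expression and the pooled
#' out-of-fold predictions at that penalty ([cv_predictive_r2()]).
#' Genes with a single cis variant are fitted by per-fold least squares
#' (no selection problem exists). Weights are reported on the original
#' dosage scale.
#'
#' @param panel Reference [genotype_panel()].
#' @param expression Genes x samples numeric matrix (row names = gene
#'   ids), e.g. `simulate_expression(...)$expression`.
#' @param gene Gene identifier (a row of `expression`).
#' @param annotation Data frame with `gene_id`, `chrom`, `tss`.
#' @param cfg A [training_config()].
#' @return A `weight_model` (list with `gene_id`, `chrom`, `tss`,
#'   `predictors` data frame `rsid, chrom, pos, ref, alt, weight, ref_maf`,
#'   `pred_r2`, `n_variants`), or `NULL` when the gene has no cis variant.
#' @export
train_model <- function(panel, expression, gene, annotation,
                        cfg = training_config()) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- annotation[annotation$gene_id == gene, , drop = FALSE]
  if (nrow(g) != 1L) stopf("gene '%s' not found in annotation", gene)
  if (!gene %in% rownames(expression))
    stopf("gene '%s' not found in expression matrix", gene)
  y <- expression[gene, ]
  if (any(!is.finite(y))) stopf("non-finite expression values for '%s'", gene)
  n <- length(y)
  if (n != length(panel$sample_ids))
    stopf("expression and panel sample counts differ")
  if (n < 2L * cfg$n_folds)
    stopf("need at least %d samples for %d-fold CV", 2L * cfg$n_folds,
          cfg$n_folds)
  cis <- which(panel$variants$chrom == g$chrom &
                 abs(panel$variants$pos - g$tss) <= cfg$cis_window)
  if (!length(cis)) return(NULL)
  x <- panel$dosages[, cis, drop = FALSE]
  foldid <- gene_foldid(n, cfg$n_folds, cfg$seed, gene)

  if (ncol(x) == 1L) {
    oof <- numeric(n)
    for (f in seq_len(cfg$n_folds)) {
      hold <- foldid == f
      fit <- lm(y[!hold] ~ x[!hold, 1])
      oof[hold] <- coef(fit)[1] + coef(fit)[2] * x[hold, 1]
    }
    slope <- unname(coef(lm(y ~ x[, 1]))[2])
    beta <- slope
    keep <- which(is.finite(beta) & beta != 0)
    pred_r2 <- cv_predictive_r2(y, oof)
  } else {
    fit <- glmnet::cv.glmnet(x, y, alpha = cfg$alpha_mixing,
                             foldid = foldid, keep = TRUE,
                             nlambda = cfg$nlambda,
                             lambda.min.ratio = cfg$lambda_min_ratio,
                             standardize = TRUE)
    i_min <- which.min(fit$cvm)
    oof <- fit$fit.preval[, i_min]
    pred_r2 <- cv_predictive_r2(y, oof)
    beta <- as.numeric(coef(fit, s = fit$lambda[i_min]))[-1]
    keep <- which(beta != 0)
  }
  pred <- panel$variants[cis[keep], c("rsid", "chrom", "pos", "ref", "alt"),
                         drop = FALSE]
  pred$weight <- beta[keep]
  pred$ref_maf <- colMeans(panel$dosages[, cis[keep], drop = FALSE],
                           na.rm = TRUE) / 2
  rownames(pred) <- NULL
  weight_model(gene_id = gene, chrom = g$chrom, tss = g$tss,
               predictors = pred, pred_r2 = as.numeric(pred_r2))
}

#' Construct a weight model
#'
#' @param gene_id Gene identifier.
#' @param chrom,tss Transcription-start-site locus of the gene.
#' @param predictors Data frame `rsid, chrom, pos, ref, alt, weight`
#'   (optionally `ref_maf`); weights must be finite and nonzero, rsid
#'   unique.
#' @param pred_r2 Cross-validated predictive R-squared.
#' @return An object of class `weight_model`.
#' @export
weight_model <- function(gene_id, chrom, tss, predictors, pred_r2) {
  need <- c("rsid", "chrom", "pos", "ref", "alt", "weight")
  if (!all(need %in% names(predictors)))
    stopf("predictors must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(predictors$rsid))
    stopf("duplicate predictor rsid in model for %s", gene_id)
  if (nrow(predictors) &&
      (any(!is.finite(predictors$weight)) || any(predictors$weight == 0)))
    stopf("predictor weights must be finite and nonzero")
  if (!"ref_maf" %in% names(predictors)) predictors$ref_maf <- NA_real_
  structure(list(gene_id = gene_id, chrom = chrom, tss = as.numeric(tss),
                 predictors = predictors, pred_r2 = as.numeric(pred_r2),
                 n_variants = nrow(predictors)),
            class = "weight_model")
}

#' @export
print.weight_model <- function(x, ...) {
  cat(sprintf("<weight_model> %s (%s:%d): %d predictor(s), pred R2 = %.3f\n",
              x$gene_id, x$chrom, as.integer(x$tss), x$n_variants, x$pred_r2))
  invisible(x)
}

#' Train models for many genes
#'
#' @inheritParams train_model
#' @param genes Gene ids to train; default every row of `annotation`.
#' @param verbose Print a progress line every 100 genes.
#' @return Named list of `weight_model`s; genes without cis variants are
#'   omitted.
#' @export
train_models <- function(panel, expression, annotation,
                         cfg = training_config(), genes = NULL,
                         verbose = FALSE) {
  genes <- genes %||% annotation$gene_id
  out <- list()
  for (i in seq_along(genes)) {
    m <- train_model(panel, expression, genes[i], annotation, cfg)
    if (!is.null(m)) out[[genes[i]]] <- m
    if (verbose && i %% 100L == 0L)
      message(sprintf("trained %d / %d genes", i, length(genes)))
  }
  out
}

#' Filter weight models on predictive performance
#'
#' Keeps models whose cross-validated predictive R-squared is at least
#' `r2_min` (inclusive threshold), preserving order.
#'
#' @param models List of `weight_model`s.
#' @param r2_min Inclusion threshold; default 0.01.
#' @return The surviving sub-list.
#' @export
filter_models <- function(models, r2_min = 0.01) {
  keep <- vapply(models, function(m) m$pred_r2 >= r2_min, logical(1))
  models[keep]
}
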