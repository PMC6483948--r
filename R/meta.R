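#' Fixed-effect meta-analysis of per-study log odds ratios
#'
#' Default (`"ivw"`): inverse-variance weights `w_i = 1/se_i^2`,
#' `beta_meta = sum(w b) / sum(w)`, `se_meta = 1/sqrt(sum(w))`,
#' `z_meta = beta_meta / se_meta`, two-sided normal P. The alternative
#' `"stouffer"` mode combines Z scores weighted by precision,
#' `z_meta = sum(w_i z_i) / sqrt(sum(w_i^2))` with `w_i = 1/se_i`
#' (a sensitivity reading of "inverse variance weighting of Z scores");
#' it reports no pooled effect size.
#'
#' @param beta Per-study log odds ratios.
#' @param se Per-study standard errors (> 0).
#' @param method `"ivw"` (default) or `"stouffer"`.
#' @return A `meta_result`: list with `beta_meta`, `se_meta`, `z_meta`,
#'   `p_meta`, `k_studies`, `method`.
#' @examples
#' meta_fixed_effect(c(0.1, 0.1), c(0.05, 0.05))
#' @export
meta_fixed_effect <- function(beta, se, method = c("ivw", "stouffer")) {
  method <- match.arg(method)
  if (!length(beta) || length(beta) != length(se))
    stopf("need k >= 1 (beta, se) pairs of equal length")
  if (any(!is.finite(se) | se <= 0)) stopf("standard errors must be positive")
  if (method == "ivw") {
    w <- 1 / se^2
    bm <- sum(w * beta) / sum(w)
    sm <- 1 / sqrt(sum(w))
    zm <- bm / sm
  } else {
    w <- 1 / se
    z <- beta / se
    zm <- sum(w * z) / sqrt(sum(w^2))
    bm <- NA_real_
    sm <- NA_real_
  }
  structure(list(beta_meta = bm, se_meta = sm, z_meta = zm,
                 p_meta = 2 * pnorm(-abs(zm)),
                 k_studies = length(beta), method = method),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> k = %d (%s): z = %.3f, P = %.3g\n",
              x$k_studies, x$method, x$z_meta, x$p_meta))
  invisible(x)
}

#' Bonferroni replication decision
#'
#' A finding replicates when its meta-analysis P is below
#' `alpha / n_genes_tested` and (when both are supplied) the replication
#' effect direction agrees with discovery.
#'
#' @param p_meta Two-sided meta-analysis P-value.
#' @param n_genes_tested Number of genes carried to replication (>= 1).
#' @param alpha Family-wise level; default 0.05.
#' @param beta_meta,beta_discovery Optional effect estimates for the
#'   direction-consistency requirement.
#' @return List with `threshold` (= `alpha / n_genes_tested`) and
#'   `replicated` (logical).
#' @examples
#' replication_test(1.1e-2, 3)   # threshold 0.05/3, replicated
#' replication_test(0.62, 3)     # not replicated
#' @export
replication_test <- function(p_meta, n_genes_tested, alpha = 0.05,
                             beta_meta = NULL, beta_discovery = NULL) {
  if (!is_count(n_genes_tested)) stopf("'n_genes_tested' must be >= 1")
  threshold <- alpha / n_genes_tested
  ok <- is.finite(p_meta) && p_meta < threshold
  if (!is.null(beta_meta) && !is.null(beta_discovery))
    ok <- ok && sign(beta_meta) == sign(beta_discovery)
  list(threshold = threshold, replicated = ok)
}

#' Two-stage discovery/replication report
#'
#' Genes with discovery `q_bh <= fdr` (converged fits only) that pass the
#' novelty screen are carried to replication; for each carried gene the
#' per-study replication effects are combined by [meta_fixed_effect()]
#' and judged by [replication_test()] against `alpha / n_carried`, with
#' direction consistency required. Labels per gene:
#' `replicated`, `not_replicated`, `untested` (carried but absent from
#' every replication study), `not_novel`, `not_carried`.
#'
#' @param discovery Association data frame (as from
#'   [association_scan()]) with columns `gene, beta, se, p, q_bh,
#'   converged`.
#' @param replication List of per-study association data frames with
#'   columns `gene, beta, se, converged`.
#' @param fdr Discovery FDR threshold; default 0.2.
#' @param alpha Replication family-wise level; default 0.05.
#' @param novel Optional named logical over genes (from
#'   [novelty_check()]); default: every gene is novel.
#' @param method Meta-analysis mode, see [meta_fixed_effect()].
#' @return Data frame, one row per discovery gene: `gene, status, q_bh,
#'   beta_discovery, k_studies, beta_meta, z_meta, p_meta, threshold`.
#' @export
two_stage <- function(discovery, replication, fdr = 0.2, alpha = 0.05,
                      novel = NULL, method = "ivw") {
  if (!nrow(discovery))
    return(data.frame(gene = character(0), status = character(0),
                      q_bh = numeric(0), beta_discovery = numeric(0),
                      k_studies = integer(0), beta_meta = numeric(0),
                      z_meta = numeric(0), p_meta = numeric(0),
                      threshold = numeric(0), stringsAsFactors = FALSE))
  if (is.null(novel)) {
    novel <- setNames(rep(TRUE, nrow(discovery)), discovery$gene)
  }
  is_novel <- novel[discovery$gene]
  is_novel[is.na(is_novel)] <- TRUE
  hit <- discovery$converged & is.finite(discovery$q_bh) &
    discovery$q_bh <= fdr
  carried <- discovery$gene[hit & is_novel]
  n_carried <- length(carried)
  threshold <- if (n_carried) alpha / n_carried else NA_real_

  out <- data.frame(gene = discovery$gene,
                    status = "not_carried",
                    q_bh = discovery$q_bh,
                    beta_discovery = discovery$beta,
                    k_studies = 0L, beta_meta = NA_real_,
                    z_meta = NA_real_, p_meta = NA_real_,
                    threshold = NA_real_, stringsAsFactors = FALSE)
  out$status[hit & !is_novel] <- "not_novel"
  for (g in carried) {
    i <- match(g, out$gene)
    out$threshold[i] <- threshold
    studies <- do.call(rbind, lapply(replication, function(df) {
      r <- df[df$gene == g & df$converged, c("gene", "beta", "se"),
              drop = FALSE]
      if (nrow(r)) r else NULL
    }))
    if (is.null(studies) || !nrow(studies)) {
      out$status[i] <- "untested"
      next
    }
    mr <- meta_fixed_effect(studies$beta, studies$se, method = method)
    eff <- if (is.finite(mr$beta_meta)) mr$beta_meta else mr$z_meta
    dec <- replication_test(mr$p_meta, n_carried, alpha,
                            beta_meta = eff,
                            beta_discovery = out$beta_discovery[i])
    out$k_studies[i] <- mr$k_studies
    out$beta_meta[i] <- mr$beta_meta
    out$z_meta[i] <- mr$z_meta
    out$p_meta[i] <- mr$p_meta
    out$status[i] <- if (dec$replicated) "replicated" else "not_replicated"
  }
  out
}
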