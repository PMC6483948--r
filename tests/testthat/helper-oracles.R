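# independent reference implementations used as oracles; deliberately
# naive and kept apart from the package's own code paths

# O(m^2) direct minimization form of the BH step-up adjustment
bh_direct <- function(p) {
  m <- length(p)
  ord <- order(p)
  vapply(seq_len(m), function(i) {
    ri <- which(ord == i)  # rank of observation i
    min(1, min(vapply(ri:m, function(j) m * p[ord[j]] / j, numeric(1))))
  }, numeric(1))
}

# transitive-closure brute force for interval merging: repeatedly merge
# any overlapping pair until a fixed point
merge_brute <- function(start, end) {
  iv <- cbind(start, end)
  repeat {
    merged <- FALSE
    i <- 1
    while (i < nrow(iv)) {
      j <- i + 1
      while (j <= nrow(iv)) {
        if (iv[i, 1] <= iv[j, 2] && iv[j, 1] <= iv[i, 2]) {
          iv[i, ] <- c(min(iv[i, 1], iv[j, 1]), max(iv[i, 2], iv[j, 2]))
          iv <- iv[-j, , drop = FALSE]
          merged <- TRUE
        } else j <- j + 1
      }
      i <- i + 1
    }
    if (!merged) break
  }
  iv[order(iv[, 1]), , drop = FALSE]
}

# element-by-element loop computation of a weighted dosage sum
grex_brute <- function(model, panel, missing_policy = "mean") {
  n <- length(panel$sample_ids)
  out <- numeric(n)
  key <- paste(panel$variants$chrom, panel$variants$pos)
  for (i in seq_len(nrow(model$predictors))) {
    pr <- model$predictors[i, ]
    if (paste0(pr$ref, "/", pr$alt) %in% c("A/T", "T/A", "C/G", "G/C")) {
      j <- NA
    } else {
      j <- match(paste(pr$chrom, pr$pos), key)
      if (!is.na(j)) {
        vr <- panel$variants$ref[j]; va <- panel$variants$alt[j]
        if (!((vr == pr$ref && va == pr$alt) ||
              (vr == pr$alt && va == pr$ref))) j <- NA
      }
    }
    for (s in seq_len(n)) {
      if (!is.na(j)) {
        d <- panel$dosages[s, j]
        if (panel$variants$ref[j] == pr$alt) d <- 2 - d
        out[s] <- out[s] + pr$weight * d
      } else if (missing_policy == "mean" && is.finite(pr$ref_maf)) {
        out[s] <- out[s] + pr$weight * 2 * pr$ref_maf
      }
    }
  }
  out
}
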