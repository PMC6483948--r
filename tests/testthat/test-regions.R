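test_that("a single index variant defines a +/- 1 Mb window", {
  iv <- data.frame(rsid = "r1", chrom = "chr5", pos = 5e6)
  r <- build_regions(iv)
  expect_equal(r$start, 4e6)
  expect_equal(r$end, 6e6)
  expect_equal(r$n_index, 1)
  # windows are floored at position 1
  r2 <- build_regions(data.frame(rsid = "r2", chrom = "chr1", pos = 100))
  expect_equal(r2$start, 1)
})

test_that("overlapping windows merge transitively", {
  iv <- data.frame(rsid = c("a", "b", "c"), chrom = "chr1",
                   pos = c(1e6, 2.5e6, 5e6))
  r <- build_regions(iv)
  expect_equal(nrow(r), 2)
  expect_equal(r$start, c(1, 4e6))
  expect_equal(r$end, c(3.5e6, 6e6))
  expect_equal(r$n_index, c(2, 1))
  expect_equal(r$index_rsids, c("a,b", "c"))
})

test_that("merging matches brute force, is order-invariant and idempotent", {
  set.seed(60)
  for (rep in 1:50) {
    k <- sample(1:20, 1)
    iv <- data.frame(rsid = sprintf("r%d", 1:k),
                     chrom = sample(c("chr1", "chr2"), k, replace = TRUE),
                     pos = sample(1e6:3e7, k))
    r <- build_regions(iv, flank = 1e6)
    for (ch in unique(iv$chrom)) {
      sub <- iv[iv$chrom == ch, ]
      bf <- merge_brute(pmax(1, sub$pos - 1e6), sub$pos + 1e6)
      got <- r[r$chrom == ch, ]
      expect_equal(unname(cbind(got$start, got$end)), unname(bf))
    }
    # order invariance
    perm <- iv[sample(nrow(iv)), ]
    r_perm <- build_regions(perm, flank = 1e6)
    expect_equal(r[, c("chrom", "start", "end", "n_index")],
                 r_perm[, c("chrom", "start", "end", "n_index")])
    # conservation and coverage: each input variant in exactly one region
    expect_equal(sum(r$n_index), nrow(iv))
    for (i in seq_len(nrow(iv))) {
      inreg <- r$chrom == iv$chrom[i] & r$start <= iv$pos[i] &
        r$end >= iv$pos[i]
      expect_equal(sum(inreg), 1)
    }
    # output regions are pairwise disjoint per chromosome (a fixed point
    # of merging: re-merging them is a no-op)
    for (ch in unique(r$chrom)) {
      got <- r[r$chrom == ch, ]
      if (nrow(got) > 1)
        expect_true(all(got$start[-1] > got$end[-nrow(got)]))
    }
  }
})

test_that("touching windows (sharing one bp) are merged", {
  iv <- data.frame(rsid = c("a", "b"), chrom = "chr1", pos = c(2e6, 4e6))
  expect_equal(nrow(build_regions(iv)), 1)   # [1e6,3e6] and [3e6,5e6] touch
  iv2 <- data.frame(rsid = c("a", "b"), chrom = "chr1", pos = c(2e6, 4e6 + 1))
  expect_equal(nrow(build_regions(iv2)), 2)
})

test_that("region summaries count genes and reductions as defined", {
  ann <- data.frame(gene_id = sprintf("g%02d", 1:25),
                    chrom = c(rep("chr1", 20), rep("chr2", 5)),
                    tss = c(seq(1e6, 2.9e6, length.out = 20),
                            seq(1e6, 2e6, length.out = 5)))
  region <- data.frame(chrom = "chr1", start = 1e6, end = 3e6)
  models_ct <- sprintf("g%02d", 1:12)
  models_wb <- sprintf("g%02d", 5:16)
  assoc <- data.frame(gene = c("g01", "g22"), tissue = "ct",
                      p = c(0.04, 0.01))
  s <- summarize_region(region, ann, models_ct, models_wb, assoc)
  expect_equal(s$n_ccds, 20)
  expect_equal(s$n_models_ct, 12)
  expect_equal(s$n_models_wb, 12)
  expect_equal(s$n_overlap, 8)
  expect_equal(s$pct_overlap, 100 * 8 / 16)
  expect_equal(s$n_assoc, 1)          # g22 is outside the region
  expect_equal(s$pct_reduced, 95)     # 20 genes -> 1 associated

  # boundary conventions: no associated gene -> 100; all associated -> 0
  s0 <- summarize_region(region, ann, models_ct, models_wb,
                         data.frame(gene = character(0), tissue = character(0),
                                    p = numeric(0)))
  expect_equal(s0$pct_reduced, 100)
  all_sig <- data.frame(gene = sprintf("g%02d", 1:20), tissue = "ct", p = 0.01)
  s1 <- summarize_region(region, ann, sprintf("g%02d", 1:20), character(0),
                         all_sig)
  expect_equal(s1$pct_reduced, 0)
  # an empty region has an undefined reduction
  empty <- summarize_region(data.frame(chrom = "chr9", start = 1, end = 2),
                            ann, models_ct, models_wb, assoc)
  expect_true(is.na(empty$pct_reduced))
  # p threshold is inclusive (P <= 0.05 counts)
  at_cut <- data.frame(gene = "g01", tissue = "ct", p = 0.05)
  expect_equal(summarize_region(region, ann, models_ct, models_wb,
                                at_cut)$n_assoc, 1)
})

test_that("percent reduction weakly decreases as the p cutoff loosens", {
  set.seed(61)
  ann <- data.frame(gene_id = sprintf("g%02d", 1:30), chrom = "chr1",
                    tss = seq(1e6, 2.9e6, length.out = 30))
  region <- data.frame(chrom = "chr1", start = 1e6, end = 3e6)
  assoc <- data.frame(gene = ann$gene_id, tissue = "ct", p = runif(30))
  cuts <- c(0.001, 0.01, 0.05, 0.2, 1)
  red <- vapply(cuts, function(pc)
    summarize_region(region, ann, ann$gene_id, character(0), assoc,
                     p_cut = pc)$pct_reduced, numeric(1))
  expect_false(is.unsorted(rev(red)))
})

test_that("LD r2 matches the direct covariance formula", {
  expect_equal(ld_r2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  expect_warning(r <- ld_r2(c(1, 1, 1), c(0, 1, 2)), "zero-variance")
  expect_true(is.na(r))
  set.seed(62)
  a <- rbinom(10, 2, 0.4); b <- rbinom(10, 2, 0.4)
  direct <- (mean(a * b) - mean(a) * mean(b))^2 /
    ((mean(a^2) - mean(a)^2) * (mean(b^2) - mean(b)^2))
  expect_equal(ld_r2(a, b), direct, tolerance = 1e-12)
  # independent common variants are near-zero LD
  hits <- vapply(1:40, function(i) {
    x <- rbinom(2000, 2, 0.3); y <- rbinom(2000, 2, 0.3)
    ld_r2(x, y) < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("novelty screening enforces distance and LD rules", {
  set.seed(63)
  n <- 200
  base <- rbinom(n, 2, 0.3)
  noisy <- pmin(2, pmax(0, base + rbinom(n, 1, 0.15)))  # r2 ~ 0.7 partner
  indep <- rbinom(n, 2, 0.3)
  d <- cbind(base, noisy, indep)
  panel <- manual_panel(d, pos = c(1e6, 1.2e6, 8e6))
  known <- data.frame(rsid = "idx1", chrom = "chr1", pos = 1e6)

  # predictor identical to the index variant: r2 = 1, and distance 0
  m_same <- manual_model(1, pos = 1e6)
  expect_false(novelty_check(m_same, known, panel)$novel)

  # predictor far away but in LD >= 0.2: not novel by the LD rule
  m_ld <- manual_model(1, pos = 1.2e6)
  stopifnot(ld_r2(d[, 1], d[, 2]) >= 0.2)
  nc <- novelty_check(m_ld, known, panel, distance_min = 1e5)
  expect_false(nc$novel)
  expect_equal(nc$evidence$index, "idx1")

  # far and unlinked: novel
  m_far <- manual_model(1, pos = 8e6)
  stopifnot(ld_r2(d[, 1], d[, 3]) < 0.2)
  expect_true(novelty_check(m_far, known, panel)$novel)

  # no known variant on the predictor's chromosome: novel
  known2 <- data.frame(rsid = "idx2", chrom = "chr7", pos = 1e6)
  expect_true(novelty_check(m_same, known2, panel)$novel)

  # near but unlinked: the distance rule alone voids novelty
  m_near <- manual_model(1, pos = 8e6)
  known3 <- data.frame(rsid = "idx3", chrom = "chr1", pos = 8.5e6)
  expect_false(novelty_check(m_near, known3, panel)$novel)
})

test_that("novelty evidence reports the worst pair from an exhaustive scan", {
  set.seed(64)
  n <- 500
  x <- rbinom(n, 2, 0.4)
  mk <- function(flip_p) {                      # correlated partner
    flip <- rbinom(n, 1, flip_p)
    pmin(2, pmax(0, ifelse(flip, 2 - x, x)))
  }
  d <- cbind(x, mk(0.25), mk(0.6))
  r2s <- c(1, ld_r2(d[, 1], d[, 2]), ld_r2(d[, 1], d[, 3]))
  panel <- manual_panel(d, pos = c(1e6, 3e6, 5e6))
  known <- data.frame(rsid = "idx", chrom = "chr1", pos = 1e6)
  model <- manual_model(c(1, 1), pos = c(3e6, 5e6))
  nc <- novelty_check(model, known, panel, r2_max = min(r2s[2:3]) * 0.9,
                      distance_min = 1e5)
  expect_false(nc$novel)
  # brute force over all predictor x index pairs
  worst <- which.max(r2s[2:3])
  expect_equal(nc$evidence$predictor, model$predictors$rsid[worst])
})

test_that("BED export converts to 0-based half-open coordinates", {
  r <- build_regions(data.frame(rsid = "r1", chrom = "chr2", pos = 5e6))
  path <- withr::local_tempfile(fileext = ".bed")
  regions_to_bed(r, path)
  bed <- read.delim(path, header = FALSE)
  expect_equal(bed$V2, 4e6 - 1)
  expect_equal(bed$V3, 6e6)
})
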