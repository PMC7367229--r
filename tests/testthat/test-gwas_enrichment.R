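test_that("window construction clips, merges and respects half-open ends", {
  ann <- as_gene_annotation(data.frame(
    gene_id = c("gA", "gB"), chrom = "chr1",
    start = c(30000, 5000), end = c(40000, 9000),
    length_bp = c(10000, 4000)))
  w <- gene_windows(ann[1, ], flank = 20000)
  expect_equal(c(w$start, w$end), c(10000, 60000))
  # 1-based SNP at 10001 sits at 0-based 10000: first base inside [10000, 60000)
  expect_true(snps_in_windows("chr1", 10001, w))
  expect_false(snps_in_windows("chr1", 10000, w))   # 0-based 9999
  expect_true(snps_in_windows("chr1", 60000, w))    # 0-based 59999, last in
  expect_false(snps_in_windows("chr1", 60001, w))   # 0-based 60000, excluded

  # clipping at zero
  w2 <- gene_windows(ann[2, ], flank = 20000)
  expect_equal(w2$start, 0)

  # merging of overlapping windows within a module
  wm <- gene_windows(ann, flank = 20000)
  expect_equal(nrow(wm), 1)    # [0, 29000) and [10000, 60000) overlap
  expect_equal(c(wm$start, wm$end), c(0, 60000))
})

test_that("snp-to-module mapping equals the all-pairs oracle", {
  set.seed(61)
  cfg <- small_cfg(seed = 61)
  sim <- simulate_expression(cfg)
  gw <- simulate_gwas(cfg, sim$annot, sim$truth)
  part <- sim$truth$modules
  idx <- map_snps_to_modules(gw, sim$annot, part, flank = 20000)
  for (m in names(idx)) {
    ann_m <- sim$annot[sim$annot$gene_id %in%
                         names(part)[part == m], , drop = FALSE]
    w <- gene_windows(ann_m, 20000, merge = FALSE)
    expect_identical(idx[[m]], which(oracle_snps_in_windows(gw$chrom,
                                                            gw$pos, w)))
  }
  # chromosome naming mismatch is a hard error listing names
  gw2 <- gw
  gw2$chrom <- sub("chr", "", gw2$chrom)
  expect_error(map_snps_to_modules(as_gwas_summary(as.data.frame(gw2)),
                                   sim$annot, part),
               "no shared chromosome")
})

test_that("t_sum is the plain sum of squares", {
  expect_equal(t_sum(c(0, 0, 0), 1:3), 0)
  expect_equal(t_sum(c(0.5, -0.5, 1.0), 1:3), 1.5)
  set.seed(8)
  for (i in 1:50) {
    b <- rnorm(200)
    s <- sample(200, sample(1:100, 1))
    acc <- 0
    for (j in s) acc <- acc + b[j] * b[j]
    expect_equal(t_sum(b, s), acc, tolerance = 1e-12)
  }
  expect_error(t_sum(c(1, NA), 1:2), "finite")
})

test_that("circular permutation reproduces the worked 4-SNP example", {
  gw <- data.frame(snp_id = paste0("s", 1:4), chrom = "chr1", pos = 1:4,
                   effect_b = c(1, 0, 0, 0), pvalue = rep(0.5, 4))
  gw <- as_gwas_summary(gw)
  ex <- circular_permutation_test(gw, snp_idx = 1:2, exhaustive = TRUE)
  # offsets 1,2,3 give T_perm {0, 0, 1}; add-one p = (1+1)/(1+3)
  expect_equal(ex$t_obs, 1)
  expect_equal(ex$n_perm, 3)
  expect_equal(ex$n_greater_equal, 1)
  expect_equal(ex$empirical_p, 0.5)

  # sampling mode concentrates on the underlying offset proportion 1/3
  sm <- circular_permutation_test(gw, 1:2, n_perm = 10000, seed = 1)
  phat <- sm$n_greater_equal / sm$n_perm
  expect_lt(abs(phat - 1/3), 3 * sqrt((1/3) * (2/3) / 10000))

  # module containing every SNP: rotation invariance forces p = 1
  full <- circular_permutation_test(gw, 1:4, exhaustive = TRUE)
  expect_equal(full$empirical_p, 1)

  # permutation preserves the effect multiset (asserted per draw)
  gw2 <- tiny_gwas(30, seed = 9)
  expect_silent(circular_permutation_test(gw2, c(2, 5, 11), n_perm = 50,
                                          seed = 2, check_multiset = TRUE))

  # empty module set: NA result row
  e <- circular_permutation_test(gw, integer(0))
  expect_true(is.na(e$empirical_p))
  expect_equal(e$n_snps, 0L)
})

test_that("T_sum is additive over disjoint SNP sets", {
  set.seed(10)
  b <- rnorm(500)
  s1 <- sample(500, 60)
  s2 <- sample(setdiff(1:500, s1), 80)
  expect_equal(t_sum(b, c(s1, s2)), t_sum(b, s1) + t_sum(b, s2),
               tolerance = 1e-12)
})

test_that("exhaustive and sampling modes agree within Monte-Carlo error", {
  gw <- tiny_gwas(400, seed = 17)
  idx <- sort(sample(400, 50))
  ex <- circular_permutation_test(gw, idx, exhaustive = TRUE)
  p_true <- ex$n_greater_equal / ex$n_perm
  sm <- circular_permutation_test(gw, idx, n_perm = 4000, seed = 3)
  se <- sqrt(p_true * (1 - p_true) / 4000)
  expect_lt(abs(sm$n_greater_equal / sm$n_perm - p_true), 3 * se + 1e-9)
})

test_that("enrich_all is deterministic and pools FDR over the grid", {
  cfg <- small_cfg(seed = 62)
  sim <- simulate_expression(cfg)
  gw <- simulate_gwas(cfg, sim$annot, sim$truth)
  part <- sim$truth$modules
  class(part) <- "module_partition"
  traits <- list(KETO = gw, MAST = simulate_gwas(cfg, sim$annot, sim$truth,
                                                 seed = 99))
  e1 <- enrich_all(traits, part, sim$annot, n_perm = 300, seed = 5)
  e2 <- enrich_all(traits, part, sim$annot, n_perm = 300, seed = 5)
  expect_identical(e1, e2)
  expect_equal(nrow(e1), 4 * 2)      # (3 modules + unassigned) x 2 traits
  expect_equal(e1$fdr, bh_fdr(e1$empirical_p))
  expect_true(all(e1$empirical_p > 0 & e1$empirical_p <= 1, na.rm = TRUE))
})

test_that("candidate genes come from per-gene min-p windows", {
  # one SNP at p = 1e-6 inside a significant-module gene: that gene only
  ann <- as_gene_annotation(data.frame(
    gene_id = c("gHit", "gFar"), chrom = "chr1",
    start = c(50000, 300000), end = c(60000, 310000),
    length_bp = c(10000, 10000)))
  gw <- as_gwas_summary(data.frame(
    snp_id = c("a", "b"), chrom = "chr1", pos = c(55000, 200000),
    effect_b = c(0.5, 0.1), pvalue = c(1e-6, 0.2)))
  part <- structure(setNames(c("m1", "m1"), c("gHit", "gFar")),
                    class = "module_partition")
  cand <- call_candidate_genes(gw, ann, part, "m1")
  expect_equal(cand$gene, "gHit")
  expect_equal(cand$top_snp, "a")

  # gene with no SNP in its window is absent even in a significant module
  expect_false("gFar" %in% cand$gene)

  # random fixture equals a brute-force per-gene min-p oracle
  cfg <- small_cfg(seed = 63)
  sim <- simulate_expression(cfg)
  gws <- simulate_gwas(cfg, sim$annot, sim$truth)
  part2 <- sim$truth$modules
  class(part2) <- "module_partition"
  cand2 <- call_candidate_genes(gws, sim$annot, part2, c("M1", "M2"),
                                p_threshold = 1e-3)
  expected <- character(0)
  for (g in names(part2)[part2 %in% c("M1", "M2")]) {
    ann_g <- sim$annot[sim$annot$gene_id == g, ]
    win <- c(max(0, ann_g$start - 20000), ann_g$end + 20000)
    inw <- gws$chrom == ann_g$chrom & gws$pos - 1 >= win[1] &
      gws$pos - 1 < win[2]
    if (any(inw) && min(gws$pvalue[inw]) < 1e-3) expected <- c(expected, g)
  }
  expect_setequal(cand2$gene, expected)
})
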