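test_that("config validation catches infeasible settings", {
  expect_error(synth_config(), "seed")
  expect_error(synth_config(seed = 1, within_module_cor = 1), "strictly")
  expect_error(synth_config(seed = 1, module_sizes = c(300, 300),
                            n_genes = 400), "n_genes")
  expect_error(synth_config(seed = 1, enriched_modules = c(M1 = 0.5)),
               ">= 1")
})

test_that("planted modules hit the configured within-module correlation", {
  # calibration oracle: latent pairwise cor = loading^2/(loading^2+noise)
  # = rho by construction; the observed log-count correlation is
  # attenuated by NB noise (dispersion 0.1) but must stay in [0.6, 0.8]
  # for rho = 0.7 at default depth.
  for (s in 1:3) {
    cfg <- synth_config(seed = s)
    sim <- simulate_expression(cfg)
    m3 <- names(sim$truth$modules)[sim$truth$modules == "M3"]  # 100 genes
    cc <- cor(t(log2(unclass(sim$counts)[m3, ] + 1)))
    expect_gt(mean(cc[upper.tri(cc)]), 0.6)
    expect_lt(mean(cc[upper.tri(cc)]), 0.8)
    # latent layer matches the calibration oracle: with realized factor
    # variance v, pairwise cor = rho v / (rho v + (1 - rho))
    zl <- cor(t(sim$truth$latent[m3, ]))
    v <- var(sim$truth$factors["M3", ])
    expect_equal(mean(zl[upper.tri(zl)]), 0.7 * v / (0.7 * v + 0.3),
                 tolerance = 0.03)
  }
})

test_that("null generator plants no module-state association", {
  # no trait coupling: the per-cell rate of |cor(factor, state)| > 0.5
  # stays at its null level (P ~ 0.013 at n = 24; bounded at twice that).
  # A "no cell in any seed exceeds 0.5" phrasing cannot hold under the
  # null across a multi-module grid: with 12 cells per seed the chance of
  # at least one exceedance is ~15% per seed by direct calculation.
  hits <- 0; cells <- 0
  for (s in 1:100) {
    cfg <- small_cfg(seed = s, trait_driving = list(),
                     enriched_modules = c(M1 = 1))
    sim <- simulate_expression(cfg)
    st <- sim$sample_info$state
    r <- abs(cor(t(sim$truth$factors),
                 sapply(KN_STATES, function(x) as.numeric(st == x))))
    hits <- hits + sum(r > 0.5)
    cells <- cells + length(r)
  }
  expect_lte(hits / cells, 2 * 0.013)
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- small_cfg(seed = 5)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$sample_info, b$sample_info)
  expect_identical(simulate_gwas(cfg, a$annot, a$truth),
                   simulate_gwas(cfg, b$annot, b$truth))
  expect_identical(simulate_tissue_panel(cfg)$panel$expr,
                   simulate_tissue_panel(cfg)$panel$expr)
})

test_that("bio-indicator couplings land at the configured correlation", {
  cfg <- synth_config(seed = 3)
  sim <- simulate_expression(cfg)
  f <- sim$truth$factors
  # exact by construction up to the 4-decimal rounding of written values
  expect_equal(abs(cor(sim$sample_info$BHBA, f["M1", ])), 0.7,
               tolerance = 1e-3)
  expect_equal(abs(cor(sim$sample_info$HDL, f["M2", ])), 0.75,
               tolerance = 1e-3)
})

test_that("gwas effects inflate inside enriched windows as configured", {
  cfg <- synth_config(seed = 2)
  sim <- simulate_expression(cfg)
  gw <- simulate_gwas(cfg, sim$annot, sim$truth)
  sdv <- attr(gw, "effect_sd")
  inside <- sdv > cfg$baseline_effect_sd
  expect_gt(sum(inside), 500)
  ratio <- mean(gw$effect_b[inside]^2) / mean(gw$effect_b[!inside]^2)
  expect_gt(ratio, 3.0)   # chi-square sampling bound around inflation 4
  expect_lt(ratio, 5.0)

  # inflation 1 everywhere: window/background mean b^2 within 10%
  cfg0 <- synth_config(seed = 2, enriched_modules = c(M1 = 1))
  sim0 <- simulate_expression(cfg0)
  gw0 <- simulate_gwas(cfg0, sim0$annot, sim0$truth)
  g1 <- names(sim0$truth$modules)[sim0$truth$modules == "M1"]
  win <- gene_windows(sim0$annot[sim0$annot$gene_id %in% g1, ], 20000)
  in0 <- snps_in_windows(gw0$chrom, gw0$pos, win)
  expect_lt(abs(mean(gw0$effect_b[in0]^2) / mean(gw0$effect_b[!in0]^2) - 1),
            0.10)

  # degenerate: zero effect SD gives all-zero effects
  cfgz <- small_cfg(seed = 4, baseline_effect_sd = 0,
                    enriched_modules = c(M1 = 1))
  simz <- simulate_expression(cfgz)
  expect_warning(gwz <- simulate_gwas(cfgz, simz$annot, simz$truth),
                 regexp = NA)
  expect_true(all(gwz$effect_b == 0))
})

test_that("tissue panel plants recoverable specific sets", {
  cfg <- small_cfg(seed = 6)
  expect_error(simulate_tissue_panel(cfg, n_tissues = 1), "2 tissues")

  # strong shift: planted genes recovered in the top 5% at sensitivity .9
  tp <- simulate_tissue_panel(cfg, shift = 5)
  sets <- top_fraction_sets(tp$panel, 0.05)
  sens <- vapply(names(tp$specific_sets), function(ts)
    mean(tp$specific_sets[[ts]] %in% sets$sets[[ts]]), numeric(1))
  expect_gte(mean(sens), 0.9)

  # zero shift: overlap with "planted" sets is at chance level
  tp0 <- simulate_tissue_panel(cfg, shift = 0)
  sets0 <- top_fraction_sets(tp0$panel, 0.05)
  ov <- vapply(names(tp0$specific_sets), function(ts)
    length(intersect(tp0$specific_sets[[ts]], sets0$sets[[ts]])), numeric(1))
  # hypergeometric expectation: |set| * |planted| / n_genes
  expected <- length(sets0$sets[[1]]) * length(tp0$specific_sets[[1]]) /
    cfg$n_genes
  expect_lt(mean(ov), expected + 3 * sqrt(expected + 1))
})

test_that("written synthetic artifacts round-trip through the readers", {
  cfg <- small_cfg(seed = 8)
  sim <- simulate_expression(cfg)
  gw <- simulate_gwas(cfg, sim$annot, sim$truth)
  d <- withr::local_tempdir()
  write_synthetic(sim, list(KETO = gw), d)
  expect_equal(unclass(read_count_matrix(file.path(d, "counts.tsv"))),
               unclass(sim$counts))
  expect_equal(read_module_partition(file.path(d, "ground_truth.tsv")),
               sim$truth$modules)
  back <- read_gwas_summary(file.path(d, "gwas_KETO.tsv"))
  expect_equal(back$effect_b, gw$effect_b, tolerance = 1e-12)
})
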