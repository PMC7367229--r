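test_that("TOM matches the hand formula and its trivial cases", {
  # two perfectly correlated genes at beta = 1: a = 1 and TOM = 1
  x <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8))
  colnames(x) <- paste0("s", 1:4)
  tom2 <- build_tom(x, 1)
  expect_equal(unname(tom2), matrix(1, 2, 2), ignore_attr = TRUE)

  # 5-gene case vs an independent triple-loop oracle
  set.seed(14)
  e5 <- matrix(rnorm(5 * 10), 5, 10,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  a <- abs(cor(t(e5)))^3
  tom <- build_tom(e5, 3)
  expect_equal(unname(unclass(tom)), oracle_tom(a), tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(build_tom(rbind(g1 = rep(2, 4), g2 = 1:4), 2), "zero-variance")
})

test_that("TOM is symmetric, unit-diagonal and within [0, 1] (property)", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(4:12, 1)
    e <- matrix(rnorm(n * 8), n, 8,
                dimnames = list(paste0("g", 1:n), paste0("s", 1:8)))
    tom <- unclass(build_tom(e, sample(1:8, 1)))
    attr(tom, "adjacency") <- NULL
    expect_identical(tom, t(tom))
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(unname(diag(tom)), rep(1, n))
  }
})

test_that("soft power selection honours fixed beta and falls back on noise", {
  cfg <- small_cfg(seed = 3)
  sim <- simulate_expression(cfg)
  vst <- vst_normalize(sim$counts, filter_genes(compute_tpm(sim$counts,
                                                            sim$annot))$genes)
  expect_equal(select_soft_power(vst, network_params(soft_power = 7))$beta, 7)

  # modular data: some beta <= 12 satisfies the scale-free criterion
  auto <- select_soft_power(vst, network_params())
  expect_lte(auto$beta, 12)
  expect_gte(max(auto$fit_table$r2), 0.8)

  # pure noise at small n rarely reaches R^2 >= 0.8: fallback 6 + warning
  set.seed(41)
  noise <- matrix(rnorm(200 * 8), 200, 8,
                  dimnames = list(paste0("g", 1:200), paste0("s", 1:8)))
  expect_warning(nb <- select_soft_power(noise,
                                         network_params(scale_free_target_r2 = 0.99)),
                 "falling back")
  expect_equal(nb$beta, 6)
})

test_that("detect_modules resolves perfect blocks and planted modules", {
  # two perfect blocks of 40: exactly two modules, empty unassigned
  g <- sprintf("g%02d", 1:80)
  tom <- matrix(0, 80, 80, dimnames = list(g, g))
  tom[1:40, 1:40] <- 1
  tom[41:80, 41:80] <- 1
  part <- detect_modules(tom, network_params())
  expect_equal(length(unique(part)), 2)
  expect_false(KN_UNASSIGNED %in% part)
  expect_equal(unname(table(part)[unique(part)]), c(40L, 40L),
               ignore_attr = TRUE)

  # determinism and gene-order invariance (up to label names)
  cfg <- small_cfg(seed = 10)
  sim <- simulate_expression(cfg)
  vst <- vst_normalize(sim$counts,
                       filter_genes(compute_tpm(sim$counts, sim$annot))$genes)
  tomv <- build_tom(vst, 4)
  p1 <- detect_modules(tomv, network_params(min_module_size = 20), expr = vst)
  p2 <- detect_modules(tomv, network_params(min_module_size = 20), expr = vst)
  expect_identical(p1, p2)
  perm <- sample(nrow(vst))
  vp <- vst[perm, ]
  p3 <- detect_modules(build_tom(vp, 4),
                       network_params(min_module_size = 20), expr = vp)
  expect_equal(adjusted_rand_index(p1[names(p3)], p3), 1)
})

test_that("eigengenes equal the eigendecomposition oracle", {
  cfg <- small_cfg(seed = 12)
  sim <- simulate_expression(cfg)
  vst <- vst_normalize(sim$counts)
  part <- sim$truth$modules
  class(part) <- "module_partition"
  me <- compute_eigengenes(vst, part)
  for (m in rownames(me)) {
    members <- names(part)[part == m]
    xs <- t(scale(t(vst[members, ])))
    ev <- eigen(crossprod(xs))            # sample-space covariance oracle
    v1 <- ev$vectors[, 1]
    expect_equal(abs(sum(me[m, ] * v1)), 1, tolerance = 1e-9)
    expect_equal(attr(me, "var_explained")[[m]],
                 ev$values[1] / sum(ev$values), tolerance = 1e-9)
    # maximal-variance direction: eigengene variance beats random unit dirs
    set.seed(4)
    best <- ev$values[1]
    for (k in 1:25) {
      u <- rnorm(ncol(xs)); u <- u / sqrt(sum(u^2))
      expect_lte(sum((xs %*% u)^2), best + 1e-8)
    }
    # orientation: mean correlation with members is non-negative
    expect_gte(mean(cor(t(vst[members, ]), me[m, ])), 0)
  }

  # module of identical genes: eigengene is the z-scored common profile
  prof <- rnorm(10)
  same <- rbind(a = prof, b = prof, c = prof)
  colnames(same) <- paste0("s", 1:10)
  p <- structure(setNames(rep("mod", 3), rownames(same)),
                 class = "module_partition")
  me1 <- compute_eigengenes(same, p)
  z <- scale(prof)[, 1] / sqrt(sum(scale(prof)^2))
  expect_equal(abs(cor(me1["mod", ], z)), 1, tolerance = 1e-9)
  expect_equal(attr(me1, "var_explained")[["mod"]], 1, tolerance = 1e-9)

  # flipping the sign of every member flips the eigengene
  me2 <- compute_eigengenes(-same, p)
  expect_equal(me2["mod", ], -me1["mod", ], tolerance = 1e-9)
})

test_that("merge_modules follows the greedy eigengene procedure", {
  # two modules with identical eigengene profiles merge
  prof <- rnorm(8)
  e <- rbind(a1 = prof + rnorm(8, 0, 1e-3), a2 = prof + rnorm(8, 0, 1e-3),
             b1 = prof + rnorm(8, 0, 1e-3), b2 = prof + rnorm(8, 0, 1e-3))
  colnames(e) <- paste0("s", 1:8)
  p <- structure(setNames(c("mA", "mA", "mB", "mB"), rownames(e)),
                 class = "module_partition")
  expect_equal(length(unique(merge_modules(e, p, 0.9))), 1)

  # threshold 1: no merges ever
  expect_identical(sort(unique(merge_modules(e, p, 1))), c("mA", "mB"))

  # three near-identical modules collapse to one after two greedy merges
  e3 <- rbind(e, c1 = prof + rnorm(8, 0, 1e-3), c2 = prof + rnorm(8, 0, 1e-3))
  p3 <- structure(setNames(c("mA", "mA", "mB", "mB", "mC", "mC"),
                           rownames(e3)), class = "module_partition")
  expect_equal(length(unique(merge_modules(e3, p3, 0.9))), 1)
})

test_that("hub genes satisfy both thresholds and match brute force", {
  # 61 perfectly inter-correlated genes at beta = 1: kIM = 60 for all
  prof <- rnorm(12)
  e <- matrix(rep(prof, each = 61), 61, 12) *
    matrix(runif(61, 0.5, 2), 61, 12)
  rownames(e) <- sprintf("g%02d", 1:61)
  colnames(e) <- paste0("s", 1:12)
  p <- structure(setNames(rep("mod", 61), rownames(e)),
                 class = "module_partition")
  hub <- call_hub_genes(e, p, list(tr = prof), beta = 1)
  expect_equal(nrow(hub), 61)
  expect_equal(hub$kIM, rep(60, 61), tolerance = 1e-9)

  # gene uncorrelated with every trait is excluded regardless of kIM
  hub0 <- call_hub_genes(e, p, list(tr = rnorm(12) * 0 + c(1, rep(0, 11))),
                         beta = 1, gs_threshold = 0.999)
  expect_equal(nrow(hub0), 0)

  # synthetic data: equals an independent brute-force recomputation
  cfg <- small_cfg(seed = 13)
  sim <- simulate_expression(cfg)
  vst <- vst_normalize(sim$counts)
  part <- sim$truth$modules
  class(part) <- "module_partition"
  traits <- list(K_Post = as.numeric(sim$sample_info$state == "K_Post"),
                 BHBA = sim$sample_info$BHBA)
  hub2 <- call_hub_genes(vst, part, traits, beta = 4, k_threshold = 2,
                         gs_threshold = 0.3)
  expected <- character(0)
  for (m in setdiff(unique(part), KN_UNASSIGNED)) {
    for (g in names(part)[part == m]) {
      others <- setdiff(names(part)[part == m], g)
      kim <- sum(abs(cor(vst[g, ], t(vst[others, ])))^4)
      gs <- max(abs(cor(vst[g, ], traits$K_Post)),
                abs(cor(vst[g, ], traits$BHBA)))
      if (kim > 2 && gs > 0.3) expected <- c(expected, g)
    }
  }
  expect_setequal(hub2$gene, expected)
})
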