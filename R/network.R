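# Weighted gene co-expression network: soft-threshold selection, adjacency
# and topological overlap, hierarchical module detection with size
# dissolution and eigengene-based reassignment, module eigengenes, eigengene
# merging, and hub-gene calling. The network is unsigned
# (a_ij = |cor|^beta) by default.

#' Network-stage parameters
#'
#' @param soft_power integer in 1..20 or `"auto"` (scale-free criterion).
#' @param min_module_size smallest branch kept as a module (default 30).
#' @param merge_cor_threshold eigengene correlation above which modules are
#'   merged (default 0.9).
#' @param cut_height fraction of the maximum merge height below which
#'   branches may seed modules (default 0.99).
#' @param scale_free_target_r2 model-fit R^2 the soft power must reach.
#' @param reassign_cor_threshold minimum |cor| between a gene and a module
#'   eigengene for (re)assignment during refinement (default 0.2); the
#'   correlation must additionally be BH-significant (q < 0.05) over the
#'   gene x module grid so that small-sample noise correlations do not
#'   flood modules.
#' @return list with class `network_params`.
#' @export
network_params <- function(soft_power = "auto", min_module_size = 30,
                           merge_cor_threshold = 0.9, cut_height = 0.99,
                           scale_free_target_r2 = 0.8,
                           reassign_cor_threshold = 0.2) {
  if (!identical(soft_power, "auto")) {
    soft_power <- as.integer(soft_power)
    stopifnot(soft_power >= 1, soft_power <= 20)
  }
  stopifnot(merge_cor_threshold > 0, merge_cor_threshold <= 1,
            cut_height > 0, cut_height <= 1)
  structure(list(soft_power = soft_power, min_module_size = min_module_size,
                 merge_cor_threshold = merge_cor_threshold,
                 cut_height = cut_height,
                 scale_free_target_r2 = scale_free_target_r2,
                 reassign_cor_threshold = reassign_cor_threshold),
            class = "network_params")
}

# Scale-free topology fit: R^2 of log10(density) ~ log10(mean k) over
# connectivity quantile bins (equal occupancy; density = frequency/width,
# so unequal widths are handled correctly). Counted only when the fitted
# slope is negative (a positive slope is not scale-free behaviour).
# Quantile bins give a far smoother R^2-vs-beta profile than equal-width
# bins when the connectivity distribution is heavy-tailed.
scale_free_fit_r2 <- function(k, n_bins = 10) {
  k <- k[k > 0]
  breaks <- unique(stats::quantile(k, seq(0, 1, length.out = n_bins + 1),
                                   names = FALSE))
  if (length(breaks) < 4) stop("fewer than 3 populated connectivity bins")
  bin <- cut(k, breaks, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mean_k <- tapply(k, bin, mean)
  width <- diff(breaks)
  ok <- !is.na(freq) & freq > 0 & width > 0
  if (sum(ok) < 3) stop("fewer than 3 populated connectivity bins")
  x <- log10(mean_k[ok])
  y <- log10((freq[ok] / width[ok]) / sum(freq[ok]))
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  if (stats::coef(fit)[2] > 0) r2 <- 0
  unname(r2)
}

#' Select the soft-thresholding power
#'
#' Smallest beta in 1..20 whose scale-free fit R^2 reaches
#' `scale_free_target_r2`; falls back to 6 with a warning if none does.
#'
#' @param expr gene-by-sample expression matrix (vst scale).
#' @param params [network_params()].
#' @return list: `beta`, `fit_table` (beta, r2, mean_k).
#' @export
select_soft_power <- function(expr, params = network_params()) {
  if (!identical(params$soft_power, "auto"))
    return(list(beta = params$soft_power, fit_table = NULL))
  if (ncol(expr) < 8)
    warning("fewer than 8 samples; soft-power selection is unstable")
  a1 <- abs(stats::cor(t(expr)))
  diag(a1) <- 0
  fit <- data.frame(beta = 1:20, r2 = NA_real_, mean_k = NA_real_)
  beta_sel <- NA_integer_
  ak <- a1
  for (b in 1:20) {
    if (b > 1) ak <- ak * a1
    k <- rowSums(ak)
    fit$r2[b] <- scale_free_fit_r2(k)
    fit$mean_k[b] <- mean(k)
    if (is.na(beta_sel) && fit$r2[b] >= params$scale_free_target_r2) {
      beta_sel <- b
      break
    }
  }
  if (is.na(beta_sel)) {
    warning("no power in 1..20 reached scale-free R^2 >= ",
            params$scale_free_target_r2, "; falling back to beta = 6")
    beta_sel <- 6L
  }
  list(beta = beta_sel, fit_table = fit[!is.na(fit$r2), ])
}

#' Adjacency and topological overlap matrix
#'
#' `a_ij = |cor(x_i, x_j)|^beta`;
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_{u != i} a_iu`, diagonal fixed at 1.
#'
#' @param expr gene-by-sample expression matrix.
#' @param beta soft-thresholding power.
#' @return symmetric TOM in \[0, 1\] with unit diagonal; the adjacency is
#'   attached as attribute `"adjacency"`.
#' @export
build_tom <- function(expr, beta) {
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) stop("zero-variance gene(s): ",
                        paste(utils::head(rownames(expr)[v == 0], 5), collapse = ", "))
  a <- abs(stats::cor(t(expr)))^beta
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom <- (tom + t(tom)) / 2            # enforce exact symmetry
  attr(tom, "adjacency") <- a
  tom
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, followed by a
#' deterministic variant of the dynamic hybrid cut. Module seeds are the
#' "first-crossing" branches of the dendrogram: the minimal merge nodes
#' whose subtree first reaches `min_module_size` (both children smaller),
#' restricted to merge heights below `cut_height` times the maximum merge
#' height. First-crossing nodes are provably disjoint, so every gene
#' belongs to at most one seed; distinct modules that cohere at different
#' heights each get their own seed, which a single static cut cannot
#' provide. Everything outside a seed starts as "unassigned". If `expr` is
#' supplied, membership is then refined iteratively: module eigengenes are
#' computed and every gene is (re)assigned to the module whose eigengene
#' it correlates with most, provided |cor| exceeds
#' `reassign_cor_threshold` and the correlation is BH-significant
#' (q < 0.05) over the gene x module grid; genes failing either fall back
#' to "unassigned", and modules shrinking below `min_module_size`
#' dissolve. This purges chance-correlated bridging genes swept into
#' branches and recovers genuine members from dissolved ones. Over-split
#' seeds of one true module survive refinement as near-duplicate
#' eigengenes and are collapsed by [merge_modules()]. Modules are labeled
#' with color-style names in decreasing size order; the whole procedure is
#' deterministic.
#'
#' @param tom topological overlap matrix from [build_tom()].
#' @param params [network_params()].
#' @param expr optional expression matrix enabling refinement.
#' @return named character vector gene -> module label (class
#'   `module_partition`), with attribute `merge_heights`.
#' @export
detect_modules <- function(tom, params = network_params(), expr = NULL) {
  genes <- rownames(tom)
  n <- length(genes)
  if (n < params$min_module_size) {
    warning("fewer genes than min_module_size; everything unassigned")
    part <- stats::setNames(rep(KN_UNASSIGNED, n), genes)
    class(part) <- "module_partition"
    return(part)
  }
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  lab <- first_crossing_seeds(hc, params$min_module_size,
                              params$cut_height * max(hc$height))
  names(lab) <- genes

  if (!is.null(expr)) lab <- refine_membership(lab, expr, params)

  part <- relabel_modules(lab)
  attr(part, "merge_heights") <- hc$height
  class(part) <- "module_partition"
  part
}

# Branch-seeding walk over the merge tree (heights are monotone under
# average linkage). A subtree becomes a module seed when its size first
# reaches min_size below h_max ("first crossing"; such nodes are disjoint
# by construction). A uniquely-seeded branch absorbs an unseeded sister
# below h_max (branch growth), but two seeded branches never fuse here --
# collisions are left for the eigengene merge step, which is what keeps
# distinct modules from being welded together by bridging genes. Leaves
# outside any seed end up "unassigned".
first_crossing_seeds <- function(hc, min_size, h_max) {
  nmerge <- nrow(hc$merge)
  size <- integer(nmerge)
  nseeds <- integer(nmerge)             # seeds contained in subtree
  seed_id <- integer(nmerge)            # node id when nseeds == 1
  members <- vector("list", nmerge)     # leaf indices per node
  lab <- rep(KN_UNASSIGNED, nmerge + 1L)
  for (i in seq_len(nmerge)) {
    ch <- hc$merge[i, ]
    s1 <- if (ch[1] < 0) 1L else size[ch[1]]
    s2 <- if (ch[2] < 0) 1L else size[ch[2]]
    size[i] <- s1 + s2
    m1 <- if (ch[1] < 0) -ch[1] else members[[ch[1]]]
    m2 <- if (ch[2] < 0) -ch[2] else members[[ch[2]]]
    members[[i]] <- c(m1, m2)
    n1 <- if (ch[1] < 0) 0L else nseeds[ch[1]]
    n2 <- if (ch[2] < 0) 0L else nseeds[ch[2]]
    nseeds[i] <- n1 + n2
    ok_h <- hc$height[i] <= h_max
    if (nseeds[i] == 0L && size[i] >= min_size && ok_h) {
      seed_id[i] <- i                   # first crossing: new seed
      nseeds[i] <- 1L
      lab[members[[i]]] <- paste0("seed", i)
    } else if (ok_h && n1 == 1L && n2 == 0L) {
      seed_id[i] <- seed_id[ch[1]]      # grow the branch over the sister
      lab[m2] <- paste0("seed", seed_id[i])
    } else if (ok_h && n2 == 1L && n1 == 0L) {
      seed_id[i] <- seed_id[ch[2]]
      lab[m1] <- paste0("seed", seed_id[i])
    } else if (nseeds[i] == 1L) {
      seed_id[i] <- max(if (ch[1] < 0) 0L else seed_id[ch[1]],
                        if (ch[2] < 0) 0L else seed_id[ch[2]])
    }
  }
  lab
}

# Iterative eigengene-based membership refinement: every gene goes to its
# best-correlated module eigengene when that correlation is both above the
# threshold and BH-significant, otherwise to "unassigned"; undersized
# modules dissolve. Runs until stable (max 20 rounds), deterministically.
refine_membership <- function(lab, expr, params) {
  n_samp <- ncol(expr)
  for (iter in 1:20) {
    mods <- sort(setdiff(unique(lab), KN_UNASSIGNED))
    if (!length(mods)) break
    me <- eigengene_matrix(expr, lab, modules = mods)
    r <- stats::cor(t(expr), t(me))                     # genes x modules
    p <- cor_pvalue(r, n_samp)
    q <- matrix(bh_fdr(as.vector(p)), nrow(p), ncol(p), dimnames = dimnames(p))
    best <- max.col(abs(r), ties.method = "first")
    best_r <- abs(r)[cbind(seq_len(nrow(r)), best)]
    best_q <- q[cbind(seq_len(nrow(r)), best)]
    ok <- best_r > params$reassign_cor_threshold & best_q < 0.05
    new_lab <- ifelse(ok, mods[best], KN_UNASSIGNED)
    names(new_lab) <- rownames(expr)
    sizes <- table(factor(new_lab, levels = mods))
    dead <- names(sizes)[sizes < params$min_module_size]
    new_lab[new_lab %in% dead] <- KN_UNASSIGNED
    if (identical(unname(new_lab), unname(lab[names(new_lab)]))) {
      lab <- new_lab
      break
    }
    lab <- new_lab
  }
  lab
}

# deterministic color labels in decreasing size order (ties: old label)
relabel_modules <- function(lab) {
  mods <- setdiff(unique(lab), KN_UNASSIGNED)
  if (!length(mods)) return(lab)
  sizes <- table(factor(lab[lab != KN_UNASSIGNED], levels = mods))
  ord <- mods[order(-as.integer(sizes), mods)]
  newnames <- stats::setNames(kn_module_palette(length(ord)), ord)
  out <- ifelse(lab == KN_UNASSIGNED, KN_UNASSIGNED, newnames[lab])
  stats::setNames(out, names(lab))
}

# first right singular vector per module, unit norm over samples, sign
# oriented so the mean correlation with member genes is >= 0.
eigengene_matrix <- function(expr, partition, modules = NULL,
                             include_unassigned = FALSE) {
  if (is.null(modules)) {
    modules <- setdiff(sort(unique(partition)), KN_UNASSIGNED)
    if (include_unassigned && sum(partition == KN_UNASSIGNED) >= 2)
      modules <- c(modules, KN_UNASSIGNED)
  }
  n <- ncol(expr)
  me <- matrix(NA_real_, length(modules), n,
               dimnames = list(modules, colnames(expr)))
  ve <- stats::setNames(numeric(length(modules)), modules)
  for (m in modules) {
    members <- names(partition)[partition == m]
    if (length(members) < 2) stop("module ", m, " has fewer than 2 genes")
    x <- expr[members, , drop = FALSE]
    xs <- t(scale(t(x)))                   # z-score each gene across samples
    if (any(!is.finite(xs))) stop("zero-variance gene in module ", m)
    sv <- svd(xs, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (mean(stats::cor(t(x), e)) < 0) e <- -e
    me[m, ] <- e
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  attr(me, "var_explained") <- ve
  me
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' (per-gene z-scored) expression submatrix: the unit-norm sample profile
#' explaining the largest fraction of member-gene variance. Sign is
#' oriented so the mean correlation with member genes is non-negative.
#'
#' @param expr gene-by-sample expression matrix.
#' @param partition `module_partition`.
#' @param include_unassigned also compute the leftover module's eigengene.
#' @return module-by-sample matrix with attribute `var_explained`.
#' @export
compute_eigengenes <- function(expr, partition, include_unassigned = FALSE) {
  if (ncol(expr) < 2) stop("need >= 2 samples")
  eigengene_matrix(expr, partition, include_unassigned = include_unassigned)
}

#' Merge modules with highly correlated eigengenes
#'
#' Greedy: while the highest eigengene correlation between two modules
#' exceeds `threshold`, merge that pair (ties broken lexicographically by
#' label pair), recompute eigengenes, repeat. The merged module keeps the
#' label of the larger member (lexicographic on ties).
#'
#' @param expr expression matrix (for eigengene recomputation).
#' @param partition `module_partition`.
#' @param threshold merge correlation threshold in (0, 1\].
#' @return merged `module_partition`.
#' @export
merge_modules <- function(expr, partition, threshold = 0.9) {
  part <- partition
  repeat {
    mods <- setdiff(sort(unique(part)), KN_UNASSIGNED)
    if (length(mods) < 2) break
    me <- eigengene_matrix(expr, part, modules = mods)
    cc <- stats::cor(t(me))
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)
    if (max(cc) <= threshold || threshold >= 1) break
    # deterministic pick: lexicographically first (rowname, colname) pair
    pair <- best[order(rownames(cc)[best[, 1]], colnames(cc)[best[, 2]]), ,
                 drop = FALSE][1, ]
    a <- mods[pair[1]]; b <- mods[pair[2]]
    na <- sum(part == a); nb <- sum(part == b)
    keep <- if (na > nb) a else if (nb > na) b else min(a, b)
    drop <- setdiff(c(a, b), keep)
    part[part == drop] <- keep
  }
  class(part) <- "module_partition"
  part
}

#' Hub genes: intramodular connectivity and gene significance
#'
#' `kIM_i` is the sum of gene i's adjacency (`|cor|^beta`) to the other
#' genes of its module; gene significance for a trait is `|cor(x_i, trait)|`.
#' Genes with `kIM > k_threshold` and `GS > gs_threshold` for at least one
#' supplied trait are reported.
#'
#' @param expr gene-by-sample expression matrix.
#' @param partition `module_partition`.
#' @param traits named list (or matrix columns) of numeric sample vectors.
#' @param beta soft power used for the adjacency.
#' @param k_threshold,gs_threshold hub criteria (defaults 30 and 0.2).
#' @return data.frame: gene, module, kIM, one GS column per trait, is_hub.
#' @export
call_hub_genes <- function(expr, partition, traits, beta,
                           k_threshold = 30, gs_threshold = 0.2) {
  if (is.matrix(traits)) traits <- as.data.frame(traits)
  traits <- lapply(traits, as.numeric)
  genes <- rownames(expr)
  part <- partition[genes]
  kim <- stats::setNames(numeric(length(genes)), genes)
  for (m in setdiff(unique(part), KN_UNASSIGNED)) {
    members <- genes[part == m]
    if (length(members) < 2) next
    a <- abs(stats::cor(t(expr[members, , drop = FALSE])))^beta
    diag(a) <- 0
    kim[members] <- rowSums(a)
  }
  gs <- vapply(traits, function(tr) abs(stats::cor(t(expr), tr))[, 1],
               numeric(length(genes)))
  gs <- matrix(gs, nrow = length(genes),
               dimnames = list(genes, names(traits)))
  is_hub <- kim > k_threshold &
    apply(gs > gs_threshold, 1, any) & part != KN_UNASSIGNED
  out <- data.frame(gene = genes, module = unname(part), kIM = unname(kim),
                    gs, is_hub = unname(is_hub), check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[out$is_hub, , drop = FALSE]
}
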