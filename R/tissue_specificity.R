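# Tissue-specificity scoring: the +1/-1 regression t-statistic per
# gene x tissue, top-fraction tissue-specific gene sets, and the generic
# hypergeometric over-representation engine (also used for GO-style
# user-supplied gene sets).

#' Construct a tissue expression panel
#'
#' @param expr gene-by-sample expression matrix (log scale recommended).
#' @param labels tissue label per sample (length = ncol(expr)).
#' @return list with class `tissue_panel`: `expr`, `tissue` (factor).
#' @export
tissue_panel <- function(expr, labels) {
  stopifnot(is.matrix(expr), length(labels) == ncol(expr))
  tissue <- factor(labels)
  if (nlevels(tissue) < 2) stop("need at least 2 tissues")
  if (any(table(tissue) < 2)) stop("every tissue needs >= 2 samples")
  structure(list(expr = expr, tissue = tissue), class = "tissue_panel")
}

#' Tissue-specificity t-statistic
#'
#' Slope t-statistic of the simple regression of a gene's expression on a
#' +1/-1 code (target tissue = +1, all other samples = -1); algebraically
#' identical to the pooled-variance two-sample t between target and rest.
#' Zero residual variance returns a signed infinity with a warning; a gene
#' constant everywhere returns 0.
#'
#' @param panel `tissue_panel`.
#' @param tissue target tissue label.
#' @param genes optional gene subset (default all).
#' @return named numeric vector of t-statistics (one per gene).
#' @export
tissue_t_statistic <- function(panel, tissue, genes = NULL) {
  stopifnot(inherits(panel, "tissue_panel"))
  if (!tissue %in% levels(panel$tissue)) stop("unknown tissue: ", tissue)
  x <- ifelse(panel$tissue == tissue, 1, -1)
  e <- panel$expr
  if (!is.null(genes)) e <- e[genes, , drop = FALSE]
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  xc <- x - mean(x)
  beta <- (e %*% xc) / sxx
  fitted_ss <- as.vector(beta)^2 * sxx
  tot_ss <- rowSums((e - rowMeans(e))^2)
  rss <- pmax(tot_ss - fitted_ss, 0)
  sigma2 <- rss / (n - 2)
  tstat <- as.vector(beta) / sqrt(sigma2 / sxx)
  zero_sig <- sigma2 <= .Machine$double.eps * pmax(tot_ss, 1)
  if (any(zero_sig & as.vector(beta) != 0)) {
    warning("zero residual variance for ",
            sum(zero_sig & as.vector(beta) != 0), " gene(s); t set to +/-Inf")
    tstat[zero_sig] <- sign(as.vector(beta)[zero_sig]) * Inf
  }
  tstat[as.vector(beta) == 0 & zero_sig] <- 0
  tstat[tot_ss == 0] <- 0                # constant gene everywhere
  stats::setNames(tstat, rownames(e))
}

#' Top-fraction tissue-specific gene sets
#'
#' Per tissue, genes are ranked by t-statistic descending (ties, and
#' non-finite t, resolved by gene id; non-finite ranked last) and the top
#' `ceil(fraction * n_genes)` form the tissue-specific set.
#'
#' @param panel `tissue_panel`.
#' @param fraction top fraction to keep (default 0.05).
#' @return list with class `tissue_specific_sets`: `sets` (tissue -> gene
#'   ids), `fraction`, `t_matrix` (gene x tissue t-statistics).
#' @export
top_fraction_sets <- function(panel, fraction = 0.05) {
  stopifnot(fraction > 0, fraction <= 1)
  tissues <- levels(panel$tissue)
  tmat <- vapply(tissues, function(ts) tissue_t_statistic(panel, ts),
                 numeric(nrow(panel$expr)))
  rownames(tmat) <- rownames(panel$expr)
  k <- ceiling(fraction * nrow(tmat))
  sets <- lapply(tissues, function(ts) {
    t_ord <- tmat[, ts]
    t_ord[!is.finite(t_ord) & t_ord > 0] <- Inf   # +Inf sorts first
    t_ord[is.na(t_ord)] <- -Inf
    ord <- order(-t_ord, rownames(tmat))
    rownames(tmat)[ord[seq_len(k)]]
  })
  names(sets) <- tissues
  structure(list(sets = sets, fraction = fraction, t_matrix = tmat),
            class = "tissue_specific_sets")
}

#' Upper-tail hypergeometric over-representation test
#'
#' `p = P(X >= overlap)` where X is the overlap of a random draw of
#' `|module|` genes from the universe containing `|set|` successes. The
#' same engine serves GO-style enrichment with user-supplied gene sets.
#'
#' @param module_genes,set_genes character vectors, subsets of `universe`.
#' @param universe character vector of all scoreable genes.
#' @return list: `overlap`, `pvalue`, `n_universe`, `n_set`, `n_module`.
#' @export
hypergeom_enrichment <- function(module_genes, set_genes, universe) {
  if (!length(universe)) stop("empty universe")
  module_genes <- intersect(module_genes, universe)
  set_genes <- intersect(set_genes, universe)
  ov <- length(intersect(module_genes, set_genes))
  p <- stats::phyper(ov - 1, length(set_genes),
                     length(universe) - length(set_genes),
                     length(module_genes), lower.tail = FALSE)
  list(overlap = ov, pvalue = p, n_universe = length(universe),
       n_set = length(set_genes), n_module = length(module_genes))
}

#' Module x tissue (or gene-set) enrichment grid
#'
#' Hypergeometric test of every module against every set, BH FDR over the
#' grid.
#'
#' @param partition `module_partition`.
#' @param sets named list of gene sets (e.g. `top_fraction_sets()$sets` or
#'   GMT-derived sets).
#' @param universe gene universe; defaults to the partitioned genes.
#' @param include_unassigned test the leftover module too.
#' @return data.frame: module, set, overlap, n_module, n_set, pvalue, fdr.
#' @export
module_set_enrichment <- function(partition, sets, universe = names(partition),
                                  include_unassigned = FALSE) {
  mods <- sort(unique(unname(partition)))
  if (!include_unassigned) mods <- setdiff(mods, KN_UNASSIGNED)
  grid <- expand.grid(module = mods, set = names(sets),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    h <- hypergeom_enrichment(names(partition)[partition == grid$module[i]],
                              sets[[grid$set[i]]], universe)
    data.frame(module = grid$module[i], set = grid$set[i],
               overlap = h$overlap, n_module = h$n_module, n_set = h$n_set,
               pvalue = h$pvalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- bh_fdr(out$pvalue)
  out
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated, first field the set name,
#' second a description (ignored), remaining fields gene ids.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(names(sets))) stop("duplicate set names in ", path)
  sets
}
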