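# GWAS signal enrichment of gene modules: sum of squared marker effects
# (T_sum) over SNPs within +/-20 kb of a module's genes, a circular
# genotype permutation null (the genome-ordered effect vector is rotated by
# a random offset over one genome-wide circle), BH FDR across the
# module x trait grid, and candidate-gene extraction.

## ---- interval plumbing (0-based half-open) --------------------------------

#' Flank-extended gene windows
#'
#' Gene bodies extended by `flank` bp on both sides, clipped at 0; intervals
#' are 0-based half-open. Overlapping windows are merged per chromosome.
#'
#' @param annot `gene_annotation` rows to window.
#' @param flank flank size in bp (default 20000).
#' @param merge merge overlapping windows (default TRUE).
#' @return data.frame: chrom, start, end (plus gene_id when `merge = FALSE`).
#' @export
gene_windows <- function(annot, flank = 20000, merge = TRUE) {
  w <- data.frame(chrom = annot$chrom,
                  start = pmax(0, annot$start - flank),
                  end = annot$end + flank,
                  gene_id = annot$gene_id, stringsAsFactors = FALSE)
  if (!merge) return(w)
  out <- lapply(split(w, w$chrom), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1, end = d$end))
    data.frame(chrom = d$chrom[1], start = IRanges::start(ir) - 1,
               end = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Membership of SNPs in genomic windows
#'
#' Positions are 1-based (as read from GWAS summary files); windows are
#' 0-based half-open, so a SNP at 1-based position `pos` lies inside
#' `[s, e)` iff `s <= pos - 1 < e`.
#'
#' @param chrom,pos SNP chromosome names and 1-based positions.
#' @param windows data.frame with chrom, start, end (0-based half-open).
#' @return logical vector, one entry per SNP.
#' @export
snps_in_windows <- function(chrom, pos, windows) {
  hit <- logical(length(pos))
  for (ch in unique(windows$chrom)) {
    wc <- windows[windows$chrom == ch, , drop = FALSE]
    sel <- which(chrom == ch)
    if (!length(sel)) next
    q <- IRanges::IRanges(start = pos[sel], width = 1)
    s <- IRanges::IRanges(start = wc$start + 1, end = wc$end)
    hit[sel] <- IRanges::overlapsAny(q, s)
  }
  hit
}

#' Map SNPs to module windows
#'
#' A SNP belongs to a module iff its position falls inside any
#' flank-extended window of that module's genes; a SNP may belong to
#' several modules. Requires the two files to agree on chromosome naming.
#'
#' @param gwas genome-ordered `gwas_summary`.
#' @param annot `gene_annotation`.
#' @param partition `module_partition`.
#' @param flank flank size in bp.
#' @param include_unassigned also map the reserved "unassigned" module.
#' @return named list: module -> integer row indices into `gwas`.
#' @export
map_snps_to_modules <- function(gwas, annot, partition, flank = 20000,
                                include_unassigned = TRUE) {
  shared <- intersect(unique(gwas$chrom), unique(annot$chrom))
  if (!length(shared))
    stop("no shared chromosome names; gwas has {",
         paste(utils::head(sort(unique(gwas$chrom)), 5), collapse = ", "),
         "} vs annotation {",
         paste(utils::head(sort(unique(annot$chrom)), 5), collapse = ", "), "}")
  mods <- sort(unique(unname(partition)))
  if (!include_unassigned) mods <- setdiff(mods, KN_UNASSIGNED)
  out <- lapply(mods, function(m) {
    genes_m <- names(partition)[partition == m]
    ann <- annot[annot$gene_id %in% genes_m, , drop = FALSE]
    if (!nrow(ann)) return(integer(0))
    win <- gene_windows(ann, flank)
    which(snps_in_windows(gwas$chrom, gwas$pos, win))
  })
  names(out) <- mods
  out
}

#' Module windows table for all modules (BED-exportable)
#'
#' @inheritParams map_snps_to_modules
#' @return data.frame: module, chrom, start, end (merged per module).
#' @export
module_windows <- function(annot, partition, flank = 20000) {
  mods <- sort(unique(unname(partition)))
  out <- lapply(mods, function(m) {
    genes_m <- names(partition)[partition == m]
    ann <- annot[annot$gene_id %in% genes_m, , drop = FALSE]
    if (!nrow(ann)) return(NULL)
    cbind(module = m, gene_windows(ann, flank))
  })
  do.call(rbind, out)
}

## ---- the statistic --------------------------------------------------------

#' Sum of squared marker effects over a SNP set
#'
#' @param effects_b numeric vector of marker effect estimates.
#' @param snp_idx integer indices of the SNPs in the tested module.
#' @return `sum(effects_b[snp_idx]^2)`.
#' @export
t_sum <- function(effects_b, snp_idx) {
  stopifnot(all(is.finite(effects_b)))
  sum(effects_b[snp_idx]^2)
}

#' Circular permutation test for one module
#'
#' All m SNPs are ordered by (chrom, pos) into one genome-wide circle
#' (chromosomes concatenated in sorted name order). Each permutation draws
#' an offset k uniform on 1..m-1 and rotates the effect vector by k; T_sum
#' is recomputed on the fixed module index set, which preserves local
#' effect ordering (and the effect multiset exactly) while breaking the
#' SNP-to-gene assignment. The empirical p uses the add-one estimator
#' `(1 + #(T_perm >= T_obs)) / (1 + n_perm)`, with ">=" (conservative).
#' `exhaustive = TRUE` enumerates all m-1 rotations instead of sampling.
#'
#' @param gwas genome-ordered `gwas_summary` (or a bare numeric effect
#'   vector already in genome order).
#' @param snp_idx integer indices (genome order) of the module's SNPs.
#' @param n_perm number of sampled offsets (default 10000).
#' @param seed RNG seed for offset sampling.
#' @param exhaustive enumerate all rotations (p over m-1 offsets).
#' @param check_multiset assert, per draw, that the rotated effect vector is
#'   a permutation of the original (slow; for tests).
#' @return list: `n_snps`, `t_obs`, `n_perm`, `n_greater_equal`,
#'   `empirical_p`, `seed`, `exhaustive`.
#' @export
circular_permutation_test <- function(gwas, snp_idx, n_perm = 10000,
                                      seed = NULL, exhaustive = FALSE,
                                      check_multiset = FALSE) {
  b <- if (is.numeric(gwas)) gwas else gwas$effect_b
  m <- length(b)
  if (m < 2) stop("need at least 2 SNPs genome-wide")
  if (!length(snp_idx))
    return(list(n_snps = 0L, t_obs = NA_real_, n_perm = 0L,
                n_greater_equal = NA_integer_, empirical_p = NA_real_,
                seed = seed, exhaustive = exhaustive))
  b2 <- b^2
  t_obs <- sum(b2[snp_idx])
  pos0 <- snp_idx - 1L                   # 0-based positions on the circle
  offsets <- if (exhaustive) seq_len(m - 1L) else {
    if (!is.null(seed)) set.seed(seed)
    sample.int(m - 1L, n_perm, replace = TRUE)
  }
  tol <- 1e-9 * max(t_obs, 1)            # guard fp noise in the >= count
  cnt <- 0L
  chunk <- max(1L, floor(2e6 / length(pos0)))
  for (i in seq(1, length(offsets), by = chunk)) {
    ks <- offsets[i:min(i + chunk - 1L, length(offsets))]
    idx <- (outer(pos0, ks, "+") %% m) + 1L
    tp <- colSums(matrix(b2[idx], nrow = length(pos0)))
    if (check_multiset) {
      for (k in ks) {
        rot <- b[((seq_len(m) - 1L + k) %% m) + 1L]
        stopifnot(identical(sort(rot), sort(b)))
      }
    }
    cnt <- cnt + sum(tp >= t_obs - tol)
  }
  n_eff <- length(offsets)
  list(n_snps = length(snp_idx), t_obs = t_obs, n_perm = n_eff,
       n_greater_equal = cnt, empirical_p = (1 + cnt) / (1 + n_eff),
       seed = seed, exhaustive = exhaustive)
}

#' GWAS enrichment of every module for every trait
#'
#' One circular permutation test per (module, trait); BH FDR pooled over the
#' full grid; cells with FDR < 0.05 are flagged. Deterministic for a fixed
#' seed: per-cell seeds are derived from `seed` in (trait, module) sort
#' order.
#'
#' @param gwas_by_trait named list of genome-ordered `gwas_summary` objects.
#' @param partition `module_partition`.
#' @param annot `gene_annotation`.
#' @param n_perm permutations per cell (default 10000).
#' @param seed base RNG seed.
#' @param flank window flank in bp.
#' @param include_unassigned test the leftover module too (default TRUE).
#' @return data.frame: module, trait, n_snps, t_obs, n_perm,
#'   n_greater_equal, empirical_p, fdr, significant, seed.
#' @export
enrich_all <- function(gwas_by_trait, partition, annot, n_perm = 10000,
                       seed = 1, flank = 20000, include_unassigned = TRUE) {
  stopifnot(is.list(gwas_by_trait), !is.null(names(gwas_by_trait)))
  traits <- sort(names(gwas_by_trait))
  rows <- list()
  cell <- 0L
  for (tr in traits) {
    gw <- gwas_by_trait[[tr]]
    idx_by_mod <- map_snps_to_modules(gw, annot, partition, flank,
                                      include_unassigned = include_unassigned)
    for (m in names(idx_by_mod)) {
      cell <- cell + 1L
      cell_seed <- (as.integer(seed) + 7919L * cell) %% .Machine$integer.max
      res <- circular_permutation_test(gw, idx_by_mod[[m]], n_perm = n_perm,
                                       seed = cell_seed)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, trait = tr, n_snps = res$n_snps, t_obs = res$t_obs,
        n_perm = res$n_perm, n_greater_equal = res$n_greater_equal,
        empirical_p = res$empirical_p, seed = cell_seed,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$empirical_p)
  out$significant <- !is.na(out$fdr) & out$fdr < 0.05
  out
}

#' Candidate genes within significant modules
#'
#' For each gene of a significant module, the top SNP is the minimum-p SNP
#' within the gene's +/-`flank` window; the gene is a candidate iff that
#' p-value is below `p_threshold` (default 1e-5). If other traits' summary
#' statistics are supplied, a cross-trait support column reports the traits
#' in which the gene's top SNP (recomputed per trait) has p < 0.05.
#'
#' @param gwas genome-ordered `gwas_summary` for the focal trait.
#' @param annot `gene_annotation`.
#' @param partition `module_partition`.
#' @param significant_modules character vector of module labels to scan.
#' @param p_threshold top-SNP p-value cutoff.
#' @param flank window flank in bp.
#' @param other_gwas optional named list of `gwas_summary` for other traits.
#' @return data.frame: gene, module, top_snp, top_snp_chrom, top_snp_pos,
#'   top_snp_effect, top_snp_pvalue, cross_trait_support.
#' @export
call_candidate_genes <- function(gwas, annot, partition, significant_modules,
                                 p_threshold = 1e-5, flank = 20000,
                                 other_gwas = list()) {
  genes <- names(partition)[partition %in% significant_modules]
  rows <- list()
  for (g in genes) {
    ann <- annot[annot$gene_id == g, , drop = FALSE]
    if (!nrow(ann)) next
    win <- gene_windows(ann, flank, merge = FALSE)
    hit <- which(snps_in_windows(gwas$chrom, gwas$pos, win))
    if (!length(hit)) next
    top <- hit[which.min(gwas$pvalue[hit])]
    if (gwas$pvalue[top] >= p_threshold) next
    support <- character(0)
    for (tr in names(other_gwas)) {
      og <- other_gwas[[tr]]
      oh <- which(snps_in_windows(og$chrom, og$pos, win))
      if (length(oh) && min(og$pvalue[oh]) < 0.05) support <- c(support, tr)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g, module = unname(partition[g]), top_snp = gwas$snp_id[top],
      top_snp_chrom = gwas$chrom[top], top_snp_pos = gwas$pos[top],
      top_snp_effect = gwas$effect_b[top], top_snp_pvalue = gwas$pvalue[top],
      cross_trait_support = paste(support, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene = character(0), module = character(0),
                      top_snp = character(0), top_snp_chrom = character(0),
                      top_snp_pos = integer(0), top_snp_effect = numeric(0),
                      top_snp_pvalue = numeric(0),
                      cross_trait_support = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$top_snp_pvalue), , drop = FALSE]
}
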