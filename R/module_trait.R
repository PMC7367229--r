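# Module-trait association: eigengene vs physiological state / bio-indicator
# Pearson correlations with t-based p-values and BH FDR over the whole grid,
# plus gene-level Welch group tests.

#' Benjamini-Hochberg step-up FDR
#'
#' `q_(i) = min_(j>=i) p_(j) * m / j` on the sorted p-values, mapped back to
#' input order and clipped at 1. NAs propagate.
#'
#' @param p numeric vector of p-values.
#' @return numeric vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  pv <- p[ok]
  m <- length(pv)
  ord <- order(pv)
  q <- pv[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out[ok][ord] <- q
  out
}

#' Trait design matrix from sample metadata
#'
#' Physiological states are encoded as four one-vs-rest 1/0 indicators; the
#' seven bio-indicators are carried as numeric columns.
#'
#' @param sample_info `sample_info` data.frame.
#' @return numeric matrix samples x traits (4 states + 7 bio-indicators).
#' @export
trait_design <- function(sample_info) {
  states <- vapply(KN_STATES, function(s) as.numeric(sample_info$state == s),
                   numeric(nrow(sample_info)))
  bio <- as.matrix(sample_info[, KN_BIOINDICATORS, drop = FALSE])
  out <- cbind(states, bio)
  rownames(out) <- sample_info$sample_id
  out
}

#' Associate module eigengenes with states and bio-indicators
#'
#' Pearson correlation of each eigengene with each trait column; two-sided
#' p from `t = r * sqrt(n-2) / sqrt(1-r^2)` with n-2 df; BH FDR pooled over
#' the full module x trait grid. Constant traits give NA rows with a
#' warning. Samples are treated as independent (the paired pre/post design
#' is not modeled); output metadata flags this assumption.
#'
#' @param eigengenes module-by-sample matrix from [compute_eigengenes()].
#' @param sample_info `sample_info` aligned to the eigengene columns.
#' @return data.frame: module, trait, r, pvalue, fdr, n_samples, signif
#'   ("**" FDR<0.05, "*" FDR<0.1).
#' @export
associate_modules_traits <- function(eigengenes, sample_info) {
  n <- ncol(eigengenes)
  if (n < 4) stop("need at least 4 samples")
  stopifnot(all(colnames(eigengenes) == sample_info$sample_id))
  traits <- trait_design(sample_info)
  res <- expand.grid(module = rownames(eigengenes), trait = colnames(traits),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res$r <- NA_real_; res$pvalue <- NA_real_
  for (i in seq_len(nrow(res))) {
    tr <- traits[, res$trait[i]]
    if (anyNA(tr) || stats::sd(tr, na.rm = TRUE) == 0) {
      ok <- !is.na(tr)
      if (sum(ok) < 4 || stats::sd(tr[ok]) == 0) {
        warning("constant or insufficient trait vector: ", res$trait[i])
        next
      }
      r <- stats::cor(eigengenes[res$module[i], ok], tr[ok])
      res$r[i] <- r; res$pvalue[i] <- cor_pvalue(r, sum(ok))
    } else {
      r <- stats::cor(eigengenes[res$module[i], ], tr)
      res$r[i] <- r; res$pvalue[i] <- cor_pvalue(r, n)
    }
  }
  res$fdr <- bh_fdr(res$pvalue)
  res$n_samples <- n
  res$signif <- ifelse(is.na(res$fdr), "",
                       ifelse(res$fdr < 0.05, "**",
                              ifelse(res$fdr < 0.1, "*", "")))
  res
}

#' Welch two-sample t-test for one gene between two state groups
#'
#' @param expr gene-by-sample expression matrix.
#' @param sample_info `sample_info` aligned to `expr` columns.
#' @param gene gene id (row of `expr`).
#' @param group_a,group_b state labels to compare.
#' @return list: `t`, `pvalue`, `df`, group means.
#' @export
gene_group_ttest <- function(expr, sample_info, gene, group_a, group_b) {
  stopifnot(gene %in% rownames(expr))
  xa <- expr[gene, sample_info$state == group_a]
  xb <- expr[gene, sample_info$state == group_b]
  if (length(xa) < 2 || length(xb) < 2) stop("each group needs >= 2 samples")
  va <- stats::var(xa) / length(xa)
  vb <- stats::var(xb) / length(xb)
  if (va + vb == 0) return(list(t = 0, pvalue = 1, df = NA_real_,
                                mean_a = mean(xa), mean_b = mean(xb)))
  tstat <- (mean(xa) - mean(xb)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(xa) - 1) + vb^2 / (length(xb) - 1))
  list(t = tstat, pvalue = 2 * stats::pt(-abs(tstat), df), df = df,
       mean_a = mean(xa), mean_b = mean(xb))
}
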