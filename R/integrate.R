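# Headline integration: correlate per-module GWAS enrichment evidence with
# module-state association evidence across modules, and assemble the final
# run report.

#' Correlate GWAS enrichment with module-trait association across modules
#'
#' Default axes: `x = -log10(empirical_p)` of the GWAS enrichment of
#' `trait`, `y = -log10(pvalue)` of the eigengene association with `state`,
#' one point per module (the leftover "unassigned" module included by
#' default). Pearson r with the usual two-sided t-based p. A Spearman-style
#' check on rank-transformed axes is reported alongside; with planted
#' coupling its sign must agree.
#'
#' @param enrich table from [enrich_all()].
#' @param modtrait table from [associate_modules_traits()].
#' @param trait GWAS trait name (column `trait` of `enrich`).
#' @param state module-trait column to use (state or bio-indicator name).
#' @param transform `"neglog10"` (default) or `"r"` (y = association r).
#' @param include_unassigned keep the leftover module as a point.
#' @return data.frame row: trait, state, r, pvalue, r_rank, pvalue_rank,
#'   n_modules; attribute `"points"` holds the per-module coordinates.
#' @export
correlate_enrichment_association <- function(enrich, modtrait, trait, state,
                                             transform = c("neglog10", "r"),
                                             include_unassigned = TRUE) {
  transform <- match.arg(transform)
  e <- enrich[enrich$trait == trait & !is.na(enrich$empirical_p), ]
  a <- modtrait[modtrait$trait == state & !is.na(modtrait$pvalue), ]
  mods <- intersect(e$module, a$module)
  if (!include_unassigned) mods <- setdiff(mods, KN_UNASSIGNED)
  if (length(mods) < 3) stop("need at least 3 modules with both scores")
  x <- -log10(e$empirical_p[match(mods, e$module)])
  y <- if (transform == "neglog10")
    -log10(a$pvalue[match(mods, a$module)]) else a$r[match(mods, a$module)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant axis; integration correlation undefined")
    r <- NA_real_; p <- NA_real_; rr <- NA_real_; pr <- NA_real_
  } else {
    r <- stats::cor(x, y)
    p <- cor_pvalue(r, length(mods))
    rr <- stats::cor(rank(x), rank(y))
    pr <- cor_pvalue(rr, length(mods))
  }
  out <- data.frame(trait = trait, state = state, r = r, pvalue = p,
                    r_rank = rr, pvalue_rank = pr, n_modules = length(mods),
                    stringsAsFactors = FALSE)
  attr(out, "points") <- data.frame(module = mods, x = x, y = y,
                                    stringsAsFactors = FALSE)
  out
}

#' Assemble the per-module run report
#'
#' Cross-references every stage table into one dossier per module (size,
#' strongest trait association, GWAS enrichment per trait, top tissue
#' enrichment, hub and candidate gene counts) plus a reproducibility block.
#' Numbers are copied from the stage tables, never recomputed.
#'
#' @param partition `module_partition`.
#' @param modtrait table from [associate_modules_traits()].
#' @param enrich table from [enrich_all()].
#' @param integration optional table from
#'   [correlate_enrichment_association()].
#' @param tissue_enrich optional table from [module_set_enrichment()].
#' @param hubs optional table from [call_hub_genes()].
#' @param candidates optional table from [call_candidate_genes()].
#' @param seed,config_hash reproducibility metadata.
#' @return list: `summary` (one data.frame row per module) and `markdown`
#'   (character vector of report lines).
#' @export
build_report <- function(partition, modtrait, enrich, integration = NULL,
                         tissue_enrich = NULL, hubs = NULL,
                         candidates = NULL, seed = NA, config_hash = NA) {
  mods <- sort(unique(unname(partition)))
  rows <- lapply(mods, function(m) {
    mt <- modtrait[modtrait$module == m & !is.na(modtrait$r), ]
    top_mt <- if (nrow(mt)) mt[which.max(abs(mt$r)), ] else NULL
    en <- enrich[enrich$module == m & !is.na(enrich$empirical_p), ]
    top_en <- if (nrow(en)) en[which.min(en$empirical_p), ] else NULL
    te <- if (!is.null(tissue_enrich))
      tissue_enrich[tissue_enrich$module == m, ] else NULL
    top_te <- if (!is.null(te) && nrow(te)) te[which.min(te$pvalue), ] else NULL
    data.frame(
      module = m, n_genes = sum(partition == m),
      top_trait = if (is.null(top_mt)) NA_character_ else top_mt$trait,
      top_trait_r = if (is.null(top_mt)) NA_real_ else top_mt$r,
      top_trait_fdr = if (is.null(top_mt)) NA_real_ else top_mt$fdr,
      top_gwas_trait = if (is.null(top_en)) NA_character_ else top_en$trait,
      top_gwas_p = if (is.null(top_en)) NA_real_ else top_en$empirical_p,
      top_gwas_fdr = if (is.null(top_en)) NA_real_ else top_en$fdr,
      top_tissue = if (is.null(top_te)) NA_character_ else top_te$set,
      top_tissue_p = if (is.null(top_te)) NA_real_ else top_te$pvalue,
      n_hub_genes = if (is.null(hubs)) NA_integer_ else
        sum(hubs$module == m),
      n_candidate_genes = if (is.null(candidates)) NA_integer_ else
        sum(candidates$module == m),
      stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)

  md <- c("# ketonet run report", "",
          sprintf("- pipeline version: %s", kn_version()),
          sprintf("- seed: %s", format(seed)),
          sprintf("- config hash: %s", format(config_hash)),
          sprintf("- modules: %d (leftover '%s' included)",
                  length(mods), KN_UNASSIGNED), "")
  if (!is.null(integration))
    md <- c(md, sprintf(
      "Integration (%s vs %s): r = %.3f, p = %.3g over %d modules.",
      integration$trait[1], integration$state[1], integration$r[1],
      integration$pvalue[1], integration$n_modules[1]), "")
  md <- c(md, "## Modules", "")
  for (i in seq_len(nrow(summary))) {
    s <- summary[i, ]
    md <- c(md, sprintf(
      "- **%s** (%d genes): top trait %s (r = %.2f, FDR = %.3g); top GWAS trait %s (p = %.3g, FDR = %.3g)%s%s",
      s$module, s$n_genes,
      ifelse(is.na(s$top_trait), "none", s$top_trait),
      ifelse(is.na(s$top_trait_r), NA, s$top_trait_r),
      s$top_trait_fdr,
      ifelse(is.na(s$top_gwas_trait), "none", s$top_gwas_trait),
      s$top_gwas_p, s$top_gwas_fdr,
      ifelse(is.na(s$n_hub_genes), "",
             sprintf("; hub genes: %d", s$n_hub_genes)),
      ifelse(is.na(s$n_candidate_genes), "",
             sprintf("; candidate genes: %d", s$n_candidate_genes))))
  }
  md <- c(md, "",
          "Note: samples are treated as independent; the paired pre/post-partum design is not modeled.")
  list(summary = summary, markdown = md)
}
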