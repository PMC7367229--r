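# Run-directory pipeline: each stage reads its inputs (from the configured
# paths or from a previous stage's outputs in the run directory), writes
# TSV artifacts with metadata headers, and logs parameters and seeds.
# Stages are deliberately file-coupled so CLI subcommands can be re-run
# independently.

kn_default_config <- function() {
  list(
    seed = 1L,
    simulate = list(n_samples = 24, n_genes = 2000,
                    module_sizes = c(150, 120, 100, 80, 60),
                    within_module_cor = 0.7, n_snps = 20000, n_chroms = 5,
                    count_depth = 5e5),
    preprocess = list(min_tpm = 1, min_samples = 1, mad_quantile = 0.25,
                      mad_floor = 0.01),
    network = list(soft_power = "auto", min_module_size = 30,
                   merge_cor_threshold = 0.9, cut_height = 0.99,
                   k_threshold = 30, gs_threshold = 0.2),
    gwas_enrichment = list(n_perm = 10000, flank = 20000,
                           candidate_p_threshold = 1e-5),
    tissue = list(n_tissues = 8, samples_per_tissue = 5, fraction = 0.05),
    integrate = list(trait = "KETO", state = "K_Post",
                     include_unassigned = TRUE)
  )
}

# shallow-merge user config over defaults, section by section
kn_merge_config <- function(user) {
  cfg <- kn_default_config()
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(cfg[[k]]))
      cfg[[k]] <- utils::modifyList(cfg[[k]], user[[k]])
    else cfg[[k]] <- user[[k]]
  }
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are kept; known sections are merged over package defaults.
#' The raw file content is hashed (FNV-1a) into `attr(cfg, "hash")` and
#' stamped into every output table.
#'
#' @param path YAML file.
#' @return config list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- paste(readLines(path), collapse = "\n")
  cfg <- kn_merge_config(yaml::yaml.load(raw))
  attr(cfg, "hash") <- kn_hash(raw)
  cfg
}

kn_paths <- function(outdir) {
  list(input = file.path(outdir, "input"),
       counts = file.path(outdir, "input", "counts.tsv"),
       sample_info = file.path(outdir, "input", "sample_info.tsv"),
       annot = file.path(outdir, "input", "gene_annotation.tsv"),
       truth = file.path(outdir, "input", "ground_truth.tsv"),
       tissue_panel = file.path(outdir, "input", "tissue_panel.tsv"),
       tissue_labels = file.path(outdir, "input", "tissue_labels.tsv"),
       tpm = file.path(outdir, "tpm.tsv"),
       vst = file.path(outdir, "vst.tsv"),
       filter_report = file.path(outdir, "filter_report.tsv"),
       modules = file.path(outdir, "modules.tsv"),
       eigengenes = file.path(outdir, "eigengenes.tsv"),
       dendro = file.path(outdir, "dendrogram_heights.tsv"),
       hubs = file.path(outdir, "hub_genes.tsv"),
       module_trait = file.path(outdir, "module_trait.tsv"),
       windows_bed = file.path(outdir, "module_windows.bed"),
       enrichment = file.path(outdir, "enrichment.tsv"),
       candidates = file.path(outdir, "candidates.tsv"),
       tissue_t = file.path(outdir, "tissue_t.tsv"),
       tissue_sets = file.path(outdir, "tissue_sets.tsv"),
       tissue_enrichment = file.path(outdir, "tissue_enrichment.tsv"),
       integration = file.path(outdir, "integration.tsv"),
       report = file.path(outdir, "report.md"),
       log = file.path(outdir, "ketonet.log"))
}

kn_meta_for <- function(cfg) {
  kn_meta_lines(seed = cfg$seed, config_hash = attr(cfg, "hash"))
}

kn_read_matrix_tsv <- function(path) {
  df <- read_tsv_skip_meta(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

kn_write_matrix_tsv <- function(m, path, meta, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv_with_meta(df, path, meta)
}

stage_simulate <- function(cfg, paths) {
  sim_args <- cfg$simulate
  sim_args$seed <- cfg$seed
  scfg <- do.call(synth_config, sim_args[names(sim_args) %in%
                                           names(formals(synth_config))])
  sim <- simulate_expression(scfg)
  gw <- simulate_gwas(scfg, sim$annot, sim$truth)
  trait <- cfg$integrate$trait
  gwas_list <- stats::setNames(list(gw), trait)
  write_synthetic(sim, gwas_list, paths$input, config_hash = attr(cfg, "hash"))
  tp <- simulate_tissue_panel(scfg, n_tissues = cfg$tissue$n_tissues,
                              samples_per_tissue = cfg$tissue$samples_per_tissue)
  meta <- kn_meta_for(cfg)
  kn_write_matrix_tsv(tp$panel$expr, paths$tissue_panel, meta, "gene")
  write_tsv_with_meta(data.frame(sample_id = colnames(tp$panel$expr),
                                 tissue = as.character(tp$panel$tissue)),
                      paths$tissue_labels, meta)
  kn_log("simulate: ", nrow(sim$counts), " genes x ", ncol(sim$counts),
         " samples, ", nrow(gw), " SNPs, seed ", cfg$seed,
         file = paths$log)
  invisible(NULL)
}

kn_input_path <- function(cfg, paths, key, default) {
  p <- cfg$inputs[[key]]
  if (is.null(p)) default else p
}

stage_preprocess <- function(cfg, paths) {
  counts <- read_count_matrix(kn_input_path(cfg, paths, "counts", paths$counts))
  annot <- read_gene_annotation(kn_input_path(cfg, paths, "annotation", paths$annot))
  tpm <- compute_tpm(counts, annot)
  fl <- filter_genes(tpm, min_tpm = cfg$preprocess$min_tpm,
                     min_samples = cfg$preprocess$min_samples,
                     mad_quantile = cfg$preprocess$mad_quantile,
                     mad_floor = cfg$preprocess$mad_floor)
  vst <- vst_normalize(counts, fl$genes)
  meta <- kn_meta_for(cfg)
  kn_write_matrix_tsv(round(tpm, 4), paths$tpm, meta, "gene")
  kn_write_matrix_tsv(round(vst, 6), paths$vst, meta, "gene")
  rep_df <- data.frame(gene = rownames(tpm), mad = round(fl$report$mad, 6),
                       kept = rownames(tpm) %in% fl$genes)
  write_tsv_with_meta(rep_df, paths$filter_report, c(
    meta,
    sprintf("# n_input_genes=%d n_pass_expression=%d n_pass_mad=%d",
            fl$report$n_input_genes, fl$report$n_pass_expression,
            fl$report$n_pass_mad),
    sprintf("# mad_scale=%s", fl$report$mad_scale),
    sprintf("# thresholds=%s",
            paste(names(fl$report$thresholds), fl$report$thresholds,
                  sep = "=", collapse = " "))))
  kn_log("preprocess: kept ", length(fl$genes), "/", nrow(counts), " genes",
         file = paths$log)
  invisible(NULL)
}

stage_network <- function(cfg, paths) {
  vst <- kn_read_matrix_tsv(paths$vst)
  info <- read_sample_info(kn_input_path(cfg, paths, "sample_info",
                                         paths$sample_info))
  params <- network_params(soft_power = cfg$network$soft_power,
                           min_module_size = cfg$network$min_module_size,
                           merge_cor_threshold = cfg$network$merge_cor_threshold,
                           cut_height = cfg$network$cut_height)
  sp <- select_soft_power(vst, params)
  tom <- build_tom(vst, sp$beta)
  part <- detect_modules(tom, params, expr = vst)
  part <- merge_modules(vst, part, params$merge_cor_threshold)
  me <- compute_eigengenes(vst, part, include_unassigned = TRUE)
  meta <- c(kn_meta_for(cfg), sprintf("# soft_power=%d", sp$beta))
  write_module_partition(part, paths$modules, meta)
  kn_write_matrix_tsv(round(me, 8), paths$eigengenes, meta, "module")
  write_tsv_with_meta(data.frame(merge = seq_along(attr(part, "merge_heights")),
                                 height = round(attr(part, "merge_heights"), 8)),
                      paths$dendro, meta)
  traits <- as.data.frame(trait_design(info))
  traits <- traits[, colSums(is.na(traits)) == 0, drop = FALSE]
  hubs <- call_hub_genes(vst, part, traits, beta = sp$beta,
                         k_threshold = cfg$network$k_threshold,
                         gs_threshold = cfg$network$gs_threshold)
  hubs[, vapply(hubs, is.numeric, TRUE)] <-
    round(hubs[, vapply(hubs, is.numeric, TRUE)], 6)
  write_tsv_with_meta(hubs, paths$hubs, meta)
  kn_log("network: beta ", sp$beta, ", ",
         length(setdiff(unique(part), KN_UNASSIGNED)), " modules + ",
         KN_UNASSIGNED, file = paths$log)
  invisible(NULL)
}

stage_modtrait <- function(cfg, paths) {
  me <- kn_read_matrix_tsv(paths$eigengenes)
  info <- read_sample_info(kn_input_path(cfg, paths, "sample_info",
                                         paths$sample_info))
  mt <- associate_modules_traits(me, info)
  mt$r <- round(mt$r, 6); mt$pvalue <- signif(mt$pvalue, 6)
  mt$fdr <- signif(mt$fdr, 6)
  write_tsv_with_meta(mt, paths$module_trait, c(
    kn_meta_for(cfg),
    "# assumption=samples treated as independent (paired design not modeled)"))
  kn_log("modtrait: ", sum(mt$fdr < 0.05, na.rm = TRUE),
         " grid cells at FDR<0.05", file = paths$log)
  invisible(NULL)
}

kn_gwas_inputs <- function(cfg, paths) {
  if (!is.null(cfg$inputs$gwas))
    return(lapply(cfg$inputs$gwas, read_gwas_summary))
  files <- list.files(paths$input, pattern = "^gwas_.*\\.tsv$",
                      full.names = TRUE)
  if (!length(files)) stop("no GWAS summary files found")
  out <- lapply(files, read_gwas_summary)
  names(out) <- sub("^gwas_(.*)\\.tsv$", "\\1", basename(files))
  out
}

stage_gwasenrich <- function(cfg, paths) {
  part <- read_module_partition(paths$modules)
  annot <- read_gene_annotation(kn_input_path(cfg, paths, "annotation",
                                              paths$annot))
  gwas <- kn_gwas_inputs(cfg, paths)
  en <- enrich_all(gwas, part, annot, n_perm = cfg$gwas_enrichment$n_perm,
                   seed = cfg$seed, flank = cfg$gwas_enrichment$flank)
  en$t_obs <- signif(en$t_obs, 8)
  en$empirical_p <- signif(en$empirical_p, 6)
  en$fdr <- signif(en$fdr, 6)
  write_tsv_with_meta(en, paths$enrichment, kn_meta_for(cfg))
  write_module_windows_bed(module_windows(annot, part,
                                          cfg$gwas_enrichment$flank),
                           paths$windows_bed)
  sig <- unique(en$module[en$significant])
  focal <- cfg$integrate$trait
  if (!focal %in% names(gwas)) focal <- names(gwas)[1]
  cand <- call_candidate_genes(gwas[[focal]], annot, part, sig,
                               p_threshold = cfg$gwas_enrichment$candidate_p_threshold,
                               flank = cfg$gwas_enrichment$flank,
                               other_gwas = gwas[setdiff(names(gwas), focal)])
  write_tsv_with_meta(cand, paths$candidates, kn_meta_for(cfg))
  kn_log("gwasenrich: ", sum(en$significant), " significant cells, ",
         nrow(cand), " candidate genes", file = paths$log)
  invisible(NULL)
}

stage_tissue <- function(cfg, paths) {
  panel_path <- kn_input_path(cfg, paths, "tissue_panel", paths$tissue_panel)
  labels_path <- kn_input_path(cfg, paths, "tissue_labels", paths$tissue_labels)
  expr <- kn_read_matrix_tsv(panel_path)
  lab <- read_tsv_skip_meta(labels_path)
  panel <- tissue_panel(expr, lab$tissue[match(colnames(expr), lab$sample_id)])
  sets <- top_fraction_sets(panel, fraction = cfg$tissue$fraction)
  meta <- kn_meta_for(cfg)
  kn_write_matrix_tsv(round(sets$t_matrix, 6), paths$tissue_t, meta, "gene")
  flat <- data.frame(
    tissue = rep(names(sets$sets), lengths(sets$sets)),
    gene = unlist(sets$sets, use.names = FALSE))
  write_tsv_with_meta(flat, paths$tissue_sets,
                      c(meta, sprintf("# fraction=%g", sets$fraction)))
  if (file.exists(paths$modules)) {
    part <- read_module_partition(paths$modules)
    universe <- intersect(names(part), rownames(expr))
    te <- module_set_enrichment(part[universe], sets$sets, universe)
    te$pvalue <- signif(te$pvalue, 6); te$fdr <- signif(te$fdr, 6)
    write_tsv_with_meta(te, paths$tissue_enrichment, meta)
  }
  kn_log("tissue: ", length(sets$sets), " tissue sets of ",
         length(sets$sets[[1]]), " genes", file = paths$log)
  invisible(NULL)
}

stage_integrate <- function(cfg, paths) {
  en <- read_tsv_skip_meta(paths$enrichment)
  mt <- read_tsv_skip_meta(paths$module_trait)
  part <- read_module_partition(paths$modules)
  ir <- correlate_enrichment_association(
    en, mt, trait = cfg$integrate$trait, state = cfg$integrate$state,
    include_unassigned = isTRUE(cfg$integrate$include_unassigned))
  pts <- attr(ir, "points")
  ir$r <- round(ir$r, 6); ir$pvalue <- signif(ir$pvalue, 6)
  ir$r_rank <- round(ir$r_rank, 6); ir$pvalue_rank <- signif(ir$pvalue_rank, 6)
  write_tsv_with_meta(ir, paths$integration, kn_meta_for(cfg))
  te <- if (file.exists(paths$tissue_enrichment))
    read_tsv_skip_meta(paths$tissue_enrichment) else NULL
  hubs <- if (file.exists(paths$hubs)) read_tsv_skip_meta(paths$hubs) else NULL
  cand <- if (file.exists(paths$candidates))
    read_tsv_skip_meta(paths$candidates) else NULL
  rep <- build_report(part, mt, en, integration = ir, tissue_enrich = te,
                      hubs = hubs, candidates = cand, seed = cfg$seed,
                      config_hash = attr(cfg, "hash"))
  writeLines(rep$markdown, paths$report)
  kn_log("integrate: r = ", round(ir$r, 3), ", p = ", signif(ir$pvalue, 3),
         file = paths$log)
  invisible(NULL)
}

#' Run pipeline stages into a run directory
#'
#' @param config config list (see [read_pipeline_config()]) or path to a
#'   YAML file.
#' @param outdir run directory (created).
#' @param stages subset of `c("simulate", "preprocess", "network",
#'   "modtrait", "gwasenrich", "tissue", "integrate")`; default all.
#' @param seed optional seed override.
#' @return `outdir`, invisibly.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("simulate", "preprocess", "network",
                                    "modtrait", "gwasenrich", "tissue",
                                    "integrate"),
                         seed = NULL) {
  cfg <- if (is.character(config)) read_pipeline_config(config) else config
  if (is.null(attr(cfg, "hash"))) attr(cfg, "hash") <- kn_hash("inline-config")
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- kn_paths(outdir)
  all_stages <- c(simulate = stage_simulate, preprocess = stage_preprocess,
                  network = stage_network, modtrait = stage_modtrait,
                  gwasenrich = stage_gwasenrich, tissue = stage_tissue,
                  integrate = stage_integrate)
  bad <- setdiff(stages, names(all_stages))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  skip_simulate <- !is.null(cfg$inputs) && "simulate" %in% stages &&
    !is.null(cfg$inputs$counts)
  for (s in stages) {
    if (s == "simulate" && skip_simulate) {
      kn_log("simulate: skipped (external inputs configured)",
             file = paths$log)
      next
    }
    kn_log("stage ", s, " (seed ", cfg$seed, ")", file = paths$log)
    all_stages[[s]](cfg, paths)
  }
  invisible(outdir)
}
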