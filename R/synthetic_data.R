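# Synthetic-data generator. Emulates the transition-cow study design: 24
# blood transcriptomes in 4 physiological states (healthy/ketotic x
# pre/post-partum), planted co-expression modules driven by latent factors
# that are coupled to states and bio-indicators, and genome-ordered SNP
# effect vectors with inflated squared effects near the genes of chosen
# modules. Every generator is a pure function of (config, seed).

#' Configuration of the synthetic world
#'
#' Defaults mirror the emulated study design: 24 samples, 6 per state; five
#' planted modules of 150/120/100/80/60 genes among `n_genes` total; latent
#' within-module correlation 0.7; 20,000 SNPs on 5 chromosomes; SNP effect
#' variance inflated 4-fold inside the +/-20 kb windows of two "enriched"
#' modules. Module M1 is activated in ketotic post-partum samples (shift
#' +2.5 latent SD) and drives a BHBA-like indicator; module M2 is mildly
#' suppressed post-partum in ketosis (shift -1.5) and positively coupled to
#' an HDL-like indicator.
#'
#' @param seed mandatory RNG seed (integer).
#' @param n_samples total samples; must be divisible by 4 (states balanced).
#' @param n_genes total genes, planted modules included.
#' @param module_sizes planted module sizes; sum must be <= `n_genes`.
#' @param within_module_cor target latent pairwise Pearson correlation of
#'   module genes, in (0, 1).
#' @param trait_driving list per module: `state` + `shift` (latent SD units)
#'   and/or `indicator` + `indicator_cor`.
#' @param n_snps,n_chroms GWAS marker count and chromosome count.
#' @param enriched_modules named numeric: effect-variance inflation factor
#'   (>= 1) per enriched module.
#' @param baseline_effect_sd SD of null SNP effects (also the reported SE).
#' @param count_depth mean library size (reads per sample).
#' @param nb_dispersion negative-binomial dispersion of the count layer.
#' @param libsize_cv coefficient of variation of log-normal library sizes.
#' @param latent_log_sd scale mapping latent z to log expression.
#' @param gene_mean_log_sd SD of log baseline expression across genes.
#' @param flank_bp window flank used when planting GWAS enrichment.
#' @return list with class `synth_config`.
#' @export
synth_config <- function(seed,
                         n_samples = 24,
                         n_genes = 2000,
                         module_sizes = c(150, 120, 100, 80, 60),
                         within_module_cor = 0.7,
                         trait_driving = list(
                           M1 = list(state = "K_Post", shift = 2.5,
                                     indicator = "BHBA", indicator_cor = 0.7),
                           M2 = list(state = "K_Post", shift = -1.5,
                                     indicator = "HDL", indicator_cor = 0.75)
                         ),
                         n_snps = 20000,
                         n_chroms = 5,
                         enriched_modules = c(M1 = 4, M2 = 4),
                         baseline_effect_sd = 0.1,
                         count_depth = 3e6,
                         nb_dispersion = 0.1,
                         libsize_cv = 0.2,
                         latent_log_sd = 1.5,
                         gene_mean_log_sd = 1,
                         flank_bp = 20000) {
  if (missing(seed) || is.null(seed) || is.na(seed)) stop("seed is mandatory")
  if (sum(module_sizes) > n_genes) stop("sum(module_sizes) must be <= n_genes")
  if (within_module_cor <= 0 || within_module_cor >= 1)
    stop("within_module_cor must lie strictly in (0, 1)")
  if (length(enriched_modules) && any(enriched_modules < 1))
    stop("inflation factors must be >= 1")
  if (n_samples %% 4 != 0) stop("n_samples must be divisible by 4")
  cfg <- list(seed = as.integer(seed), n_samples = n_samples,
              n_genes = n_genes, module_sizes = module_sizes,
              within_module_cor = within_module_cor,
              trait_driving = trait_driving, n_snps = n_snps,
              n_chroms = n_chroms, enriched_modules = enriched_modules,
              baseline_effect_sd = baseline_effect_sd,
              count_depth = count_depth, nb_dispersion = nb_dispersion,
              libsize_cv = libsize_cv, latent_log_sd = latent_log_sd,
              gene_mean_log_sd = gene_mean_log_sd, flank_bp = flank_bp)
  class(cfg) <- "synth_config"
  cfg
}

synth_module_labels <- function(cfg) paste0("M", seq_along(cfg$module_sizes))

# Realistic plasma bio-indicator baselines (mmol/L except INS in uIU/mL).
kn_bioindicator_baselines <- function() {
  list(BHBA = c(mean = 0.9, sd = 0.30),
       TC   = c(mean = 4.2, sd = 0.90),
       TG   = c(mean = 0.25, sd = 0.08),
       HDL  = c(mean = 1.6, sd = 0.40),
       LDL  = c(mean = 2.0, sd = 0.60),
       Ca   = c(mean = 2.3, sd = 0.15),
       INS  = c(mean = 8.0, sd = 3.00))
}

#' Simulate the expression side of the study
#'
#' Draws one latent factor per module per sample (standard normal, plus the
#' configured mean shift in a target state); each module gene's latent
#' expression is `sqrt(rho) * factor + sqrt(1-rho) * noise`, so the expected
#' latent pairwise correlation equals `within_module_cor`
#' (rho = loading^2 / (loading^2 + noise_var)). Background genes are
#' independent noise. Latent z is mapped to a relative expression rate
#' `exp(mu_g + latent_log_sd * z)`, scaled by gene length, and observed
#' through a negative-binomial layer with log-normal library sizes.
#' Bio-indicators are linear functions of their designated latent factor
#' plus noise, at the configured correlation.
#'
#' @param cfg a [synth_config()].
#' @return list with elements `counts` (count_matrix), `sample_info`,
#'   `annot` (gene_annotation), `truth` (ground-truth list: `modules`
#'   named gene->label vector with "unassigned" background, `factors`
#'   module-by-sample matrix, `enriched_modules`, `latent` gene-by-sample
#'   latent matrix, and the config).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples; G <- cfg$n_genes
  genes <- sprintf("g%04d", seq_len(G))
  samples <- sprintf("s%02d", seq_len(n))
  per_state <- n / 4
  state <- rep(KN_STATES, each = per_state)

  mods <- synth_module_labels(cfg)
  # scatter module genes across the (genomic) gene order, like real modules
  member <- rep(KN_UNASSIGNED, G)
  pool <- sample.int(G, sum(cfg$module_sizes))
  off <- 0
  for (i in seq_along(mods)) {
    member[pool[off + seq_len(cfg$module_sizes[i])]] <- mods[i]
    off <- off + cfg$module_sizes[i]
  }
  names(member) <- genes

  # latent factors, with trait-driving mean shifts. For driving modules the
  # noise is standardized within the target group and its complement, so
  # the realized group separation equals the configured shift exactly
  # (stratified draw); otherwise n=24 sampling noise would randomize which
  # module associates most strongly with its state.
  factors <- matrix(stats::rnorm(length(mods) * n), length(mods), n,
                    dimnames = list(mods, samples))
  std <- function(v) (v - mean(v)) / stats::sd(v)
  for (m in names(cfg$trait_driving)) {
    td <- cfg$trait_driving[[m]]
    if (!is.null(td$state) && !is.null(td$shift) && m %in% mods) {
      tgt <- state == td$state
      factors[m, tgt] <- std(factors[m, tgt]) + td$shift
      factors[m, !tgt] <- std(factors[m, !tgt])
    }
  }

  rho <- cfg$within_module_cor
  z <- matrix(stats::rnorm(G * n, sd = 1), G, n, dimnames = list(genes, samples))
  for (m in mods) {
    idx <- which(member == m)
    z[idx, ] <- sqrt(rho) * matrix(factors[m, ], length(idx), n, byrow = TRUE) +
      sqrt(1 - rho) * z[idx, ]
  }

  # gene model: genes laid end to end on n_chroms chromosomes, 50 kb grid
  grid <- 50000
  per_chrom <- ceiling(G / cfg$n_chroms)
  chrom <- paste0("chr", 1 + (seq_len(G) - 1) %/% per_chrom)
  slot <- (seq_len(G) - 1) %% per_chrom
  len <- pmin(round(stats::rlnorm(G, meanlog = log(3000), sdlog = 0.5)), 30000)
  len <- pmax(len, 200)
  start <- slot * grid + 5000
  annot <- as_gene_annotation(data.frame(
    gene_id = genes, chrom = chrom, start = start, end = start + len,
    length_bp = len, stringsAsFactors = FALSE))

  # counts: NB around length- and depth-scaled rates. Depth enters through
  # an explicit log-normal library-size factor against a constant
  # normalizer, not compositional closure: closing each sample to its own
  # rate sum would inject an artifactual anti-module component into every
  # background gene whenever a large module swings (the real compositional
  # artifact of extreme DE, deliberately out of scope here).
  mu_g <- stats::rnorm(G, mean = 0, sd = cfg$gene_mean_log_sd)
  rate <- exp(mu_g + cfg$latent_log_sd * z) * (len / 1000)
  libsize <- stats::rlnorm(n, meanlog = log(cfg$count_depth) -
                             log(1 + cfg$libsize_cv^2) / 2,
                           sdlog = sqrt(log(1 + cfg$libsize_cv^2)))
  mu <- sweep(rate, 2, libsize / mean(colSums(rate)), "*")
  counts <- matrix(stats::rnbinom(G * n, mu = mu, size = 1 / cfg$nb_dispersion),
                   G, n, dimnames = list(genes, samples))

  # bio-indicators: linear in a designated factor + noise at target cor
  base <- kn_bioindicator_baselines()
  bio <- lapply(names(base), function(b) {
    stats::rnorm(n, base[[b]]["mean"], base[[b]]["sd"])
  })
  names(bio) <- names(base)
  for (m in names(cfg$trait_driving)) {
    td <- cfg$trait_driving[[m]]
    if (is.null(td$indicator) || !(m %in% mods)) next
    r <- td$indicator_cor
    f <- factors[m, ]
    fz <- (f - mean(f)) / stats::sd(f)
    # orthogonalize the noise against the factor so the realized sample
    # correlation equals the configured one exactly
    e <- stats::rnorm(n)
    e <- e - fz * sum(e * fz) / sum(fz^2)
    e <- (e - mean(e)) / stats::sd(e)
    b <- base[[td$indicator]]
    bio[[td$indicator]] <-
      b["mean"] + b["sd"] * (r * fz + sqrt(1 - r^2) * e)
  }
  info <- as_sample_info(data.frame(
    sample_id = samples, state = state,
    as.data.frame(lapply(bio, round, 4)), stringsAsFactors = FALSE))

  truth <- list(modules = member, factors = factors,
                enriched_modules = cfg$enriched_modules,
                latent = z, config = cfg)
  list(counts = as_count_matrix(counts), sample_info = info,
       annot = annot, truth = truth)
}

#' Simulate single-marker GWAS summary statistics
#'
#' SNP positions are placed uniformly along the synthetic chromosomes.
#' Effects are `b ~ N(0, sigma^2)` with
#' `sigma^2 = baseline_effect_sd^2 * inflation` for SNPs falling within
#' +/-`flank_bp` of any gene of an enriched module and `baseline^2`
#' elsewhere; p-values come from the z-score `b / baseline_effect_sd`.
#' Genome order is preserved.
#'
#' @param cfg a [synth_config()].
#' @param annot gene annotation from [simulate_expression()].
#' @param truth ground truth from [simulate_expression()].
#' @param seed optional seed override (defaults to `cfg$seed + 1`).
#' @return a `gwas_summary` data.frame; attribute `"effect_sd"` carries the
#'   per-SNP generative SD for ground-truth scoring.
#' @export
simulate_gwas <- function(cfg, annot, truth, seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(seed)
  chroms <- sort(unique(annot$chrom))
  chrom_len <- vapply(chroms, function(ch)
    max(annot$end[annot$chrom == ch]) + 50000, numeric(1))
  n_per <- round(cfg$n_snps * chrom_len / sum(chrom_len))
  n_per[length(n_per)] <- cfg$n_snps - sum(n_per[-length(n_per)])

  snp <- do.call(rbind, lapply(seq_along(chroms), function(i) {
    pos <- sort(sample.int(chrom_len[i], n_per[i]))  # 1-based positions
    data.frame(chrom = chroms[i], pos = pos, stringsAsFactors = FALSE)
  }))
  snp$snp_id <- sprintf("snp%06d", seq_len(nrow(snp)))

  sd_vec <- rep(cfg$baseline_effect_sd, nrow(snp))
  hit_any <- FALSE
  for (m in names(cfg$enriched_modules)) {
    genes_m <- names(truth$modules)[truth$modules == m]
    if (!length(genes_m)) next
    win <- gene_windows(annot[annot$gene_id %in% genes_m, ], cfg$flank_bp)
    hits <- snps_in_windows(snp$chrom, snp$pos, win)
    if (any(hits)) hit_any <- TRUE
    sd_vec[hits] <- pmax(sd_vec[hits],
                         cfg$baseline_effect_sd * sqrt(cfg$enriched_modules[[m]]))
  }
  if (length(cfg$enriched_modules) && any(cfg$enriched_modules > 1) && !hit_any)
    stop("no SNP falls in any enriched-module window; increase n_snps")

  b <- stats::rnorm(nrow(snp), 0, sd_vec)
  pval <- if (cfg$baseline_effect_sd > 0)
    pmax(2 * stats::pnorm(-abs(b) / cfg$baseline_effect_sd), 1e-300)
  else rep(1, nrow(snp))                 # degenerate zero-SE case
  gw <- as_gwas_summary(data.frame(
    snp_id = snp$snp_id, chrom = snp$chrom, pos = snp$pos,
    effect_b = b, pvalue = pval, stringsAsFactors = FALSE),
    source = "simulated gwas")
  attr(gw, "effect_sd") <- sd_vec[order(snp$chrom, snp$pos)]
  gw
}

#' Simulate a multi-tissue expression panel with planted specific genes
#'
#' Each tissue gets a disjoint random fraction of genes whose mean is
#' shifted upward in that tissue only; all other values are standard normal
#' (log-expression scale). The planted sets are the ground truth for
#' top-fraction tissue-specificity recovery.
#'
#' @param cfg a [synth_config()] (supplies `n_genes` and the seed).
#' @param n_tissues number of tissues (>= 2).
#' @param samples_per_tissue samples per tissue (>= 2).
#' @param specific_fraction fraction of genes planted per tissue.
#' @param shift mean shift (in SD units) of planted genes in their tissue.
#' @param seed optional seed override (defaults to `cfg$seed + 2`).
#' @return list: `panel` (a [tissue_panel()]), `specific_sets` (named list
#'   tissue -> planted gene ids).
#' @export
simulate_tissue_panel <- function(cfg, n_tissues = 8, samples_per_tissue = 5,
                                  specific_fraction = 0.02, shift = 3,
                                  seed = cfg$seed + 2L) {
  if (n_tissues < 2) stop("need at least 2 tissues")
  set.seed(seed)
  G <- cfg$n_genes
  genes <- sprintf("g%04d", seq_len(G))
  tissues <- sprintf("T%02d", seq_len(n_tissues))
  labels <- rep(tissues, each = samples_per_tissue)
  ns <- length(labels)
  expr <- matrix(stats::rnorm(G * ns), G, ns,
                 dimnames = list(genes, sprintf("ts%03d", seq_len(ns))))
  k <- max(0L, round(specific_fraction * G))
  pool <- sample.int(G, min(G, k * n_tissues))
  sets <- vector("list", n_tissues)
  names(sets) <- tissues
  for (i in seq_len(n_tissues)) {
    idx <- pool[((i - 1) * k + 1):(i * k)]
    if (k == 0) idx <- integer(0)
    expr[idx, labels == tissues[i]] <- expr[idx, labels == tissues[i]] + shift
    sets[[i]] <- genes[idx]
  }
  list(panel = tissue_panel(expr, labels), specific_sets = sets)
}

#' Write all synthetic artifacts to a directory
#'
#' Emits exactly the TSVs the readers consume, plus `ground_truth.tsv`
#' (gene, planted module) and `factors.tsv`.
#'
#' @param sim output of [simulate_expression()].
#' @param gwas optional `gwas_summary` (written per trait name).
#' @param dir output directory (created).
#' @param config_hash fingerprint stamped into headers.
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(sim, gwas = NULL, dir, config_hash = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- kn_meta_lines(seed = sim$truth$config$seed, config_hash = config_hash)
  write_count_matrix(sim$counts, file.path(dir, "counts.tsv"), meta)
  write_sample_info(sim$sample_info, file.path(dir, "sample_info.tsv"), meta)
  write_gene_annotation(sim$annot, file.path(dir, "gene_annotation.tsv"), meta)
  write_module_partition(sim$truth$modules, file.path(dir, "ground_truth.tsv"), meta)
  write_tsv_with_meta(data.frame(module = rownames(sim$truth$factors),
                                 sim$truth$factors, check.names = FALSE),
                      file.path(dir, "factors.tsv"), meta)
  if (!is.null(gwas)) {
    if (inherits(gwas, "gwas_summary")) gwas <- list(trait1 = gwas)
    for (tr in names(gwas))
      write_gwas_summary(gwas[[tr]], file.path(dir, paste0("gwas_", tr, ".tsv")), meta)
  }
  invisible(dir)
}
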