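# Fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdirs.

# tiny deterministic count matrix + annotation
tiny_counts <- function(genes = 3, samples = 2, seed = 99) {
  set.seed(seed)
  m <- matrix(rpois(genes * samples, 50), genes, samples,
              dimnames = list(sprintf("g%02d", seq_len(genes)),
                              sprintf("s%02d", seq_len(samples))))
  as_count_matrix(m)
}

tiny_annot <- function(genes, len = NULL, chrom = "chr1", spacing = 50000) {
  n <- length(genes)
  if (is.null(len)) len <- rep(1000L, n)
  start <- (seq_len(n) - 1L) * spacing + 1000L
  as_gene_annotation(data.frame(
    gene_id = genes, chrom = rep(chrom, n), start = start,
    end = start + len, length_bp = len, stringsAsFactors = FALSE))
}

tiny_sample_info <- function(samples, seed = 7) {
  set.seed(seed)
  n <- length(samples)
  st <- rep(KN_STATES, length.out = n)
  df <- data.frame(sample_id = samples, state = st,
                   stringsAsFactors = FALSE)
  for (b in KN_BIOINDICATORS) df[[b]] <- round(runif(n, 1, 5), 3)
  as_sample_info(df)
}

tiny_gwas <- function(n = 10, seed = 3, chrom = "chr1") {
  set.seed(seed)
  b <- rnorm(n, 0, 0.1)
  as_gwas_summary(data.frame(
    snp_id = sprintf("snp%03d", seq_len(n)), chrom = chrom,
    pos = sort(sample.int(5e5, n)), effect_b = b,
    pvalue = 2 * pnorm(-abs(b) / 0.1), stringsAsFactors = FALSE))
}

# small but complete synthetic world shared by unit tests (cheap: ~0.1 s)
small_cfg <- function(seed = 1, ...) {
  synth_config(seed = seed, n_genes = 400,
               module_sizes = c(60, 50, 40), n_snps = 4000, n_chroms = 3,
               count_depth = 5e5, ...)
}

# brute-force SNP-to-window overlap oracle: O(n_snps * n_windows) loops,
# 0-based half-open semantics spelled out independently of the package
oracle_snps_in_windows <- function(chrom, pos, windows) {
  out <- logical(length(pos))
  for (i in seq_along(pos)) {
    p0 <- pos[i] - 1  # 0-based
    for (j in seq_len(nrow(windows))) {
      if (chrom[i] == windows$chrom[j] &&
          p0 >= windows$start[j] && p0 < windows$end[j]) {
        out[i] <- TRUE
        break
      }
    }
  }
  out
}

# hand TOM oracle: direct triple loop over the formula
oracle_tom <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { tom[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# exhaustive hypergeometric upper-tail oracle by enumerating all draws
oracle_hyper <- function(universe_n, set_n, module_n, overlap) {
  draws <- combn(universe_n, module_n)
  succ <- seq_len(set_n)              # wlog the first set_n items
  hits <- apply(draws, 2, function(d) sum(d %in% succ) >= overlap)
  mean(hits)
}
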