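# Expression preprocessing: TPM, expression/variability filters, and a
# variance-stabilizing normalization feeding the network stage.

#' Transcripts-per-million normalization
#'
#' Each count is divided by gene length in kilobases (reads per kilobase,
#' RPK); RPK values are divided by the sample's RPK sum over 1e6 (the
#' "per million" scaling factor), so every sample column sums to 1e6.
#'
#' @param counts gene-by-sample `count_matrix`.
#' @param annot `gene_annotation` covering every gene in `counts`.
#' @return numeric matrix of TPM values with attribute `scale = "TPM"`.
#' @export
compute_tpm <- function(counts, annot) {
  genes <- rownames(counts)
  miss <- setdiff(genes, annot$gene_id)
  if (length(miss)) stop("genes missing from annotation: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  len_kb <- annot$length_bp[match(genes, annot$gene_id)] / 1000
  if (any(len_kb <= 0)) stop("non-positive gene lengths")
  rpk <- unclass(counts) / len_kb
  depth <- colSums(rpk)
  zero <- depth == 0
  if (any(zero)) stop("zero-depth sample(s): ",
                      paste(colnames(counts)[zero], collapse = ", "))
  tpm <- sweep(rpk, 2, depth / 1e6, "/")
  attr(tpm, "scale") <- "TPM"
  tpm
}

#' Expression and variability gene filter
#'
#' Keeps genes expressed above `min_tpm` (strictly) in at least
#' `min_samples` samples, then requires the median absolute deviation of
#' `log2(TPM + 1)` across samples to be strictly above both an absolute
#' floor (`mad_floor`, default 0.01) and the `mad_quantile` empirical
#' quantile of MAD among the expression-passing genes (default 0.25, i.e.
#' the top 75% of MAD survive). MAD is computed without the 1.4826
#' normal-consistency constant; the choice is recorded in the report.
#'
#' @param tpm TPM matrix from [compute_tpm()].
#' @param min_tpm,min_samples expression threshold (strict) and the minimum
#'   number of samples that must exceed it.
#' @param mad_quantile quantile of MAD below which genes are dropped.
#' @param mad_floor absolute MAD floor.
#' @return list: `genes` (kept gene ids, input order) and `report`
#'   (a `filter_report` list with counts, per-gene MAD and thresholds).
#' @export
filter_genes <- function(tpm, min_tpm = 1, min_samples = 1,
                         mad_quantile = 0.25, mad_floor = 0.01) {
  if (!identical(attr(tpm, "scale"), "TPM"))
    stop("filter_genes expects a TPM-scaled matrix")
  expressed <- rowSums(tpm > min_tpm) >= min_samples
  logx <- log2(tpm + 1)
  mad_all <- apply(logx, 1, function(v) stats::median(abs(v - stats::median(v))))
  mad_cut <- if (any(expressed))
    stats::quantile(mad_all[expressed], mad_quantile, names = FALSE) else NA_real_
  keep <- expressed & mad_all > mad_floor & mad_all > mad_cut
  if (!any(keep))
    stop("all genes filtered out; lower min_tpm/mad_floor or mad_quantile")
  report <- list(n_input_genes = nrow(tpm),
                 n_pass_expression = sum(expressed),
                 n_pass_mad = sum(keep),
                 mad = mad_all,
                 thresholds = c(min_tpm = min_tpm, min_samples = min_samples,
                                mad_floor = mad_floor,
                                mad_quantile = mad_quantile,
                                mad_quantile_value = mad_cut),
                 mad_scale = "log2(TPM+1), no 1.4826 consistency constant")
  class(report) <- "filter_report"
  list(genes = rownames(tpm)[keep], report = report)
}

#' Median-of-ratios size factors
#'
#' Reference = per-gene geometric mean over samples, computed on genes with
#' all-positive counts; a sample's factor is the median of its count/reference
#' ratios. Falls back to total-count factors (normalized to geometric mean 1)
#' with a warning when no gene is all-positive.
#'
#' @param counts gene-by-sample count matrix.
#' @return numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  m <- unclass(counts)
  allpos <- rowSums(m > 0) == ncol(m)
  if (!any(allpos)) {
    warning("no gene with all-positive counts; using total-count size factors")
    tot <- colSums(m)
    return(tot / exp(mean(log(tot))))
  }
  lg <- log(m[allpos, , drop = FALSE])
  ref <- rowMeans(lg)                      # log geometric mean
  apply(lg, 2, function(col) exp(stats::median(col - ref)))
}

#' Variance-stabilizing normalization of counts
#'
#' Median-of-ratios size-factor scaling followed by `log2(x + 1)`. This is a
#' deliberate simplification of a dispersion-fit VST: the network stage only
#' needs approximate homoskedasticity, which the log transform of
#' depth-normalized counts provides. The returned matrix carries the
#' mean-vs-SD trend slope before and after (attribute `"trend_slopes"`) so
#' the flattening can be inspected.
#'
#' @param counts gene-by-sample `count_matrix`.
#' @param kept_genes optional subset of gene ids (filter output).
#' @return numeric matrix (genes x samples) with attribute `scale = "vst"`.
#' @export
vst_normalize <- function(counts, kept_genes = NULL) {
  if (ncol(counts) < 2) stop("vst_normalize needs >= 2 samples")
  sf <- size_factors(counts)
  m <- unclass(counts)
  if (!is.null(kept_genes)) {
    miss <- setdiff(kept_genes, rownames(m))
    if (length(miss)) stop("kept_genes absent from counts: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    m <- m[kept_genes, , drop = FALSE]
  }
  norm <- sweep(m, 2, sf, "/")
  out <- log2(norm + 1)
  attr(out, "scale") <- "vst"
  attr(out, "size_factors") <- sf
  attr(out, "trend_slopes") <- c(before = mean_sd_trend_slope(log2(m + 1)),
                                 after = mean_sd_trend_slope(out))
  out
}

# slope of per-gene SD against rank of per-gene mean; a homoskedastic matrix
# has slope near 0. Used as a diagnostic, not a test statistic.
mean_sd_trend_slope <- function(x) {
  mu <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  r <- rank(mu) / length(mu)
  if (stats::sd(r) == 0 || stats::sd(s) == 0) return(0)
  unname(stats::coef(stats::lm(s ~ r))[2])
}
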