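# Readers/writers for all on-disk artifacts. All tables are TSV with
# '#'-prefixed metadata lines; coordinates are BED-convention 0-based
# half-open internally (GWAS positions are read 1-based and converted at the
# point of interval arithmetic). No science in this file.

read_tsv_skip_meta <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "", ...)
}

write_tsv_with_meta <- function(df, path, meta = kn_meta_lines()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

## ---- CountMatrix ----------------------------------------------------------

#' Validate a count matrix
#'
#' A count matrix is a gene-by-sample integer matrix with unique, non-empty
#' row (gene) and column (sample) names and non-negative integral entries.
#'
#' @param counts numeric matrix, genes in rows, samples in columns.
#' @return the matrix, invisibly, with class `count_matrix` prepended.
#' @export
as_count_matrix <- function(counts) {
  stopifnot(is.matrix(counts))
  g <- rownames(counts); s <- colnames(counts)
  if (is.null(g) || is.null(s)) stop("count matrix must have gene and sample names")
  if (anyDuplicated(g)) stop("duplicate gene ids: ",
                             paste(unique(g[duplicated(g)]), collapse = ", "))
  if (anyDuplicated(s)) stop("duplicate sample ids: ",
                             paste(unique(s[duplicated(s)]), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(counts))
    stop(sprintf("counts must be non-negative integers; offending cell gene='%s' sample='%s' value=%s",
                 g[i[1]], s[i[2]], format(counts[bad[1]])))
  }
  storage.mode(counts) <- "double"
  class(counts) <- c("count_matrix", class(counts))
  invisible(counts)
}

#' Read a gene-by-sample count matrix from TSV
#'
#' First column holds gene ids, header row holds sample ids. Lines starting
#' with `#` are metadata and skipped. Structural problems (duplicate ids,
#' negative or fractional counts) are hard errors naming the offender.
#'
#' @param path TSV file path.
#' @return a validated `count_matrix`.
#' @export
read_count_matrix <- function(path) {
  df <- read_tsv_skip_meta(path)
  if (ncol(df) < 2) stop("count matrix needs a gene-id column plus >=1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate gene ids in ", path, ": ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  as_count_matrix(m)
}

#' Write a count matrix to TSV
#' @param counts `count_matrix` (or plain named matrix).
#' @param path output file.
#' @param meta character vector of `#` metadata lines.
#' @export
write_count_matrix <- function(counts, path, meta = kn_meta_lines()) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write_tsv_with_meta(df, path, meta)
}

## ---- GeneAnnotation -------------------------------------------------------

#' Read gene annotation (coordinates + length) from TSV
#'
#' Columns: gene_id, chrom, start, end, length_bp. Coordinates are 0-based
#' half-open; `length_bp` is the TPM length denominator (single flat gene
#' model, length = end - start unless stated otherwise in the file).
#'
#' @param path TSV file path.
#' @return data.frame with class `gene_annotation`.
#' @export
read_gene_annotation <- function(path) {
  df <- read_tsv_skip_meta(path)
  as_gene_annotation(df)
}

#' @rdname read_gene_annotation
#' @param df data.frame with the annotation columns.
#' @export
as_gene_annotation <- function(df) {
  need <- c("gene_id", "chrom", "start", "end", "length_bp")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in annotation: ",
    paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  if (any(df$start >= df$end)) stop("annotation rows with start >= end: ",
    paste(df$gene_id[df$start >= df$end], collapse = ", "))
  if (any(df$length_bp <= 0)) stop("annotation rows with length_bp <= 0")
  class(df) <- c("gene_annotation", class(df))
  df
}

#' @rdname read_gene_annotation
#' @param annot annotation data.frame.
#' @param meta metadata lines.
#' @export
write_gene_annotation <- function(annot, path, meta = kn_meta_lines()) {
  write_tsv_with_meta(as.data.frame(annot), path, meta)
}

## ---- SampleInfo -----------------------------------------------------------

#' Physiological states of the transition-cow design
#' @export
KN_STATES <- c("H_Pre", "H_Post", "K_Pre", "K_Post")

#' The seven plasma bio-indicators carried in sample metadata
#' @export
KN_BIOINDICATORS <- c("BHBA", "TC", "TG", "HDL", "LDL", "Ca", "INS")

#' Read sample metadata (state + bio-indicators) from TSV
#'
#' Columns: sample_id, state (one of H_Pre, H_Post, K_Pre, K_Post) and the
#' seven bio-indicators BHBA, TC, TG, HDL, LDL, Ca, INS (numeric; NA allowed).
#'
#' @param path TSV file path.
#' @return data.frame with class `sample_info`.
#' @export
read_sample_info <- function(path) as_sample_info(read_tsv_skip_meta(path))

#' @rdname read_sample_info
#' @param df data.frame to validate.
#' @export
as_sample_info <- function(df) {
  need <- c("sample_id", "state", KN_BIOINDICATORS)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample info missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample info")
  bad <- setdiff(unique(df$state), KN_STATES)
  if (length(bad)) stop("unknown states: ", paste(bad, collapse = ", "))
  for (b in KN_BIOINDICATORS) {
    v <- df[[b]]
    if (!is.numeric(v) || any(is.infinite(v)))
      stop("bio-indicator ", b, " must be finite numeric or NA")
  }
  class(df) <- c("sample_info", class(df))
  df
}

#' @rdname read_sample_info
#' @param info sample info data.frame.
#' @param meta metadata lines.
#' @export
write_sample_info <- function(info, path, meta = kn_meta_lines()) {
  write_tsv_with_meta(as.data.frame(info), path, meta)
}

## ---- GwasSummary ----------------------------------------------------------

#' Read single-marker GWAS summary statistics from TSV
#'
#' Columns: snp_id, chrom, pos (1-based), effect_b (marker effect estimate),
#' pvalue in (0, 1]. Records are sorted by (chrom, pos) on load; unsorted
#' input is sorted silently with a logged notice. p-values outside (0, 1]
#' are rejected (a permutation or LMM cannot produce an exact zero).
#'
#' @param path TSV file path.
#' @return data.frame with class `gwas_summary`, genome-ordered.
#' @export
read_gwas_summary <- function(path) {
  df <- read_tsv_skip_meta(path)
  as_gwas_summary(df, source = path)
}

#' @rdname read_gwas_summary
#' @param df data.frame to validate.
#' @param source label used in messages.
#' @export
as_gwas_summary <- function(df, source = "gwas summary") {
  need <- c("snp_id", "chrom", "pos", "effect_b", "pvalue")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(source, " missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$effect_b))) stop(source, ": non-finite effect_b")
  if (any(df$pvalue <= 0 | df$pvalue > 1))
    stop(source, ": p-values must lie in (0, 1]; offending snp_id: ",
         paste(utils::head(df$snp_id[df$pvalue <= 0 | df$pvalue > 1], 5), collapse = ", "))
  ord <- order(df$chrom, df$pos)
  if (!identical(ord, seq_len(nrow(df)))) {
    kn_log("sorting ", source, " by (chrom, pos)")
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
  }
  key <- paste(df$chrom, df$pos, df$snp_id)
  if (anyDuplicated(key)) stop(source, ": duplicate (chrom, pos, snp_id) records")
  class(df) <- c("gwas_summary", class(df))
  df
}

#' @rdname read_gwas_summary
#' @param gwas gwas summary data.frame.
#' @param meta metadata lines.
#' @export
write_gwas_summary <- function(gwas, path, meta = kn_meta_lines()) {
  write_tsv_with_meta(as.data.frame(gwas), path, meta)
}

## ---- ModulePartition ------------------------------------------------------

#' Reserved label for genes not assigned to any co-expression module
#' @export
KN_UNASSIGNED <- "unassigned"

#' Read / write a gene-to-module partition
#'
#' Two-column TSV (gene, module); the reserved module label is
#' `"unassigned"`. In memory a partition is a named character vector
#' (names = gene ids, values = module labels).
#'
#' @param path TSV file path.
#' @return named character vector.
#' @export
read_module_partition <- function(path) {
  df <- read_tsv_skip_meta(path)
  stats::setNames(as.character(df$module), df$gene)
}

#' @rdname read_module_partition
#' @param partition named character vector gene -> module label.
#' @param meta metadata lines.
#' @export
write_module_partition <- function(partition, path, meta = kn_meta_lines()) {
  write_tsv_with_meta(data.frame(gene = names(partition),
                                 module = unname(partition)), path, meta)
}

## ---- BED export -----------------------------------------------------------

#' Export module windows as BED6
#'
#' Writes the merged, flank-extended gene windows of each module as BED6
#' (0-based half-open, name = module, score = 0, strand = '.').
#'
#' @param windows data.frame from [module_windows()].
#' @param path output BED path.
#' @export
write_module_windows_bed <- function(windows, path) {
  bed <- data.frame(chrom = windows$chrom, start = windows$start,
                    end = windows$end, name = windows$module,
                    score = 0L, strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
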