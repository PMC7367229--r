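# Internal helpers shared across stages: logging, metadata headers, label
# palette, adjusted Rand index.

kn_version <- function() as.character(utils::packageVersion("ketonet"))

#' @keywords internal
kn_log <- function(..., file = NULL) {
  msg <- paste0("[ketonet] ", paste0(..., collapse = ""))
  message(msg)
  if (!is.null(file)) cat(msg, "\n", file = file, append = TRUE, sep = "")
  invisible(msg)
}

# FNV-1a 32-bit hash of a character scalar; stable across platforms, used to
# stamp output tables with a config fingerprint without a digest dependency.
kn_hash <- function(x) {
  stopifnot(is.character(x))
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256                      # xor only touches the low byte
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply without exceeding double's exact-integer range
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

# Standard metadata block written at the top of every result table.
kn_meta_lines <- function(seed = NA, config_hash = NA, extra = character()) {
  c(
    sprintf("# ketonet_version=%s", kn_version()),
    sprintf("# config_hash=%s", ifelse(is.na(config_hash), "none", config_hash)),
    sprintf("# seed=%s", ifelse(is.na(seed), "none", format(seed))),
    extra
  )
}

# WGCNA-style color labels, assigned to modules in decreasing size order.
# "unassigned" is reserved for the leftover (grey-like) module.
kn_module_palette <- function(n) {
  base <- c(
    "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue"
  )
  if (n <= length(base)) base[seq_len(n)] else
    c(base, sprintf("module%02d", seq_len(n - length(base)) + length(base)))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same objects.
#' Used to score module recovery against planted ground truth; 1 means
#' identical partitions (up to label names), 0 is the expectation under
#' independent random labelings.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxidx <- (sum_a + sum_b) / 2
  if (maxidx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maxidx - expected)
}

# Pearson correlation p-value from r and n (two-sided, t with n-2 df).
cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tstat), df = n - 2)
}
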