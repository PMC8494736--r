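# Shared helpers: canonical pair ordering and pair indexing.
#
# All pairwise results in the package enumerate unordered gene pairs in
# "upper triangle, column-major" order: for genes g_1 < g_2 < ... (alphabetical),
# pairs are (g_1,g_2), (g_1,g_3), (g_2,g_3), (g_1,g_4), ...  This matches the
# 0-based flat index j*(j-1)/2 + i used by the compiled code.

#' Enumerate all unordered gene pairs in canonical order
#'
#' @param genes character vector of gene symbols (assumed already in canonical,
#'   i.e. alphabetical, order as produced by [build_matrix()]).
#' @return data.frame with columns `gene_a`, `gene_b` (`gene_a` precedes
#'   `gene_b` in `genes`), one row per unordered pair, in the same order as
#'   the flat pair index used throughout the package.
#' @export
pair_grid <- function(genes) {
  n <- length(genes)
  if (n < 2L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- which(upper.tri(matrix(0L, n, n)))  # column-major upper triangle
  i <- ((idx - 1L) %% n) + 1L
  j <- ((idx - 1L) %/% n) + 1L
  data.frame(gene_a = genes[i], gene_b = genes[j], stringsAsFactors = FALSE)
}

#' Canonically order a two-column pair table
#'
#' Swaps `gene_a`/`gene_b` where needed so that `gene_a < gene_b`
#' lexicographically; used when merging candidate tables from sources that may
#' list pairs in either orientation.
#'
#' @param pairs data.frame with character columns `gene_a` and `gene_b`.
#' @return the same data.frame with the two columns canonically ordered.
#' @export
canonical_pairs <- function(pairs) {
  swap <- pairs$gene_a > pairs$gene_b
  if (any(swap)) {
    tmp <- pairs$gene_a[swap]
    pairs$gene_a[swap] <- pairs$gene_b[swap]
    pairs$gene_b[swap] <- tmp
  }
  pairs
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

`%||%` <- function(x, y) if (is.null(x)) y else x
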