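# The binary gene x sample mutation matrix: the single substrate of all tests.

#' Construct a mutation matrix object
#'
#' A `mutation_matrix` is a binary integer matrix with genes as rows and
#' samples as columns, plus a per-sample cancer-type label carried as an
#' attribute. Rows and columns are kept in canonical (alphabetical) order so
#' that all downstream iteration and output are deterministic.
#'
#' @param incidence integer/numeric matrix of 0/1 entries, genes in rows
#'   (rownames) and samples in columns (colnames).
#' @param cancer_type named character vector mapping every sample to its
#'   cancer-type label; a single unnamed value is recycled to all samples.
#' @return an object of class `mutation_matrix`.
#' @export
mutation_matrix <- function(incidence, cancer_type) {
  if (is.null(rownames(incidence)) || is.null(colnames(incidence)))
    stop("incidence must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(incidence)) || anyDuplicated(colnames(incidence)))
    stop("duplicate gene or sample names in incidence matrix")
  storage.mode(incidence) <- "integer"
  if (!all(incidence %in% c(0L, 1L)))
    stop("incidence entries must be exactly 0 or 1")
  if (length(cancer_type) == 1L && is.null(names(cancer_type)))
    cancer_type <- setNames(rep(cancer_type, ncol(incidence)), colnames(incidence))
  if (!all(colnames(incidence) %in% names(cancer_type)))
    stop("every sample needs a cancer-type label")
  incidence <- incidence[order(rownames(incidence)), order(colnames(incidence)),
                         drop = FALSE]
  attr(incidence, "cancer_type") <-
    cancer_type[colnames(incidence)]
  class(incidence) <- c("mutation_matrix", class(incidence))
  incidence
}

#' Cancer-type labels of a mutation matrix
#' @param m a `mutation_matrix`.
#' @return named character vector, one label per sample (column).
#' @export
cancer_types <- function(m) attr(m, "cancer_type")

#' Restrict a mutation matrix to a subset of samples
#'
#' @param m a `mutation_matrix`.
#' @param samples character vector of sample IDs to keep.
#' @return a `mutation_matrix` over the selected samples (genes untouched;
#'   apply [prune_matrix()] afterwards if post-filter invariants are needed).
#' @export
subset_samples <- function(m, samples) {
  samples <- intersect(colnames(m), samples)
  mutation_matrix(unclass(m)[, samples, drop = FALSE],
                  cancer_types(m)[samples])
}

#' @export
print.mutation_matrix <- function(x, ...) {
  ct <- table(cancer_types(x))
  cat(sprintf("mutation_matrix: %d genes x %d samples, %d entries set\n",
              nrow(x), ncol(x), sum(x)))
  cat("cancer types:", paste(sprintf("%s (%d)", names(ct), ct), collapse = ", "),
      "\n")
  invisible(x)
}

block_ids <- function(m) {
  # 0-based block index per sample, one block per cancer type
  ct <- cancer_types(m)
  as.integer(factor(ct, levels = sort(unique(ct)))) - 1L
}

#' Write / read a mutation matrix as TSV
#'
#' The matrix is serialized with genes as rows and samples as columns plus a
#' sidecar table mapping each sample to its cancer type.
#'
#' @param m a `mutation_matrix`.
#' @param path output TSV path for the 0/1 matrix.
#' @param metadata_path output TSV path for the sample -> cancer-type map.
#' @return `path`, invisibly.
#' @export
write_mutation_matrix <- function(m, path, metadata_path) {
  df <- data.frame(gene = rownames(m), unclass(m)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = colnames(m), cancer_type = cancer_types(m),
                     stringsAsFactors = FALSE)
  write.table(meta, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mutation_matrix
#' @export
read_mutation_matrix <- function(path, metadata_path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
  inc <- as.matrix(df[, -1, drop = FALSE])
  rownames(inc) <- df$gene
  mutation_matrix(inc, setNames(meta$cancer_type, meta$sample_id))
}
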