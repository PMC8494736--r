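# Fixed-margin matrix-permutation null model and empirical P-values.
#
# The null hypothesis conditions on all row (gene) and column (sample) sums
# of the observed mutation matrix: permuted matrices are drawn from the space
# of binary matrices with identical margins via curveball trades, blockwise
# per cancer type when requested, and per-pair null co-occurrence counts are
# accumulated as histograms. The empirical P-values use the +1/+1 estimator
#   p_co = (1 + #{i : co_i >= co_obs}) / (1 + N)
#   p_me = (1 + #{i : co_i <= co_obs}) / (1 + N)
# which avoids P-values of zero; hence p in [1/(1+N), 1].

#' Observed pairwise co-occurrence statistics
#'
#' @param m a [mutation_matrix()].
#' @return data.frame, one row per unordered gene pair in canonical order,
#'   with columns `gene_a`, `gene_b`, `co_obs` (samples with both genes
#'   mutated), `me_obs` (samples with exactly one mutated), `margin_a`,
#'   `margin_b`. Empty for matrices with fewer than two genes.
#' @export
count_pair_stats <- function(m) {
  genes <- rownames(m)
  pairs <- pair_grid(genes)
  if (nrow(pairs) == 0) {
    pairs$co_obs <- pairs$me_obs <- integer()
    pairs$margin_a <- pairs$margin_b <- integer()
    return(pairs)
  }
  margins <- rowSums(m)
  pairs$co_obs <- as.integer(cpp_co_counts(unclass(m)))
  pairs$margin_a <- as.integer(margins[pairs$gene_a])
  pairs$margin_b <- as.integer(margins[pairs$gene_b])
  pairs$me_obs <- pairs$margin_a + pairs$margin_b - 2L * pairs$co_obs
  pairs[, c("gene_a", "gene_b", "co_obs", "me_obs", "margin_a", "margin_b")]
}

#' Draw one fixed-margin permutation of a mutation matrix
#'
#' Applies a configured number of curveball trades (independently
#' within each cancer-type block) and returns the resulting matrix, which has
#' exactly the same per-gene and per-sample margins as the input.
#'
#' @param m a [mutation_matrix()].
#' @param n_trades number of trades (attempted gene-pair redeals); default 5 times the number of
#'   1-entries, enough to decorrelate the output from the input.
#' @param block_by_cancer_type permute within cancer types (`TRUE`) or the
#'   whole matrix as one block (`FALSE`, default).
#' @return a permuted [mutation_matrix()].
#' @export
sample_fixed_margin_matrix <- function(m, n_trades = 5 * sum(m),
                                       block_by_cancer_type = FALSE) {
  blocks <- if (block_by_cancer_type) block_ids(m) else
    integer(ncol(m))
  nb <- max(blocks) + 1L
  out <- cpp_curveball_permute(unclass(m), blocks, nb, n_trades)
  mutation_matrix(out, cancer_types(m))
}

#' Build the permutation null ensemble
#'
#' Generates `N` fixed-margin permutations of the matrix (one curveball chain
#' per cancer-type block when `block_by_cancer_type = TRUE`, as used in
#' pan-cancer mode), accumulating per-pair histograms of null co-occurrence
#' counts. A random reservoir of `n_pseudo` permutations keeps its full
#' per-pair co-count vectors so they can later be scored as pseudo-observed
#' matrices for the empirical FDR null.
#'
#' @param m a [mutation_matrix()].
#' @param N number of permutations (desk-scale default `1e4`; the full-scale
#'   analysis uses `1e6`).
#' @param block_by_cancer_type permute each cancer type's sub-matrix
#'   independently; with a single cancer type this is equivalent to `FALSE`.
#' @param n_pseudo size of the pseudo-observed reservoir (default 100).
#' @param burn_in trades before the first saved permutation
#'   (default 5 x number of 1-entries).
#' @param thin trades between saved permutations (default 1 x
#'   number of 1-entries).
#' @return an object of class `null_ensemble`.
#' @export
build_null_ensemble <- function(m, N = 1e4, block_by_cancer_type = FALSE,
                                n_pseudo = 100, burn_in = NULL, thin = NULL) {
  N <- as.integer(N)
  if (N < 1) stop("N must be at least 1")
  n_pseudo <- min(as.integer(n_pseudo), N)
  ones <- sum(m)
  burn_in <- burn_in %||% (5 * ones)
  thin <- thin %||% ones
  blocks <- if (block_by_cancer_type) block_ids(m) else integer(ncol(m))
  nb <- max(blocks) + 1L
  max_co <- max(rowSums(m))
  pseudo_idx <- sort(sample.int(N, n_pseudo))
  res <- cpp_perm_null(unclass(m), blocks, nb, N, burn_in, thin,
                       pseudo_idx, max_co)
  structure(list(genes = rownames(m), N = N, hist = res$hist,
                 pseudo_co = res$pseudo_co, pseudo_idx = pseudo_idx,
                 max_co = max_co,
                 block_by_cancer_type = block_by_cancer_type,
                 burn_in = burn_in, thin = thin),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf(paste0("null_ensemble: %d genes, N = %d permutations, ",
                     "%d pseudo-observed, blockwise = %s\n"),
              length(x$genes), x$N, length(x$pseudo_idx),
              x$block_by_cancer_type))
  invisible(x)
}

# tail counts against the per-pair histograms for a vector of observed
# co-counts (one per pair, canonical order)
ensemble_tail_counts <- function(ensemble, co) {
  hist <- ensemble$hist
  np <- nrow(hist)
  stopifnot(length(co) == np)
  cum <- t(apply(hist, 1, cumsum))
  col <- pmin(co, ensemble$max_co) + 1L
  le <- cum[cbind(seq_len(np), col)]
  ge <- ensemble$N - le + hist[cbind(seq_len(np), col)]
  list(ge = ge, le = le)
}

#' Empirical P-values from a null ensemble
#'
#' Applies the +1/+1 estimator to the per-pair null co-occurrence histograms.
#'
#' @param pairs pair statistics from [count_pair_stats()] on the same matrix
#'   (same gene order) the ensemble was built from.
#' @param ensemble a `null_ensemble` from [build_null_ensemble()].
#' @return `pairs` with columns `p_co` and `p_me` appended.
#' @export
empirical_pvalues <- function(pairs, ensemble) {
  if (!identical(paste(pairs$gene_a, pairs$gene_b),
                 paste(pair_grid(ensemble$genes)$gene_a,
                       pair_grid(ensemble$genes)$gene_b)))
    stop("pairs do not match the ensemble's gene set/order")
  tails <- ensemble_tail_counts(ensemble, pairs$co_obs)
  pairs$p_co <- (1 + tails$ge) / (1 + ensemble$N)
  pairs$p_me <- (1 + tails$le) / (1 + ensemble$N)
  pairs
}

#' Null P-value sets from pseudo-observed permutations
#'
#' Each matrix in the ensemble's pseudo-observed reservoir is scored against
#' the full ensemble with the same +1/+1 estimator (the reservoir matrices
#' are part of the ensemble, so each is scored including itself, shifting p
#' by at most 1/(1+N)). The resulting P-values form the null sets feeding the
#' empirical FDR, one multiset per direction.
#'
#' @param ensemble a `null_ensemble` from [build_null_ensemble()].
#' @return list with numeric vectors `co` and `me` of length
#'   `n_pairs * n_pseudo`.
#' @export
null_pvalue_set <- function(ensemble) {
  np <- nrow(ensemble$hist)
  n_pseudo <- ncol(ensemble$pseudo_co)
  co <- me <- matrix(NA_real_, np, n_pseudo)
  for (j in seq_len(n_pseudo)) {
    tails <- ensemble_tail_counts(ensemble, ensemble$pseudo_co[, j])
    co[, j] <- (1 + tails$ge) / (1 + ensemble$N)
    me[, j] <- (1 + tails$le) / (1 + ensemble$N)
  }
  list(co = as.numeric(co), me = as.numeric(me))
}

#' Run the full permutation test on a mutation matrix
#'
#' Convenience wrapper chaining [count_pair_stats()],
#' [build_null_ensemble()], [empirical_pvalues()], [null_pvalue_set()] and
#' [empirical_fdr()]: every gene pair is tested in both directions and
#' annotated with its empirical P-value, FDR and q-value.
#'
#' @inheritParams build_null_ensemble
#' @param mode label recorded in the outcome table (`"per-type"` or `"pan"`);
#'   defaults to `"pan"` when the matrix holds more than one cancer type.
#' @return a test-outcome data.frame with one row per (pair, direction):
#'   columns `gene_a`, `gene_b`, `direction` (`"co"`/`"me"`), `cancer_type`,
#'   `mode`, `test`, `p`, `fdr`, `q`, `co_obs`, `me_obs`, `margin_a`,
#'   `margin_b`, `n_permutations`.
#' @export
permutation_test <- function(m, N = 1e4, block_by_cancer_type = NULL,
                             n_pseudo = 100, burn_in = NULL, thin = NULL,
                             mode = NULL) {
  types <- sort(unique(cancer_types(m)))
  block_by_cancer_type <- block_by_cancer_type %||% (length(types) > 1)
  mode <- mode %||% if (length(types) > 1) "pan" else "per-type"
  ct_label <- if (length(types) > 1) "PAN" else types
  pairs <- count_pair_stats(m)
  if (nrow(pairs) == 0) stop("fewer than 2 genes; nothing to test")
  ensemble <- build_null_ensemble(m, N = N,
                                  block_by_cancer_type = block_by_cancer_type,
                                  n_pseudo = n_pseudo, burn_in = burn_in,
                                  thin = thin)
  pairs <- empirical_pvalues(pairs, ensemble)
  s_null <- null_pvalue_set(ensemble)
  fdr_co <- empirical_fdr(pairs$p_co, s_null$co)
  fdr_me <- empirical_fdr(pairs$p_me, s_null$me)
  base <- pairs[, c("gene_a", "gene_b", "co_obs", "me_obs",
                    "margin_a", "margin_b")]
  out <- rbind(
    cbind(base, direction = "co", p = pairs$p_co, fdr = fdr_co$fdr,
          q = fdr_co$q, stringsAsFactors = FALSE),
    cbind(base, direction = "me", p = pairs$p_me, fdr = fdr_me$fdr,
          q = fdr_me$q, stringsAsFactors = FALSE))
  out$cancer_type <- ct_label
  out$mode <- mode
  out$test <- "permutation"
  out$n_permutations <- ensemble$N
  rownames(out) <- NULL
  out[, c("gene_a", "gene_b", "direction", "cancer_type", "mode", "test",
          "p", "fdr", "q", "co_obs", "me_obs", "margin_a", "margin_b",
          "n_permutations")]
}
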