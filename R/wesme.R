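# Weighted-resampling (WeSME-style) genetic interaction test.
#
# Instead of permuting the whole matrix, each gene's mutated-sample set is
# redrawn without replacement with per-sample probabilities proportional to
# mutation load (number of mutated genes), within each cancer type; null
# co-occurrence counts are pooled over types. An adaptive ladder keeps the
# number of resamples small for clearly non-significant pairs and escalates
# (to a cap of 10,000) only for candidates with a low interim P-value. The
# empirical FDR uses null P-values obtained by scoring fixed-margin permuted
# matrices with the same test, stratified into mutation-rate bin combinations
# (low/low, low/high, high/high). Because a fixed-margin permutation changes
# neither the gene margins nor the sample loads, all scored matrices share
# one pool of null resampling draws (accumulated as per-pair co-count
# histograms with a snapshot at every ladder rung); each matrix still walks
# its own escalation path and reads its P-values from the snapshot of the
# rung where that path stopped.

#' Per-sample resampling weights
#'
#' Weight of a sample equals its mutation load divided by the total load of
#' its cancer type, so weights sum to one within each type.
#'
#' @param m a post-filter [mutation_matrix()].
#' @return named numeric vector of weights, one per sample.
#' @export
compute_sample_weights <- function(m) {
  load <- colSums(m)
  ct <- cancer_types(m)
  totals <- tapply(load, ct, sum)
  setNames(as.numeric(load / totals[ct]), colnames(m))
}

#' Assign genes to mutation-rate bins
#'
#' A gene is `"high"` when it is mutated in at least `threshold` (default 2%)
#' of samples (boundary inclusive), else `"low"`. In pan-cancer mode the rate
#' is the pooled rate over all samples.
#'
#' @param m a [mutation_matrix()].
#' @param threshold fraction of samples mutated separating the bins.
#' @return named character vector (`"low"`/`"high"`), one entry per gene.
#' @export
assign_rate_bins <- function(m, threshold = 0.02) {
  rate <- rowSums(m) / ncol(m)
  setNames(ifelse(rate >= threshold, "high", "low"), rownames(m))
}

#' Resample one gene's mutated-sample set
#'
#' Draws `k` distinct samples with probability proportional to their weights
#' (weighted sampling without replacement, sequential-renormalization
#' distribution). Exposed mainly for testing; the bulk resampling runs in
#' compiled code with the identical distribution.
#'
#' @param k gene margin (number of samples to draw).
#' @param weights named numeric weight vector (one cancer type's samples).
#' @return character vector of `k` sampled sample IDs.
#' @export
sample_gene_null <- function(k, weights) {
  if (k == 0) return(character())
  pos <- sum(weights > 0)
  if (k > pos) stop("gene margin exceeds number of positive-weight samples")
  if (k == length(weights)) return(names(weights))
  keys <- stats::rexp(length(weights)) / weights
  names(weights)[order(keys)[seq_len(k)]]
}

wesme_rate_bin_keys <- function(bins, pairs) {
  a <- bins[pairs$gene_a]
  b <- bins[pairs$gene_b]
  paste(pmin(a, b), pmax(a, b), sep = "-")  # high-high, high-low, low-low
}

# Shared precomputation for the compiled resampler.
wesme_setup <- function(m, bin_threshold) {
  types <- sort(unique(cancer_types(m)))
  ct <- cancer_types(m)
  margins <- vapply(types, function(ty)
    as.integer(rowSums(m[, ct == ty, drop = FALSE])), integer(nrow(m)))
  dim(margins) <- c(nrow(m), length(types))
  w <- compute_sample_weights(m)
  pairs <- count_pair_stats(m)
  list(types = types, margins = margins,
       weights_by_type = lapply(types, function(ty) w[ct == ty]),
       samples_of_type = lapply(types, function(ty) which(ct == ty) - 1L),
       pairs = pairs,
       bins = assign_rate_bins(m, bin_threshold),
       margin_sum = pairs$margin_a + pairs$margin_b)
}

# Score a set of co-count vectors (columns of co_mat) against one shared
# pool of adaptive null draws.
wesme_score_ensemble <- function(su, co_mat, ladder, escalate_num,
                                 min_co_pretest, min_me_pretest) {
  cpp_wesme_ensemble(su$margins, su$weights_by_type, su$samples_of_type,
                     co_mat, as.integer(su$margin_sum), as.integer(ladder),
                     escalate_num, as.integer(min_co_pretest),
                     as.integer(min_me_pretest))
}

#' Mutation-rate-binned null P-value sets
#'
#' Scores `n_null_perms` fixed-margin curveball permutations of the matrix
#' (blockwise per cancer type) with the weighted-resampling test and files
#' every pair's null P-value under the bin-pair key of its genes'
#' original-matrix mutation-rate bins (low-low, low-high or high-high). All
#' tested pairs contribute (no P-value pre-filter); the same pre-test count
#' filters as on the observed side are applied within each permuted matrix.
#'
#' @inheritParams wesme_test
#' @return list of two data.frames `co` and `me`, each with columns `key`
#'   (bin-pair) and `p` (null P-values).
#' @export
binned_null_pvalues <- function(m, n_null_perms = 300, bin_threshold = 0.02,
                                ladder = c(100, 1000, 10000),
                                escalate_num = 10, min_me_pretest = 3,
                                min_co_pretest = 1) {
  if (n_null_perms < 1) stop("n_null_perms must be at least 1")
  su <- wesme_setup(m, bin_threshold)
  blocks <- block_ids(m)
  ones <- sum(m)
  chain <- cpp_perm_co_chain(unclass(m), blocks, max(blocks) + 1L,
                             n_null_perms, 5 * ones, ones)
  res <- wesme_score_ensemble(su, chain, ladder, escalate_num,
                              min_co_pretest, min_me_pretest)
  file_null_pvalues(su, chain, res, 0L, n_null_perms,
                    min_co_pretest, min_me_pretest)
}

file_null_pvalues <- function(su, co_mat, res, offset, n_null,
                              min_co_pretest, min_me_pretest) {
  bin_key <- wesme_rate_bin_keys(su$bins, su$pairs)
  null_co <- vector("list", n_null)
  null_me <- vector("list", n_null)
  for (j in seq_len(n_null)) {
    col <- offset + j
    co_j <- co_mat[, col]
    me_j <- su$margin_sum - 2L * co_j
    ec <- co_j >= min_co_pretest
    em <- me_j >= min_me_pretest
    null_co[[j]] <- data.frame(key = bin_key[ec], p = res$p_co[ec, col],
                               stringsAsFactors = FALSE)
    null_me[[j]] <- data.frame(key = bin_key[em], p = res$p_me[em, col],
                               stringsAsFactors = FALSE)
  }
  list(co = do.call(rbind, null_co), me = do.call(rbind, null_me))
}

#' Run the weighted-resampling test on a mutation matrix
#'
#' Runs the full single-seed WeSME-style analysis: observed co/me counts,
#' pre-test count filters, the adaptive resampling ladder, rate-bin
#' assignment, permutation-derived null P-value sets and the empirical
#' FDR/q-values per direction and bin combination. With more than one cancer
#' type in the matrix the test runs in pan-cancer mode: counts are pooled
#' over types while resampling (and the fixed-margin permutations of the FDR
#' null) stay within each type.
#'
#' @param m a post-filter [mutation_matrix()].
#' @param ladder escalating resample schedule; the last entry is the cap.
#' @param escalate_num a pair escalates to the next rung while its interim
#'   P-value is below `escalate_num / resamples_so_far`.
#' @param n_null_perms number of fixed-margin permuted matrices scored to
#'   build the null P-value sets (default 300; the three bin combinations
#'   each need enough mass).
#' @param bin_threshold mutation-rate bin boundary, see [assign_rate_bins()].
#' @param min_me_pretest minimum pooled mutually-exclusive count for a pair
#'   to be tested in the `me` direction.
#' @param min_co_pretest minimum pooled co-occurrence count for a pair to be
#'   tested in the `co` direction.
#' @param run_seed identifier recorded in the outcome table (the caller is
#'   responsible for `set.seed`); defaults to `NA`.
#' @param mode label recorded in the outcome table; defaults to `"pan"` when
#'   the matrix has several cancer types.
#' @return a test-outcome data.frame, one row per tested (pair, direction),
#'   with columns `gene_a`, `gene_b`, `direction`, `cancer_type`, `mode`,
#'   `test`, `p`, `fdr`, `q`, `co_obs`, `me_obs`, `margin_a`, `margin_b`,
#'   `rate_bin_pair`, `resamples_used`, `run_seed`.
#' @export
wesme_test <- function(m, ladder = c(100, 1000, 10000), escalate_num = 10,
                       n_null_perms = 300, bin_threshold = 0.02,
                       min_me_pretest = 3, min_co_pretest = 1,
                       run_seed = NA_integer_, mode = NULL) {
  if (any(diff(ladder) <= 0)) stop("ladder must be strictly increasing")
  if (n_null_perms < 1) stop("n_null_perms must be at least 1")
  types <- sort(unique(cancer_types(m)))
  mode <- mode %||% if (length(types) > 1) "pan" else "per-type"
  ct_label <- if (length(types) > 1) "PAN" else types
  su <- wesme_setup(m, bin_threshold)
  pairs <- su$pairs
  if (nrow(pairs) == 0) stop("fewer than 2 genes; nothing to test")
  blocks <- block_ids(m)
  ones <- sum(m)
  chain <- cpp_perm_co_chain(unclass(m), blocks, max(blocks) + 1L,
                             n_null_perms, 5 * ones, ones)
  co_mat <- cbind(pairs$co_obs, chain)
  res <- wesme_score_ensemble(su, co_mat, ladder, escalate_num,
                              min_co_pretest, min_me_pretest)
  nulls <- file_null_pvalues(su, co_mat, res, 1L, n_null_perms,
                             min_co_pretest, min_me_pretest)

  elig <- list(co = pairs$co_obs >= min_co_pretest,
               me = pairs$me_obs >= min_me_pretest)
  bin_key <- wesme_rate_bin_keys(su$bins, pairs)
  base <- pairs[, c("gene_a", "gene_b", "co_obs", "me_obs",
                    "margin_a", "margin_b")]
  base$rate_bin_pair <- bin_key
  base$resamples_used <- res$draws[, 1]
  mk_direction <- function(direction, keep, p, null_tab) {
    out <- base[keep, , drop = FALSE]
    out$direction <- direction
    out$p <- p[keep]
    out$fdr <- out$q <- NA_real_
    for (key in unique(out$rate_bin_pair)) {
      sel <- out$rate_bin_pair == key
      nullp <- null_tab$p[null_tab$key == key]
      if (length(nullp) == 0) {
        # a bin combination absent from every permuted matrix: fall back to
        # the pooled null rather than failing
        nullp <- null_tab$p
      }
      est <- empirical_fdr(out$p[sel], nullp)
      out$fdr[sel] <- est$fdr
      out$q[sel] <- est$q
    }
    out
  }
  out <- rbind(mk_direction("co", elig$co, res$p_co[, 1], nulls$co),
               mk_direction("me", elig$me, res$p_me[, 1], nulls$me))
  out$cancer_type <- ct_label
  out$mode <- mode
  out$test <- "wesme"
  out$run_seed <- run_seed
  rownames(out) <- NULL
  out[, c("gene_a", "gene_b", "direction", "cancer_type", "mode", "test",
          "p", "fdr", "q", "co_obs", "me_obs", "margin_a", "margin_b",
          "rate_bin_pair", "resamples_used", "run_seed")]
}

#' Pan-cancer weighted-resampling test from per-type matrices
#'
#' Pools several per-cancer-type matrices into one matrix (union of genes;
#' a gene absent from a type simply contributes margin zero there) and runs
#' [wesme_test()] in pan-cancer mode: observed counts are summed over types
#' while resampling stays within each type.
#'
#' @param matrices named list of [mutation_matrix()] objects, one per cancer
#'   type; sample sets must be disjoint.
#' @param ... passed to [wesme_test()].
#' @return a test-outcome data.frame (see [wesme_test()]).
#' @export
pan_cancer_wesme <- function(matrices, ...) {
  all_samples <- unlist(lapply(matrices, colnames))
  if (anyDuplicated(all_samples))
    stop("cancer-type partition must be disjoint (duplicate sample IDs)")
  genes <- sort(unique(unlist(lapply(matrices, rownames))))
  inc <- matrix(0L, length(genes), length(all_samples),
                dimnames = list(genes, all_samples))
  ct <- character(0)
  for (mi in matrices) {
    inc[rownames(mi), colnames(mi)] <- unclass(mi)
    ct <- c(ct, cancer_types(mi))
  }
  m <- mutation_matrix(inc, ct)
  wesme_test(m, ..., mode = "pan")
}

#' Replicate weighted-resampling runs under distinct seeds
#'
#' Repeats the full [wesme_test()] analysis `n_runs` times, each under its
#' own randomization seed, applies the candidate selection thresholds to each
#' run, and counts per (pair, direction) in how many runs the pair was
#' significant (its support).
#'
#' @param m a post-filter [mutation_matrix()].
#' @param n_runs number of replicate runs (default 10).
#' @param seeds integer vector of distinct seeds, one per run; drawn from the
#'   current RNG when omitted.
#' @param q_max,p_max,min_co selection thresholds, see [select_candidates()].
#' @param ... passed to [wesme_test()].
#' @return list with `runs` (per-run outcome tables), `selections` (per-run
#'   significant outcomes) and `support` (data.frame `gene_a`, `gene_b`,
#'   `direction`, `support`).
#' @export
run_replicates <- function(m, n_runs = 10, seeds = NULL, q_max = 0.2,
                           p_max = 0.1, min_co = 3, ...) {
  seeds <- seeds %||% sample.int(.Machine$integer.max, n_runs)
  if (length(seeds) != n_runs) stop("need one seed per run")
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  runs <- selections <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(seeds[r])
    runs[[r]] <- wesme_test(m, ..., run_seed = seeds[r])
    selections[[r]] <- select_candidates(runs[[r]], q_max = q_max,
                                         p_max = p_max, min_co = min_co)
  }
  sel_all <- do.call(rbind, selections)
  support <- if (nrow(sel_all) == 0) {
    data.frame(gene_a = character(), gene_b = character(),
               direction = character(), support = integer(),
               stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(list(support = sel_all$p),
                            by = sel_all[, c("gene_a", "gene_b", "direction")],
                            FUN = length)
    agg[order(agg$gene_a, agg$gene_b, agg$direction), , drop = FALSE]
  }
  rownames(support) <- NULL
  list(runs = runs, selections = selections, support = support)
}
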