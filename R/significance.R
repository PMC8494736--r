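# Empirical FDR / q-values from permutation-derived null P-value sets,
# candidate selection, replicate-based high-confidence filtering, interaction
# map merging and the down-sampling experiment.

#' Empirical FDR and q-values against a null P-value set
#'
#' For each observed P-value `P*`, the number of false positives among the
#' rejections at threshold `P*` is estimated as
#' `V(P*) = prop(S_null <= P*) * n_observed`, the number of rejections is
#' `R(P*) = #{observed <= P*}` (ties inclusive), and `FDR(P*) = V/R`. The
#' q-value is the smallest estimated FDR among all observed P-values `>= P*`
#' (a suffix minimum over the sorted observed values), capped at 1. The FDR
#' itself may exceed 1 when `R` is small; only the q-value is capped.
#'
#' @param observed_p numeric vector of observed P-values.
#' @param null_p numeric vector (multiset) of null P-values.
#' @return data.frame with columns `p`, `fdr`, `q`, aligned with
#'   `observed_p`.
#' @export
empirical_fdr <- function(observed_p, null_p) {
  if (length(observed_p) == 0)
    return(data.frame(p = numeric(), fdr = numeric(), q = numeric()))
  if (length(null_p) == 0) stop("no null distribution")
  ord <- order(observed_p)
  ps <- observed_p[ord]
  n_obs <- length(ps)
  null_sorted <- sort(null_p)
  v <- findInterval(ps, null_sorted) / length(null_sorted) * n_obs
  r <- findInterval(ps, ps)  # ties counted inclusively
  fdr <- v / r
  q <- pmin(1, rev(cummin(rev(fdr))))
  out <- data.frame(p = observed_p, fdr = NA_real_, q = NA_real_)
  out$fdr[ord] <- fdr
  out$q[ord] <- q
  out
}

#' Select significant candidate outcomes
#'
#' A (pair, direction) outcome is significant when its q-value is below
#' `q_max` and its P-value below `p_max` (strict inequalities), and — for the
#' co-occurrence direction only — its observed co-occurrence count is at
#' least `min_co`.
#'
#' @param outcomes a test-outcome data.frame ([permutation_test()] or
#'   [wesme_test()]).
#' @param q_max,p_max selection thresholds (defaults 0.2 and 0.1).
#' @param min_co minimum co-occurrence count for co-direction candidates
#'   (default 3).
#' @return the significant subset of `outcomes`.
#' @export
select_candidates <- function(outcomes, q_max = 0.2, p_max = 0.1, min_co = 3) {
  keep <- outcomes$q < q_max & outcomes$p < p_max &
    (outcomes$direction == "me" | outcomes$co_obs >= min_co)
  out <- outcomes[keep & !is.na(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' High-confidence candidates across replicate runs
#'
#' Weighted-resampling candidates are kept only when significant in at least
#' `min_support` of the replicate runs; permutation-test candidates (a single,
#' much more expensive run) pass through without support filtering.
#'
#' @param wesme_selections list of per-run significant outcome tables (the
#'   `selections` element of [run_replicates()]), or `NULL`.
#' @param permutation_selection significant outcomes of the single
#'   permutation-test run, or `NULL`.
#' @param min_support minimum number of supporting runs (default 9).
#' @return data.frame of high-confidence candidates with columns `gene_a`,
#'   `gene_b`, `direction`, `cancer_type`, `mode`, `test`, `p`, `q`,
#'   `co_obs`, `support` (`NA` for permutation candidates).
#' @export
high_confidence_filter <- function(wesme_selections = NULL,
                                   permutation_selection = NULL,
                                   min_support = 9) {
  cols <- c("gene_a", "gene_b", "direction", "cancer_type", "mode", "test",
            "p", "q", "co_obs", "support")
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      direction = character(), cancer_type = character(),
                      mode = character(), test = character(), p = numeric(),
                      q = numeric(), co_obs = integer(), support = integer(),
                      stringsAsFactors = FALSE)
  out <- empty
  if (!is.null(wesme_selections)) {
    sel_all <- do.call(rbind, wesme_selections)
    if (!is.null(sel_all) && nrow(sel_all) > 0) {
      key <- paste(sel_all$gene_a, sel_all$gene_b, sel_all$direction,
                   sel_all$cancer_type, sel_all$mode, sep = "\r")
      support <- table(key)
      keep_keys <- names(support)[support >= min_support]
      if (length(keep_keys) > 0) {
        first <- sel_all[match(keep_keys, key), , drop = FALSE]
        # report the median p/q over the supporting runs
        first$p <- vapply(keep_keys, function(k)
          stats::median(sel_all$p[key == k]), numeric(1))
        first$q <- vapply(keep_keys, function(k)
          stats::median(sel_all$q[key == k]), numeric(1))
        first$support <- as.integer(support[keep_keys])
        out <- rbind(out, first[, cols])
      }
    }
  }
  if (!is.null(permutation_selection) && nrow(permutation_selection) > 0) {
    ps <- permutation_selection
    ps$support <- NA_integer_
    out <- rbind(out, ps[, cols])
  }
  out <- out[order(out$gene_a, out$gene_b, out$direction, out$cancer_type), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge candidate tables into an interaction map
#'
#' Combines candidate tables (possibly from several tests, modes and
#' datasets) into one record per (pair, cancer-type-or-PAN, direction),
#' annotated with the tests the candidate was detected in (`both`,
#' `wesme-only` or `permutation-only`) and whether a per-type candidate was
#' also found in the pan-cancer analysis. Conflicting directions for the
#' same pair and context are both retained and flagged.
#'
#' @param ... candidate data.frames as produced by
#'   [high_confidence_filter()] or [select_candidates()] (they need columns
#'   `gene_a`, `gene_b`, `direction`, `cancer_type`, `mode`, `test`).
#' @return list with `map` (the merged records) and `summary` (counts:
#'   total, unique pairs, co, me, per test-detection category, per mode).
#' @export
merge_interaction_map <- function(...) {
  tabs <- list(...)
  tabs <- tabs[!vapply(tabs, is.null, logical(1))]
  cand <- do.call(rbind, lapply(tabs, function(x)
    canonical_pairs(x[, c("gene_a", "gene_b", "direction", "cancer_type",
                          "mode", "test")])))
  if (is.null(cand) || nrow(cand) == 0) {
    map <- data.frame(gene_a = character(), gene_b = character(),
                      direction = character(), cancer_type = character(),
                      tests = character(), pan_overlap = logical(),
                      inconsistent_direction = logical(),
                      stringsAsFactors = FALSE)
    return(list(map = map, summary = interaction_map_summary(map)))
  }
  key <- paste(cand$gene_a, cand$gene_b, cand$direction, cand$cancer_type,
               sep = "\r")
  map <- cand[!duplicated(key), c("gene_a", "gene_b", "direction",
                                  "cancer_type"), drop = FALSE]
  ukey <- key[!duplicated(key)]
  map$tests <- vapply(ukey, function(k) {
    tests <- sort(unique(cand$test[key == k]))
    if (length(tests) > 1) "both"
    else if (tests == "wesme") "wesme-only"
    else "permutation-only"
  }, character(1))
  pair_dir <- paste(map$gene_a, map$gene_b, map$direction, sep = "\r")
  pan_pairs <- unique(pair_dir[map$cancer_type == "PAN"])
  type_pairs <- unique(pair_dir[map$cancer_type != "PAN"])
  map$pan_overlap <- pair_dir %in% pan_pairs & pair_dir %in% type_pairs
  pair_ctx <- paste(map$gene_a, map$gene_b, map$cancer_type, sep = "\r")
  dir_per_ctx <- tapply(map$direction, pair_ctx,
                        function(d) length(unique(d)))
  map$inconsistent_direction <- dir_per_ctx[pair_ctx] > 1
  map <- map[order(map$gene_a, map$gene_b, map$cancer_type, map$direction), ,
             drop = FALSE]
  rownames(map) <- NULL
  list(map = map, summary = interaction_map_summary(map))
}

interaction_map_summary <- function(map) {
  pair_dir <- unique(paste(map$gene_a, map$gene_b, map$direction, sep = "\r"))
  per_type <- map[map$cancer_type != "PAN", , drop = FALSE]
  pan <- map[map$cancer_type == "PAN", , drop = FALSE]
  data.frame(
    statistic = c("total", "unique_pairs", "co_occurring",
                  "mutually_exclusive", "both_tests", "wesme_only",
                  "permutation_only", "per_cancer_type", "pan",
                  "pan_overlap_cancer_type"),
    n = c(nrow(map), length(pair_dir),
          length(unique(paste(map$gene_a, map$gene_b)[map$direction == "co"])),
          length(unique(paste(map$gene_a, map$gene_b)[map$direction == "me"])),
          sum(map$tests == "both"), sum(map$tests == "wesme-only"),
          sum(map$tests == "permutation-only"), nrow(per_type), nrow(pan),
          sum(pan$pan_overlap)),
    stringsAsFactors = FALSE)
}

#' Down-sampling experiment
#'
#' Measures how the number of detected candidates depends on cohort size:
#' for each requested size, `n_reps` random subsamples of the cohort are
#' drawn (uniformly, without replacement), the weighted-resampling test and
#' candidate selection are run on each, and the per-replicate candidate
#' counts are recorded. High-confidence counts per size are the pairs
#' significant in at least `min_support` of the replicates.
#'
#' @param m a post-filter [mutation_matrix()].
#' @param sizes integer vector of subsample sizes (default
#'   `c(50, 100, 200, 300, 400)`, truncated to the cohort size).
#' @param n_reps replicates per size (default 10).
#' @param q_max,p_max,min_co selection thresholds, see [select_candidates()].
#' @param min_support support cutoff for the high-confidence count.
#' @param min_mutated_samples singleton-gene filter re-applied after
#'   subsampling.
#' @param ... passed to [wesme_test()].
#' @return list with `counts` (data.frame `size`, `rep`, `n_candidates`) and
#'   `high_confidence` (data.frame `size`, `n_high_confidence`).
#' @export
downsampling_experiment <- function(m, sizes = c(50, 100, 200, 300, 400),
                                    n_reps = 10, q_max = 0.2, p_max = 0.1,
                                    min_co = 3, min_support = 9,
                                    min_mutated_samples = 2, ...) {
  if (any(sizes > ncol(m)))
    stop("subsample size exceeds cohort size (", ncol(m), ")")
  counts <- data.frame(size = integer(), rep = integer(),
                       n_candidates = integer())
  hc <- data.frame(size = integer(), n_high_confidence = integer())
  for (size in sizes) {
    sels <- vector("list", n_reps)
    for (r in seq_len(n_reps)) {
      ms <- if (size == ncol(m)) m else
        subset_samples(m, sample(colnames(m), size))
      ms <- prune_matrix(ms, min_mutated_samples)$matrix
      outc <- wesme_test(ms, ...)
      sels[[r]] <- select_candidates(outc, q_max = q_max, p_max = p_max,
                                     min_co = min_co)
      counts <- rbind(counts, data.frame(size = size, rep = r,
                                         n_candidates = nrow(sels[[r]])))
    }
    hc_set <- high_confidence_filter(wesme_selections = sels,
                                     min_support = min_support)
    hc <- rbind(hc, data.frame(size = size, n_high_confidence = nrow(hc_set)))
  }
  list(counts = counts, high_confidence = hc)
}
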