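# End-to-end orchestration: variants -> filters -> matrices -> tests ->
# FDR/selection -> high-confidence -> merged interaction map -> MLA screen.

#' Pipeline run configuration
#'
#' Collects every knob of the analysis with defaults matching the published
#' procedure: selection at q < 0.2 and p < 0.1 with a minimum co-occurrence
#' count of 3; permutation test with N = 1e6 fixed-margin permutations and
#' 100 pseudo-observed matrices; weighted-resampling test with a 10,000
#' resample cap, 300 null permutations, a 2% rate-bin threshold, pan-mode
#' pre-test count filters (me >= 3, co >= 1) and ten replicate runs with a
#' nine-of-ten support cutoff.
#'
#' @param variants path to a MAF-like variant file.
#' @param dialect dataset dialect, see [dialect_config()].
#' @param mode `"per-type"`, `"pan"` or `"both"`.
#' @param test `"permutation"`, `"wesme"` or `"both"`.
#' @param out_dir output directory.
#' @param seed master seed; all run seeds derive from it.
#' @param n_permutations fixed-margin permutations for the permutation test.
#' @param n_pseudo pseudo-observed matrices for its FDR null.
#' @param ladder,n_null_perms,bin_threshold,min_me_pretest,min_co_pretest
#'   weighted-resampling parameters, see [wesme_test()].
#' @param n_runs,min_support replicate runs and support cutoff.
#' @param q_max,p_max,min_co selection thresholds.
#' @param mla_threshold suspect-rule threshold on the MLA score.
#' @param hypermutator_count hypermutator mutation-count threshold.
#' @param min_mutated_samples singleton-gene filter.
#' @param sample_blocklist samples excluded up front.
#' @return a `run_config` list.
#' @export
run_config <- function(variants, dialect = "SYNTHETIC", mode = "per-type",
                       test = "both", out_dir = "comutmap_out", seed = 1,
                       n_permutations = 1e6, n_pseudo = 100,
                       ladder = c(100, 1000, 10000), n_null_perms = 300,
                       bin_threshold = 0.02, min_me_pretest = 3,
                       min_co_pretest = 1, n_runs = 10, min_support = 9,
                       q_max = 0.2, p_max = 0.1, min_co = 3,
                       mla_threshold = 3,
                       hypermutator_count = hypermutator_threshold(),
                       min_mutated_samples = 2,
                       sample_blocklist = character()) {
  stopifnot(mode %in% c("per-type", "pan", "both"),
            test %in% c("permutation", "wesme", "both"))
  structure(as.list(environment()), class = "run_config")
}

#' Run the full detection pipeline
#'
#' Executes the stages in order — parse, hypermutator flagging (on the
#' pre-filter records, silent variants included), functional filtering,
#' matrix construction, the requested tests with empirical FDR, candidate
#' selection, replicate-based high-confidence filtering, interaction-map
#' merging and the MLA suspect screen — and writes TSV outputs plus a
#' machine-readable run manifest to the output directory. Any stage failure
#' aborts with the stage name after writing a partial manifest.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the in-memory results: `map`, `summary`,
#'   `candidates`, `mla`, `suspects`, `reports`, `manifest`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  manifest <- list(package = "comutmap",
                   version = as.character(utils::packageVersion("comutmap")),
                   config = config[setdiff(names(config), "sample_blocklist")],
                   stages = character())
  stage <- function(name, expr) {
    manifest$stages <<- c(manifest$stages, name)
    tryCatch(expr, error = function(e) {
      manifest$failed_stage <<- name
      jsonlite::write_json(manifest,
                           file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, force = TRUE, digits = NA)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  parsed <- stage("parse", parse_variants(config$variants, config$dialect))
  hyper <- stage("hypermutators",
                 flag_hypermutators(parsed$records, config$hypermutator_count))
  records <- parsed$records[!parsed$records$sample_id %in% hyper, , drop = FALSE]
  report <- report_add(parsed$report, "hypermutator", "sample", length(hyper))
  filtered <- stage("functional_filter", filter_functional(records))
  report <- rbind(report, filtered$report)

  matrices <- list()
  if (config$mode %in% c("per-type", "both")) {
    per_type <- stage("matrix_per_type",
                      build_matrices_by_type(filtered$records,
                                             config$min_mutated_samples,
                                             config$sample_blocklist))
    matrices <- c(matrices, lapply(per_type, `[[`, "matrix"))
    for (res in per_type) report <- rbind(report, res$report)
  }
  if (config$mode %in% c("pan", "both")) {
    pan <- stage("matrix_pan",
                 build_matrix(filtered$records, config$min_mutated_samples,
                              config$sample_blocklist))
    matrices$PAN <- pan$matrix
    report <- rbind(report, pan$report)
  }

  candidates <- list()
  run_seeds <- sample.int(2^30, config$n_runs)
  for (ctx in names(matrices)) {
    m <- matrices[[ctx]]
    if (nrow(m) < 2) next
    is_pan <- ctx == "PAN"
    mode_label <- if (is_pan) "pan" else "per-type"
    wesme_sel <- NULL
    perm_sel <- NULL
    if (config$test %in% c("wesme", "both")) {
      reps <- stage(paste0("wesme_", ctx), run_replicates(
        m, n_runs = config$n_runs, seeds = run_seeds,
        q_max = config$q_max, p_max = config$p_max, min_co = config$min_co,
        ladder = config$ladder, n_null_perms = config$n_null_perms,
        bin_threshold = config$bin_threshold,
        min_me_pretest = config$min_me_pretest,
        min_co_pretest = config$min_co_pretest, mode = mode_label))
      wesme_sel <- reps$selections
    }
    if (config$test %in% c("permutation", "both")) {
      perm <- stage(paste0("permutation_", ctx), permutation_test(
        m, N = config$n_permutations, block_by_cancer_type = is_pan,
        n_pseudo = config$n_pseudo, mode = mode_label))
      perm_sel <- select_candidates(perm, config$q_max, config$p_max,
                                    config$min_co)
    }
    hc <- stage(paste0("high_confidence_", ctx),
                high_confidence_filter(wesme_sel, perm_sel,
                                       config$min_support))
    if (nrow(hc) > 0) candidates[[ctx]] <- hc
  }

  merged <- stage("merge", do.call(merge_interaction_map, candidates))

  # MLA screen on candidate genes, per context matrix
  mla_tabs <- list()
  suspect_tabs <- list()
  for (ctx in names(candidates)) {
    cand <- candidates[[ctx]]
    genes <- unique(c(cand$gene_a, cand$gene_b))
    scores <- stage(paste0("mla_", ctx),
                    mla_score(matrices[[ctx]], genes))
    scores$cancer_type <- if (ctx == "PAN") "PAN" else ctx
    flags <- flag_suspects(cand, scores, config$mla_threshold)
    if (nrow(flags) > 0) flags$cancer_type <- scores$cancer_type[1]
    mla_tabs[[ctx]] <- scores
    suspect_tabs[[ctx]] <- flags
  }
  mla_all <- do.call(rbind, mla_tabs)
  suspects <- do.call(rbind, suspect_tabs)

  out <- function(df, name) {
    if (!is.null(df))
      write.table(df, file.path(config$out_dir, name), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  cand_all <- do.call(rbind, candidates)
  out(cand_all, "candidates.tsv")
  out(merged$map, "interaction_map.tsv")
  out(merged$summary, "summary.tsv")
  out(mla_all, "mla_scores.tsv")
  out(suspects, "suspect_pairs.tsv")
  out(report, "filter_report.tsv")

  manifest$run_seeds <- run_seeds
  manifest$n_candidates <- nrow(merged$map)
  manifest$filter_report <- report
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, force = TRUE, digits = NA)
  invisible(list(map = merged$map, summary = merged$summary,
                 candidates = cand_all, mla = mla_all, suspects = suspects,
                 reports = report, manifest = manifest))
}
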