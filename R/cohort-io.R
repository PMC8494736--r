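# Parsing MAF-like somatic variant tables, consequence filtering,
# overlapping-gene resolution, hypermutator flagging and matrix construction.

#' Column map and consequence vocabulary for a dataset dialect
#'
#' Two study dialects are built in. `TARGET` uses MAF-style column names and
#' keeps the variant classes Missense_Mutation, Nonsense_Mutation, missense,
#' nonsense, Frame_Shift_Del, Frame_Shift_Ins, In_Frame_Del, In_Frame_Ins,
#' frameshift, proteinDel and proteinIns. `DKFZ` uses ANNOVAR-style exonic
#' consequence labels and keeps frameshift, non-frameshift, non-synonymous,
#' stopgain and stoploss classes. `SYNTHETIC` is the generator's own compact
#' vocabulary and is fully configurable.
#'
#' @param dialect one of `"TARGET"`, `"DKFZ"`, `"SYNTHETIC"`.
#' @param ... overrides for any of the returned fields (e.g. a different
#'   `keep_consequences` vector for `SYNTHETIC` cohorts).
#' @return list with fields `dialect`, `sample_column`, `gene_column`,
#'   `consequence_column`, `cancer_type_column`, `keep_consequences`,
#'   `drop_consequences`.
#' @export
dialect_config <- function(dialect = c("TARGET", "DKFZ", "SYNTHETIC"), ...) {
  dialect <- match.arg(dialect)
  cfg <- switch(dialect,
    TARGET = list(
      dialect = "TARGET",
      sample_column = "Tumor_Sample_Barcode",
      gene_column = "Hugo_Symbol",
      consequence_column = "Variant_Classification",
      cancer_type_column = "Cancer_Type",
      keep_consequences = c(
        "Missense_Mutation", "Nonsense_Mutation", "missense", "nonsense",
        "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
        "frameshift", "proteinDel", "proteinIns"),
      drop_consequences = c(
        "Silent", "silent", "Splice_Site", "Splice_Region", "3'UTR", "5'UTR",
        "3'Flank", "5'Flank", "Intron", "IGR", "RNA", "lincRNA",
        "Translation_Start_Site", "Nonstop_Mutation")),
    DKFZ = list(
      dialect = "DKFZ",
      sample_column = "Sample",
      gene_column = "Gene",
      consequence_column = "ExonicFunc",
      cancer_type_column = "Cancer_Type",
      keep_consequences = c(
        "frameshift insertion", "frameshift deletion",
        "frameshift substitution", "nonframeshift insertion",
        "nonframeshift deletion", "nonframeshift substitution",
        "nonsynonymous SNV", "stopgain", "stoploss",
        "stopgain SNV", "stoploss SNV"),
      drop_consequences = c("synonymous SNV", "unknown")),
    SYNTHETIC = list(
      dialect = "SYNTHETIC",
      sample_column = "sample_id",
      gene_column = "gene",
      consequence_column = "consequence",
      cancer_type_column = "cancer_type",
      keep_consequences = c("missense", "nonsense", "frameshift",
                            "inframe_indel", "stopgain", "stoploss"),
      drop_consequences = "silent"))
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg
}

#' Create an empty filter report
#'
#' A filter report accounts for every record, sample or gene removed by a
#' named rule, so that `input = retained + sum(removed)` always reconciles.
#'
#' @return zero-row data.frame with columns `rule`, `level`, `n_removed`.
#' @export
filter_report <- function() {
  data.frame(rule = character(), level = character(),
             n_removed = integer(), stringsAsFactors = FALSE)
}

report_add <- function(report, rule, level, n) {
  if (n == 0) return(report)
  rbind(report, data.frame(rule = rule, level = level, n_removed = as.integer(n),
                           stringsAsFactors = FALSE))
}

#' Write a filter report as TSV
#' @param report a filter report data.frame.
#' @param path output path.
#' @export
write_filter_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a MAF-like variant table
#'
#' Reads a tab-separated somatic variant table (one row per variant call) in
#' one of the dataset dialects and returns one record per well-formed data
#' row. Rows missing the sample ID, gene symbol or consequence are collected
#' into the filter report rather than silently dropped.
#'
#' @param path path to a tab-separated file whose header names at least the
#'   sample, gene and consequence columns of the dialect.
#' @param dialect dataset dialect, see [dialect_config()].
#' @param config optional dialect configuration overriding the default one.
#' @param cancer_type fallback cancer-type label used when the file has no
#'   cancer-type column.
#' @return list with `records` (data.frame with columns `sample_id`, `gene`,
#'   `consequence`, `cancer_type`, `dataset`) and `report` (a filter report).
#' @export
parse_variants <- function(path, dialect = c("TARGET", "DKFZ", "SYNTHETIC"),
                           config = NULL, cancer_type = NA_character_) {
  dialect <- match.arg(dialect)
  config <- config %||% dialect_config(dialect)
  if (!file.exists(path)) stop("cannot read variant file: ", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "#", colClasses = "character")
  needed <- c(config$sample_column, config$gene_column, config$consequence_column)
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0)
    stop("variant file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  ct <- if (config$cancer_type_column %in% names(tab))
    tab[[config$cancer_type_column]] else rep(cancer_type, nrow(tab))
  records <- data.frame(
    sample_id = tab[[config$sample_column]],
    gene = tab[[config$gene_column]],
    consequence = tab[[config$consequence_column]],
    cancer_type = ct,
    dataset = dialect,
    stringsAsFactors = FALSE)
  bad <- is.na(records$sample_id) | records$sample_id == "" |
    is.na(records$gene) | records$gene == "" |
    is.na(records$consequence) | records$consequence == ""
  report <- report_add(filter_report(), "malformed_row", "record", sum(bad))
  list(records = records[!bad, , drop = FALSE], report = report)
}

#' Keep only variants with a likely functional consequence
#'
#' Applies the dialect's keep-list of consequence classes. Consequences on the
#' dialect's known drop-list are removed as non-functional; consequence
#' strings in neither list are removed with a separate "unknown consequence"
#' report entry so that vocabulary drift degrades visibly but gracefully.
#'
#' @param records variant record data.frame from [parse_variants()].
#' @param config optional dialect configuration; defaults to the dialect of
#'   the records themselves.
#' @return list with `records` (kept rows) and `report`.
#' @export
filter_functional <- function(records, config = NULL) {
  if (nrow(records) == 0)
    return(list(records = records, report = filter_report()))
  config <- config %||% dialect_config(records$dataset[1])
  keep <- records$consequence %in% config$keep_consequences
  known_drop <- records$consequence %in% config$drop_consequences
  unknown <- !keep & !known_drop
  report <- filter_report()
  report <- report_add(report, "non_functional_consequence", "record",
                       sum(known_drop))
  report <- report_add(report, "unknown_consequence", "record", sum(unknown))
  list(records = records[keep, , drop = FALSE], report = report)
}

#' Resolve a variant annotated to multiple overlapping genes
#'
#' When a variant overlaps several genes, one gene is chosen by sorting the
#' candidates on annotation quality: Gencode v19 status (KNOWN before NOVEL
#' before PUTATIVE), Gencode v19 type (protein-coding first), Gencode v27 type
#' (protein-coding first), total number of exonic alterations (higher first),
#' number of exonic alterations where the gene is the only annotation (higher
#' first), and finally a gene name without a dash (read-through genes usually
#' contain one). A full tie falls back to the alphabetically first symbol,
#' with a warning.
#'
#' @param candidates data.frame with columns `gene`, `gencode_v19_status`
#'   (KNOWN/NOVEL/PUTATIVE/UNKNOWN), `gencode_v19_type`, `gencode_v27_type`
#'   (`"protein_coding"` or other), `n_exonic_alterations`,
#'   `n_exonic_alterations_single`, `name_has_dash` (logical).
#' @return the selected gene symbol (length-1 character).
#' @export
resolve_overlapping_genes <- function(candidates) {
  stopifnot(nrow(candidates) >= 1)
  if (nrow(candidates) == 1L) return(candidates$gene)
  status_rank <- match(candidates$gencode_v19_status,
                       c("KNOWN", "NOVEL", "PUTATIVE", "UNKNOWN"))
  status_rank[is.na(status_rank)] <- 5L
  keys <- list(
    status_rank,
    ifelse(candidates$gencode_v19_type == "protein_coding", 0L, 1L),
    ifelse(candidates$gencode_v27_type == "protein_coding", 0L, 1L),
    -as.integer(candidates$n_exonic_alterations),
    -as.integer(candidates$n_exonic_alterations_single),
    as.integer(candidates$name_has_dash))
  ord <- do.call(order, keys)
  first_keys <- vapply(keys, function(k) k[ord[1]], numeric(1))
  second_keys <- vapply(keys, function(k) k[ord[2]], numeric(1))
  if (all(first_keys == second_keys)) {
    tied <- vapply(seq_len(nrow(candidates)), function(r)
      all(vapply(keys, function(k) k[r], numeric(1)) == first_keys), logical(1))
    warning("full tie in overlapping-gene resolution; ",
            "falling back to alphabetical order")
    return(sort(candidates$gene[tied])[1])
  }
  candidates$gene[ord[1]]
}

#' Hypermutator mutation-count threshold
#'
#' A sample is called a hypermutator when it carries more than
#' `rate_per_mb` coding mutations per megabase over a coding region of known
#' length, assuming a fraction `coverage_fraction` of that region is
#' sufficiently covered. With the defaults (23,698,355 bp of non-redundant
#' coding sequence, 95% coverage, 10 mutations per Mb) the threshold is 225
#' mutations; samples strictly above it are flagged.
#'
#' @param coding_length_bp non-redundant coding length in base pairs.
#' @param coverage_fraction fraction of the coding region assumed covered.
#' @param rate_per_mb hypermutator rate cutoff in mutations per megabase.
#' @return integer mutation-count threshold.
#' @export
hypermutator_threshold <- function(coding_length_bp = 23698355,
                                   coverage_fraction = 0.95,
                                   rate_per_mb = 10) {
  if (coding_length_bp <= 0 || coverage_fraction <= 0 ||
      coverage_fraction > 1 || rate_per_mb <= 0)
    stop("hypermutator_threshold: all arguments must be positive ",
         "(coverage_fraction in (0, 1])")
  as.integer(floor(rate_per_mb * coverage_fraction * coding_length_bp / 1e6))
}

#' Flag hypermutator samples
#'
#' Counts qualifying mutations per sample on the *pre-filter* record set: the
#' hypermutator count includes silent SNVs and all indels, i.e. it must be
#' computed before [filter_functional()] removes non-functional classes.
#'
#' @param records variant records (pre functional filtering).
#' @param threshold integer count threshold; samples with strictly more
#'   qualifying mutations are flagged.
#' @param gene_universe optional character vector restricting the counted
#'   mutations to a gene set (default: all genes present in the input).
#' @return character vector of flagged sample IDs.
#' @export
flag_hypermutators <- function(records, threshold = hypermutator_threshold(),
                               gene_universe = NULL) {
  if (nrow(records) == 0) return(character())
  if (!is.null(gene_universe))
    records <- records[records$gene %in% gene_universe, , drop = FALSE]
  counts <- table(records$sample_id)
  names(counts)[counts > threshold]
}

#' Build a binary mutation matrix from filtered variant records
#'
#' Collapses multiple mutations of one gene in one sample to a single 0/1
#' entry, removes samples without any mutated gene, then removes genes mutated
#' in fewer than `min_mutated_samples` samples (singleton genes, by default).
#' The sample and gene removals are applied once, samples first, not iterated;
#' samples emptied by the gene removal are dropped afterwards (which cannot
#' change any gene margin). Gene and sample order is canonical (alphabetical).
#'
#' @param records functionally filtered variant records with hypermutators
#'   already removed.
#' @param min_mutated_samples minimum number of mutated samples per gene.
#' @param sample_blocklist optional character vector of sample IDs excluded
#'   up front (e.g. relapse or single-end-sequenced samples).
#' @return list with `matrix` (a [mutation_matrix()]) and `report`.
#' @export
build_matrix <- function(records, min_mutated_samples = 2,
                         sample_blocklist = character()) {
  report <- filter_report()
  blocked <- unique(records$sample_id[records$sample_id %in% sample_blocklist])
  report <- report_add(report, "blocklisted_sample", "sample", length(blocked))
  records <- records[!records$sample_id %in% sample_blocklist, , drop = FALSE]
  if (nrow(records) == 0)
    stop("no testable data after filter: blocklisted_sample")
  ct_map <- tapply(records$cancer_type, records$sample_id, function(x) x[1])
  genes <- sort(unique(records$gene))
  samples <- sort(unique(records$sample_id))
  inc <- matrix(0L, length(genes), length(samples),
                dimnames = list(genes, samples))
  inc[cbind(match(records$gene, genes), match(records$sample_id, samples))] <- 1L
  pruned <- prune_matrix_impl(inc, min_mutated_samples)
  report <- rbind(report, pruned$report)
  if (nrow(pruned$matrix) == 0 || ncol(pruned$matrix) == 0)
    stop("no testable data after filter: ", pruned$last_rule)
  m <- mutation_matrix(pruned$matrix,
                       setNames(as.character(ct_map[colnames(pruned$matrix)]),
                                colnames(pruned$matrix)))
  list(matrix = m, report = report)
}

prune_matrix_impl <- function(inc, min_mutated_samples) {
  report <- filter_report()
  last_rule <- "none"
  zero_samples <- colSums(inc) == 0
  if (any(zero_samples)) {
    report <- report_add(report, "zero_mutation_sample", "sample",
                         sum(zero_samples))
    inc <- inc[, !zero_samples, drop = FALSE]
    last_rule <- "zero_mutation_sample"
  }
  rare <- rowSums(inc) < min_mutated_samples
  if (any(rare)) {
    report <- report_add(report, "singleton_gene", "gene", sum(rare))
    inc <- inc[!rare, , drop = FALSE]
    last_rule <- "singleton_gene"
  }
  emptied <- colSums(inc) == 0
  if (any(emptied)) {
    report <- report_add(report, "zero_mutation_sample", "sample", sum(emptied))
    inc <- inc[, !emptied, drop = FALSE]
  }
  list(matrix = inc, report = report, last_rule = last_rule)
}

#' Apply the zero-sample / rare-gene filters to an existing matrix
#'
#' Same single-pass filtering as [build_matrix()] applies, for matrices that
#' were not built from variant records (e.g. synthetic cohorts).
#'
#' @param m a [mutation_matrix()].
#' @param min_mutated_samples minimum number of mutated samples per gene.
#' @return list with `matrix` and `report`.
#' @export
prune_matrix <- function(m, min_mutated_samples = 2) {
  ct <- cancer_types(m)
  pruned <- prune_matrix_impl(unclass(m), min_mutated_samples)
  if (nrow(pruned$matrix) == 0 || ncol(pruned$matrix) == 0)
    stop("no testable data after filter: ", pruned$last_rule)
  list(matrix = mutation_matrix(pruned$matrix, ct[colnames(pruned$matrix)]),
       report = pruned$report)
}

#' Build per-cancer-type mutation matrices from one record set
#'
#' Convenience wrapper around [build_matrix()] for per-cancer-type testing:
#' each type's matrix gets its own singleton filtering.
#'
#' @inheritParams build_matrix
#' @return named list of `list(matrix, report)` per cancer type; types whose
#'   records yield no testable matrix are dropped with a warning.
#' @export
build_matrices_by_type <- function(records, min_mutated_samples = 2,
                                   sample_blocklist = character()) {
  types <- sort(unique(records$cancer_type))
  out <- list()
  for (ty in types) {
    rec <- records[records$cancer_type == ty, , drop = FALSE]
    res <- tryCatch(build_matrix(rec, min_mutated_samples, sample_blocklist),
                    error = function(e) NULL)
    if (is.null(res)) {
      warning("cancer type ", ty, " has no testable data; skipped")
    } else {
      out[[ty]] <- res
    }
  }
  out
}
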