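# Variant parsing, consequence filtering, gene resolution, hypermutator
# flagging and matrix construction.

test_that("parsing keeps well-formed rows and reports malformed ones", {
  path <- withr::local_tempfile(fileext = ".maf")
  write_target_maf(path, list(
    list("S1", "TP53", "Missense_Mutation"),
    list("S1", "NRAS", "Nonsense_Mutation"),
    list("S2", "TP53", "Silent"),
    list("S3", "", "Missense_Mutation")))
  res <- parse_variants(path, "TARGET")
  expect_equal(nrow(res$records), 3)
  expect_equal(res$report$n_removed[res$report$rule == "malformed_row"], 1)
  expect_true(all(res$records$dataset == "TARGET"))
  # accounting reconciles
  expect_equal(nrow(res$records) + sum(res$report$n_removed), 4)
})

test_that("parsing fails fatally on unreadable files and unknown dialects", {
  expect_error(parse_variants("/nonexistent/file.maf", "TARGET"),
               "cannot read")
  path <- withr::local_tempfile(fileext = ".maf")
  write_target_maf(path, list(list("S1", "TP53", "Missense_Mutation")))
  expect_error(parse_variants(path, "NOT_A_DIALECT"))
})

test_that("DKFZ-dialect files parse with ANNOVAR consequence labels", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dkfz_table(path, list(
    list("P1", "SMO", "stopgain"),
    list("P1", "PTCH1", "synonymous SNV"),
    list("P2", "SMO", "nonsynonymous SNV")))
  res <- parse_variants(path, "DKFZ")
  expect_equal(nrow(res$records), 3)
  expect_true(all(res$records$dataset == "DKFZ"))
  filt <- filter_functional(res$records)
  expect_equal(sort(unique(filt$records$consequence)),
               c("nonsynonymous SNV", "stopgain"))
  expect_equal(filt$report$n_removed[
    filt$report$rule == "non_functional_consequence"], 1)
})

test_that("functional filter applies the dialect keep-lists exactly", {
  rec <- function(consequence, dataset) {
    data.frame(sample_id = "S", gene = "G", consequence = consequence,
               cancer_type = "T", dataset = dataset,
               stringsAsFactors = FALSE)
  }
  # TARGET keeps its MAF classes, drops silent, reports unknowns
  records <- rbind(rec("Missense_Mutation", "TARGET"),
                   rec("Frame_Shift_Del", "TARGET"),
                   rec("Silent", "TARGET"),
                   rec("totally_new_class", "TARGET"))
  res <- filter_functional(records)
  expect_equal(res$records$consequence,
               c("Missense_Mutation", "Frame_Shift_Del"))
  expect_equal(res$report$n_removed[res$report$rule == "unknown_consequence"], 1)
  # DKFZ examples
  expect_equal(nrow(filter_functional(rec("stopgain", "DKFZ"))$records), 1)
  expect_equal(nrow(filter_functional(rec("synonymous SNV", "DKFZ"))$records), 0)
  # record counts always reconcile
  expect_equal(nrow(res$records) + sum(res$report$n_removed), nrow(records))
})

test_that("overlapping-gene resolution follows the annotation-voting order", {
  cand <- function(gene, status = "KNOWN", t19 = "protein_coding",
                   t27 = "protein_coding", nx = 5, nxs = 3, dash = FALSE) {
    data.frame(gene = gene, gencode_v19_status = status,
               gencode_v19_type = t19, gencode_v27_type = t27,
               n_exonic_alterations = nx, n_exonic_alterations_single = nxs,
               name_has_dash = dash, stringsAsFactors = FALSE)
  }
  # status dominates
  expect_equal(resolve_overlapping_genes(
    rbind(cand("A"), cand("B", status = "NOVEL"))), "A")
  # dash is the last resort before the alphabetical fallback
  expect_equal(resolve_overlapping_genes(
    rbind(cand("A"), cand("B-AS1", dash = TRUE))), "A")
  # higher alteration counts rank higher
  expect_equal(resolve_overlapping_genes(
    rbind(cand("A", nx = 2), cand("B", nx = 7))), "B")
  # single candidate: identity
  expect_equal(resolve_overlapping_genes(cand("Z")), "Z")
  # full tie: alphabetical with a warning
  expect_warning(g <- resolve_overlapping_genes(rbind(cand("B"), cand("A"))),
                 "tie")
  expect_equal(g, "A")
})

test_that("hypermutator threshold derives from coding length and coverage", {
  expect_identical(hypermutator_threshold(), 225L)
  expect_identical(hypermutator_threshold(1e6, 1, 10), 10L)
  expect_error(hypermutator_threshold(0, 0.95, 10), "positive")
  expect_error(hypermutator_threshold(1e6, 0, 10), "positive")
})

test_that("hypermutator flagging is strict and counts silent variants", {
  mk <- function(n, sample = "HM", consequence = "silent") {
    data.frame(sample_id = rep(sample, n), gene = sprintf("G%d", seq_len(n)),
               consequence = rep(consequence, n), cancer_type = rep("T", n),
               dataset = rep("SYNTHETIC", n), stringsAsFactors = FALSE)
  }
  records <- rbind(mk(226, "HM"), mk(225, "OK"), mk(3, "S3", "missense"))
  expect_equal(flag_hypermutators(records, 225), "HM")
  expect_equal(flag_hypermutators(mk(0), 225), character(0))
  # silent records count: the flagging must run before functional filtering
  post <- filter_functional(records)$records
  expect_equal(flag_hypermutators(post, 225), character(0))
  # gene-universe restriction
  expect_equal(flag_hypermutators(records, 2, gene_universe = c("G1", "G2")),
               character(0))
})

test_that("matrix construction collapses, filters once, and is canonical", {
  rec <- function(sample, gene) {
    data.frame(sample_id = sample, gene = gene, consequence = "missense",
               cancer_type = "T", dataset = "SYNTHETIC",
               stringsAsFactors = FALSE)
  }
  records <- rbind(
    rec("S1", "B"), rec("S1", "B"),           # two hits collapse to one
    rec("S1", "A"), rec("S2", "A"),
    rec("S2", "C"), rec("S3", "C"),
    rec("S3", "ONLY_ONCE"))                   # singleton gene
  res <- build_matrix(records)
  m <- res$matrix
  expect_equal(rownames(m), c("A", "C"))      # alphabetical, singleton gone
  expect_equal(unname(m["A", "S1"]), 1L)      # collapsed
  expect_true(all(colSums(m) >= 1))
  expect_equal(sum(res$report$n_removed[res$report$rule == "singleton_gene"]), 2)
  # idempotence: rebuilding from the retained entries reproduces the matrix
  kept <- which(unclass(m) == 1L, arr.ind = TRUE)
  again <- build_matrix(rec(colnames(m)[kept[, "col"]],
                            rownames(m)[kept[, "row"]]))$matrix
  expect_identical(unclass(again), unclass(m))
  # order independence
  shuffled <- records[sample(nrow(records)), ]
  expect_identical(unclass(build_matrix(shuffled)$matrix), unclass(m))
})

test_that("empty results and blocklists are handled fatally / reported", {
  rec <- data.frame(sample_id = "S1", gene = "A", consequence = "missense",
                    cancer_type = "T", dataset = "SYNTHETIC",
                    stringsAsFactors = FALSE)
  expect_error(build_matrix(rec), "no testable data")
  expect_error(build_matrix(rec, sample_blocklist = "S1"), "no testable data")
})

test_that("matrix round-trips through the TSV serialization", {
  set.seed(7)
  m <- prune_matrix(random_matrix(10, 20, 0.3))$matrix
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_mutation_matrix(m, p1, p2)
  m2 <- read_mutation_matrix(p1, p2)
  expect_identical(unclass(m2), unclass(m))
  expect_identical(cancer_types(m2), cancer_types(m))
})
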