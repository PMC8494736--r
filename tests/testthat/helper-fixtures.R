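# Small fixtures built in code.

tiny_matrix <- function(inc, type = "X") {
  mutation_matrix(inc, setNames(rep(type, ncol(inc)), colnames(inc)))
}

# 4 genes x 6 samples with modest margins: small enough for exhaustive
# fixed-margin enumeration, non-trivial enough to have a spread-out null.
oracle_matrix <- function() {
  inc <- matrix(0L, 4, 6,
                dimnames = list(paste0("G", 1:4), paste0("S", 1:6)))
  inc["G1", c(1, 2, 3)] <- 1L
  inc["G2", c(2, 3)] <- 1L
  inc["G3", c(1, 4, 5)] <- 1L
  inc["G4", c(5, 6)] <- 1L
  tiny_matrix(inc)
}

write_target_maf <- function(path, rows) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(Tumor_Sample_Barcode = r[[1]], Hugo_Symbol = r[[2]],
               Variant_Classification = r[[3]],
               Cancer_Type = if (length(r) > 3) r[[4]] else "TALL",
               stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_dkfz_table <- function(path, rows) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(Sample = r[[1]], Gene = r[[2]], ExonicFunc = r[[3]],
               Cancer_Type = if (length(r) > 3) r[[4]] else "MB",
               stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# random post-filter-looking matrix for invariance checks
random_matrix <- function(genes, samples, density = 0.1, type = "X") {
  inc <- matrix(rbinom(genes * samples, 1L, density), genes, samples,
                dimnames = list(sprintf("G%03d", seq_len(genes)),
                                sprintf("S%03d", seq_len(samples))))
  tiny_matrix(inc, type)
}
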