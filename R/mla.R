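# Mutation load association (MLA): logistic-regression screening of
# candidate genes for mutation-load-driven artifacts, and suspect-pair rules.
#
# Genes whose mutation probability rises (or falls) strongly with a sample's
# total mutation load tend to produce spurious mutual exclusivity with genes
# showing the opposite association — often reflecting tumor-subtype structure
# with subtype-specific loads rather than a genetic interaction.

#' Per-sample mutation load
#'
#' @param m a [mutation_matrix()].
#' @return named integer vector: number of mutated genes per sample (the
#'   matrix column sums).
#' @export
mutation_load <- function(m) {
  setNames(as.integer(colSums(m)), colnames(m))
}

#' Mutation load association scores
#'
#' For each gene, fits a logistic regression of the gene's mutation indicator
#' on the per-sample mutation load (untransformed) and reports
#' `MLA = coefficient / standard error` (a Wald statistic). Constant
#' indicators and separated fits are reported with a reason code rather than
#' an error.
#'
#' @param m a [mutation_matrix()].
#' @param genes genes to score (default: all genes in the matrix).
#' @param leave_one_out subtract the gene's own contribution from the load
#'   before regressing (sensitivity analysis; default `FALSE`, i.e. the load
#'   is taken from the same matrix marginals used by the tests).
#' @return data.frame with columns `gene`, `coefficient`, `se`, `mla`,
#'   `n_samples`, `status` (`"ok"`, `"constant_outcome"`, `"separation"`,
#'   `"not_converged"`).
#' @export
mla_score <- function(m, genes = rownames(m), leave_one_out = FALSE) {
  load_all <- as.numeric(colSums(m))
  out <- data.frame(gene = genes, coefficient = NA_real_, se = NA_real_,
                    mla = NA_real_, n_samples = ncol(m), status = "ok",
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    g <- genes[i]
    if (!g %in% rownames(m)) {
      out$status[i] <- "gene_not_in_matrix"
      next
    }
    y <- as.integer(unclass(m)[g, ])
    load <- if (leave_one_out) load_all - y else load_all
    if (length(unique(y)) < 2) {
      out$status[i] <- "constant_outcome"
      next
    }
    separated <- FALSE
    fit <- withCallingHandlers(
      glm(y ~ load, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          separated <<- TRUE
        invokeRestart("muffleWarning")
      })
    sm <- summary(fit)$coefficients
    if (separated || !fit$converged) {
      out$status[i] <- if (separated) "separation" else "not_converged"
      next
    }
    out$coefficient[i] <- sm["load", "Estimate"]
    out$se[i] <- sm["load", "Std. Error"]
    out$mla[i] <- out$coefficient[i] / out$se[i]
  }
  out
}

#' Flag suspect candidate pairs from MLA scores
#'
#' A mutually exclusive candidate is suspect when the two genes' MLA scores
#' differ by more than `threshold` and at least one exceeds `threshold`
#' (`me_rule`); a co-occurring candidate is suspect when both genes' MLA
#' scores exceed `threshold` (`co_rule`). Inequalities are strict. Pairs with
#' an undefined MLA on either side cannot be flagged and are reported in the
#' `unscored` attribute.
#'
#' @param candidates candidate data.frame with columns `gene_a`, `gene_b`,
#'   `direction`.
#' @param scores MLA score table from [mla_score()].
#' @param threshold rule threshold (default 3).
#' @return data.frame of fired flags with columns `gene_a`, `gene_b`,
#'   `direction`, `rule`, `mla_a`, `mla_b`; candidates that could not be
#'   evaluated are attached as attribute `"unscored"`.
#' @export
flag_suspects <- function(candidates, scores, threshold = 3) {
  mla_of <- setNames(scores$mla, scores$gene)
  flags <- data.frame(gene_a = character(), gene_b = character(),
                      direction = character(), rule = character(),
                      mla_a = numeric(), mla_b = numeric(),
                      stringsAsFactors = FALSE)
  unscored <- flags[, c("gene_a", "gene_b", "direction")]
  if (nrow(candidates) > 0) {
    for (i in seq_len(nrow(candidates))) {
      a <- candidates$gene_a[i]
      b <- candidates$gene_b[i]
      dir <- candidates$direction[i]
      ma <- mla_of[a]
      mb <- mla_of[b]
      if (is.na(ma) || is.na(mb)) {
        unscored <- rbind(unscored, data.frame(
          gene_a = a, gene_b = b, direction = dir, stringsAsFactors = FALSE))
        next
      }
      fired <- if (dir == "me") {
        abs(ma - mb) > threshold && max(ma, mb) > threshold
      } else {
        min(ma, mb) > threshold
      }
      if (fired) {
        flags <- rbind(flags, data.frame(
          gene_a = a, gene_b = b, direction = dir,
          rule = if (dir == "me") "me_rule" else "co_rule",
          mla_a = unname(ma), mla_b = unname(mb), stringsAsFactors = FALSE))
      }
    }
  }
  rownames(flags) <- NULL
  attr(flags, "unscored") <- unique(unscored)
  flags
}
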