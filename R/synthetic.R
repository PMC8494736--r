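# Synthetic tumor cohorts with the statistical structure the tests assume:
# per-cancer-type sample counts, long-tailed per-gene mutation frequencies,
# heavy-tailed per-sample mutation loads, subtype structure with
# subtype-specific loads, hypermutators, and planted co-occurring /
# mutually exclusive gene pairs with a known truth table.

#' Specify a synthetic cohort
#'
#' @param cancer_types named integer vector: samples per cancer type.
#' @param n_background_genes number of independent background genes.
#' @param freq_range range of background per-gene mutation frequencies. The
#'   default lower bound `NA` resolves to 1/n_samples.
#' @param freq_shape Pareto shape of the background frequency law (density
#'   proportional to `f^-(shape+1)` truncated to `freq_range`): a long-tailed
#'   law under which most genes are rare and a minority reach high
#'   frequencies, as in real tumor cohorts. Default 1.
#' @param load_sigma log-normal sigma of the per-sample load multiplier
#'   (mean 1); 0.6 mimics the dispersion of per-tumor mutated-gene counts in
#'   pediatric cohorts.
#' @param hypermutator_fraction fraction of samples with a hypermutator load
#'   multiplier.
#' @param hypermutator_multiplier load multiplier assigned to hypermutator
#'   samples in place of their background draw (default 50, in the range of
#'   real hypermutant-versus-typical burden ratios; their variant counts
#'   then exceed the hypermutator threshold almost surely).
#' @param subtypes optional named list (per cancer type) of
#'   `list(fractions, load_multipliers, n_private_genes, private_freq)`:
#'   samples of the type are split into subtypes with the given fractions,
#'   each subtype multiplies its samples' loads by its multiplier and owns
#'   `n_private_genes` genes mutated (at `private_freq`) only within it.
#' @param planted list of planted interactions, each a list with `kind`
#'   (`"mutual_exclusion"` or `"co_occurrence"`), `freq` (length-2 marginal
#'   mutation frequencies), `strength` (exclusivity in (0,1] for ME; lift > 1
#'   for co) and `mechanism` (`"direct"`, or `"subtype"` for ME pairs whose
#'   genes are made private to two different subtypes).
#' @param silent_rate silent variant rows per sample are Poisson with mean
#'   `silent_rate * load_multiplier * sum(gene frequencies)`.
#' @param extra_variant_rate additional functional variants per mutated
#'   (gene, sample) entry are Poisson with mean
#'   `extra_variant_rate * load_multiplier`.
#' @param seed optional seed stored in the spec and applied by
#'   [generate_cohort()].
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(cancer_types = c(T1 = 400, T2 = 300, T3 = 200, T4 = 100),
                        n_background_genes = 200,
                        freq_range = c(NA, 0.3),
                        freq_shape = 1,
                        load_sigma = 0.6,
                        hypermutator_fraction = 0.02,
                        hypermutator_multiplier = 50,
                        subtypes = NULL,
                        planted = list(),
                        silent_rate = 0.5,
                        extra_variant_rate = 0.2,
                        seed = NULL) {
  if (any(cancer_types < 1)) stop("sample counts must be >= 1")
  if (is.null(names(cancer_types))) stop("cancer_types must be named")
  if (load_sigma < 0 || hypermutator_fraction < 0 ||
      hypermutator_fraction > 1 || hypermutator_multiplier <= 0)
    stop("invalid load/hypermutator parameters")
  for (p in planted) {
    if (!p$kind %in% c("mutual_exclusion", "co_occurrence"))
      stop("planted kind must be mutual_exclusion or co_occurrence")
    if (any(p$freq <= 0) || any(p$freq > 1))
      stop("planted gene frequency must be in (0, 1]")
    if (p$kind == "mutual_exclusion" &&
        (p$strength <= 0 || p$strength > 1))
      stop("exclusivity must be in (0, 1]")
    if (p$kind == "co_occurrence" && p$strength <= 1)
      stop("co-occurrence lift must exceed 1")
  }
  if (!is.null(subtypes)) {
    for (st in subtypes) {
      if (abs(sum(st$fractions) - 1) > 1e-8)
        stop("subtype fractions must sum to 1")
      if (any(st$load_multipliers <= 0))
        stop("subtype load multipliers must be positive")
    }
  }
  if (freq_shape <= 0) stop("freq_shape must be positive")
  structure(list(cancer_types = cancer_types,
                 n_background_genes = n_background_genes,
                 freq_range = freq_range, freq_shape = freq_shape,
                 load_sigma = load_sigma,
                 hypermutator_fraction = hypermutator_fraction,
                 hypermutator_multiplier = hypermutator_multiplier,
                 subtypes = subtypes, planted = planted,
                 silent_rate = silent_rate,
                 extra_variant_rate = extra_variant_rate, seed = seed),
            class = "cohort_spec")
}

#' Assign subtype structure within one cancer type
#'
#' @param n number of samples of the type.
#' @param fractions subtype fractions (sum to 1).
#' @param load_multipliers per-subtype load multipliers.
#' @param names_prefix prefix for the generated subtype labels.
#' @return list with `labels` (character per sample) and `multiplier`
#'   (numeric per sample).
#' @export
add_subtype_structure <- function(n, fractions, load_multipliers,
                                  names_prefix = "sub") {
  if (abs(sum(fractions) - 1) > 1e-8) stop("subtype fractions must sum to 1")
  k <- length(fractions)
  labels_pool <- paste0(names_prefix, seq_len(k))
  labels <- sample(labels_pool, n, replace = TRUE, prob = fractions)
  list(labels = labels,
       multiplier = load_multipliers[match(labels, labels_pool)])
}

#' Impose mutual exclusivity on a planted gene pair
#'
#' Every sample carrying both genes has, with probability `exclusivity`, one
#' of the two (chosen uniformly) cleared. Margins are depressed accordingly
#' and reported, not re-balanced.
#'
#' @param inc binary incidence matrix (genes x samples) with rownames.
#' @param gene_a,gene_b the planted pair.
#' @param exclusivity probability in (0, 1] that a double-mutant is resolved.
#' @return the updated incidence matrix.
#' @export
plant_me_pair <- function(inc, gene_a, gene_b, exclusivity) {
  doubles <- which(inc[gene_a, ] == 1L & inc[gene_b, ] == 1L)
  if (length(doubles) == 0) return(inc)
  resolve <- doubles[runif(length(doubles)) < exclusivity]
  if (length(resolve) > 0) {
    clear_a <- runif(length(resolve)) < 0.5
    inc[gene_a, resolve[clear_a]] <- 0L
    inc[gene_b, resolve[!clear_a]] <- 0L
  }
  inc
}

#' Impose co-occurrence on a planted gene pair
#'
#' Redraws the two genes' columns jointly from per-sample 2x2 tables whose
#' margins equal the genes' marginal mutation probabilities and whose joint
#' mass is `lift` times the product (capped at the smaller margin where the
#' product would exceed it, e.g. for very high-load samples).
#'
#' @param inc binary incidence matrix (genes x samples) with rownames.
#' @param gene_a,gene_b the planted pair.
#' @param lift joint-probability multiplier over independence (> 1).
#' @param p_a,p_b per-sample marginal mutation probabilities of the two
#'   genes.
#' @return the updated incidence matrix.
#' @export
plant_co_pair <- function(inc, gene_a, gene_b, lift, p_a, p_b) {
  # the joint mass is capped at the Frechet bound min(p_a, p_b) per sample
  # (the cap can bind for very high-load samples); the lift is infeasible
  # when the cap would bind for the typical sample
  if (lift * stats::median(p_a * p_b) > stats::median(pmin(p_a, p_b))) {
    stop(sprintf("infeasible lift %.3g; maximal feasible lift is %.3g",
                 lift,
                 stats::median(pmin(p_a, p_b)) / stats::median(p_a * p_b)))
  }
  p11 <- pmin(lift * p_a * p_b, pmin(p_a, p_b))
  p10 <- p_a - p11
  p01 <- p_b - p11
  # one uniform per sample against the cumulative cell probabilities
  u <- runif(ncol(inc))
  a <- integer(ncol(inc))
  b <- integer(ncol(inc))
  both <- u < p11
  only_a <- !both & u < p11 + p10
  only_b <- !both & !only_a & u < p11 + p10 + p01
  a[both | only_a] <- 1L
  b[both | only_b] <- 1L
  inc[gene_a, ] <- a
  inc[gene_b, ] <- b
  inc
}

#' Generate a synthetic cohort
#'
#' Draws a binary mutation matrix per the spec — per sample s and gene g the
#' mutation probability is `min(1, freq(g) * load_mult(s) * subtype_mult)` —
#' then imposes the planted interactions, and emits a variant-level MAF-like
#' table (consequences drawn from the SYNTHETIC dialect keep-list plus silent
#' rows) so the parsing and filtering stages can be exercised end to end.
#'
#' @param spec a [cohort_spec()].
#' @param seed seed applied before generation (default: the spec's seed;
#'   `NULL` leaves the RNG state untouched).
#' @return list with `matrix` (an unpruned [mutation_matrix()]; apply
#'   [prune_matrix()] before testing), `truth` (planted-pair table, per-gene
#'   frequencies, per-sample info, seed), `variants` (MAF-like data.frame)
#'   and `spec`.
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  if (!is.null(seed)) set.seed(seed)
  n_total <- sum(spec$cancer_types)
  types <- rep(names(spec$cancer_types), spec$cancer_types)
  samples <- sprintf("%s_S%04d", types, unlist(lapply(spec$cancer_types, seq_len)))
  ct <- setNames(types, samples)

  # gene universe: background + planted + subtype-private
  bg_genes <- sprintf("BG%03d", seq_len(spec$n_background_genes))
  lo <- spec$freq_range[1]
  if (is.na(lo)) lo <- 1 / n_total
  hi <- spec$freq_range[2]
  # truncated Pareto via inverse CDF: long-tailed, most genes near `lo`
  a <- spec$freq_shape
  u <- runif(length(bg_genes))
  freq <- setNames((lo^(-a) - u * (lo^(-a) - hi^(-a)))^(-1 / a), bg_genes)
  planted_tab <- data.frame(gene_a = character(), gene_b = character(),
                            kind = character(), strength = numeric(),
                            mechanism = character(), stringsAsFactors = FALSE)
  for (k in seq_along(spec$planted)) {
    p <- spec$planted[[k]]
    tag <- if (p$kind == "mutual_exclusion") "ME" else "CO"
    ga <- sprintf("%s%dA", tag, k)
    gb <- sprintf("%s%dB", tag, k)
    freq[ga] <- p$freq[1]
    freq[gb] <- p$freq[2]
    planted_tab <- rbind(planted_tab, data.frame(
      gene_a = ga, gene_b = gb, kind = p$kind, strength = p$strength,
      mechanism = p$mechanism %||% "direct", stringsAsFactors = FALSE))
  }

  # per-sample load multipliers, hypermutators, subtypes
  load_mult <- rlnorm(n_total, -spec$load_sigma^2 / 2, spec$load_sigma)
  hyper <- runif(n_total) < spec$hypermutator_fraction
  # hypermutation is modelled as its own mechanism, not a tail of the
  # background load law: flagged samples get the fixed hypermutator
  # multiplier instead of their background draw
  load_mult[hyper] <- spec$hypermutator_multiplier
  subtype <- rep(NA_character_, n_total)
  private_owner <- list()  # gene -> c(type, subtype)
  for (ty in names(spec$subtypes %||% list())) {
    st <- spec$subtypes[[ty]]
    idx <- which(types == ty)
    asg <- add_subtype_structure(length(idx), st$fractions,
                                 st$load_multipliers,
                                 names_prefix = paste0(ty, ".sub"))
    subtype[idx] <- asg$labels
    load_mult[idx] <- load_mult[idx] * asg$multiplier
    n_priv <- st$n_private_genes %||% 0
    if (n_priv > 0) {
      for (u in seq_along(st$fractions)) {
        lab <- paste0(ty, ".sub", u)
        for (j in seq_len(n_priv)) {
          g <- sprintf("PV.%s.%02d", lab, j)
          freq[g] <- st$private_freq
          private_owner[[g]] <- lab
        }
      }
    }
  }
  # subtype-mediated planted ME pairs: genes become private to two subtypes
  for (k in seq_len(nrow(planted_tab))) {
    if (planted_tab$mechanism[k] == "subtype") {
      labs <- sort(unique(subtype[!is.na(subtype)]))
      if (length(labs) < 2)
        stop("subtype-mediated planting needs at least two subtypes")
      private_owner[[planted_tab$gene_a[k]]] <- labs[1]
      private_owner[[planted_tab$gene_b[k]]] <- labs[2]
    }
  }

  genes <- names(freq)
  prob <- pmin(outer(unname(freq), load_mult), 1)
  dimnames(prob) <- list(genes, samples)
  for (g in names(private_owner)) {
    prob[g, is.na(subtype) | subtype != private_owner[[g]]] <- 0
  }
  inc <- matrix(rbinom(length(prob), 1L, prob), nrow(prob), ncol(prob),
                dimnames = dimnames(prob))

  for (k in seq_len(nrow(planted_tab))) {
    ga <- planted_tab$gene_a[k]
    gb <- planted_tab$gene_b[k]
    if (planted_tab$kind[k] == "co_occurrence") {
      inc <- plant_co_pair(inc, ga, gb, planted_tab$strength[k],
                           prob[ga, ], prob[gb, ])
    }
  }
  for (k in seq_len(nrow(planted_tab))) {
    if (planted_tab$kind[k] == "mutual_exclusion" &&
        planted_tab$mechanism[k] == "direct") {
      inc <- plant_me_pair(inc, planted_tab$gene_a[k], planted_tab$gene_b[k],
                           planted_tab$strength[k])
    }
  }

  if (nrow(planted_tab) > 0) {
    planted_tab$co_obs <- vapply(seq_len(nrow(planted_tab)), function(k)
      sum(inc[planted_tab$gene_a[k], ] & inc[planted_tab$gene_b[k], ]),
      numeric(1))
    planted_tab$margin_a <- rowSums(inc)[planted_tab$gene_a]
    planted_tab$margin_b <- rowSums(inc)[planted_tab$gene_b]
  }

  variants <- synth_variants(inc, ct, spec, load_mult, sum(freq))
  truth <- list(planted = planted_tab,
                gene_freq = freq,
                sample_info = data.frame(
                  sample_id = samples, cancer_type = types, subtype = subtype,
                  hypermutator = hyper, load_multiplier = load_mult,
                  realized_load = colSums(inc), stringsAsFactors = FALSE),
                seed = seed)
  list(matrix = mutation_matrix(inc, ct), truth = truth, variants = variants,
       spec = spec)
}

# variant-level MAF-like table: >=1 functional variant per mutated entry,
# plus silent rows that the functional filter must remove but the
# hypermutator count must include. Variant counts scale with the sample's
# mutational intensity (its load multiplier), not with its mutated-gene
# count: the binary gene indicator saturates at the panel size, while real
# per-sample variant counts keep growing with mutation rate - which is what
# lets hypermutators exceed the count threshold.
synth_variants <- function(inc, ct, spec, load_mult, total_freq) {
  hits <- which(inc == 1L, arr.ind = TRUE)
  functional_classes <- dialect_config("SYNTHETIC")$keep_consequences
  n_var <- 1L + rpois(nrow(hits),
                      spec$extra_variant_rate * load_mult[hits[, "col"]])
  rows <- rep(seq_len(nrow(hits)), n_var)
  fun <- data.frame(
    sample_id = colnames(inc)[hits[rows, "col"]],
    gene = rownames(inc)[hits[rows, "row"]],
    consequence = sample(functional_classes, length(rows), replace = TRUE),
    stringsAsFactors = FALSE)
  n_sil <- rpois(ncol(inc), spec$silent_rate * load_mult * total_freq)
  sil <- data.frame(
    sample_id = rep(colnames(inc), n_sil),
    gene = sample(rownames(inc), sum(n_sil), replace = TRUE),
    consequence = "silent", stringsAsFactors = FALSE)
  out <- rbind(fun, sil)
  out$cancer_type <- unname(ct[out$sample_id])
  out <- out[order(out$sample_id, out$gene, out$consequence), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a synthetic cohort to disk
#'
#' Emits the matrix TSV plus sample-metadata sidecar, the MAF-like variant
#' table, and the truth table, each with a provenance header line recording
#' the seed.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  header <- sprintf("# comutmap synthetic cohort; seed=%s",
                    cohort$truth$seed %||% "NA")
  write_mutation_matrix(cohort$matrix, file.path(dir, "matrix.tsv"),
                        file.path(dir, "samples.tsv"))
  for (f in c("variants.tsv", "truth_planted.tsv", "truth_samples.tsv")) {
    writeLines(header, file.path(dir, f))
  }
  app <- function(df, f) suppressWarnings(
    write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE, append = TRUE))
  app(cohort$variants, "variants.tsv")
  app(cohort$truth$planted, "truth_planted.tsv")
  app(cohort$truth$sample_info, "truth_samples.tsv")
  invisible(dir)
}
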