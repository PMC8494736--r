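# Weighted-resampling test: weights, rate bins, the sampler's inclusion
# probabilities against an exact PPSWOR oracle, the escalation ladder, and
# pan-cancer pooling.

test_that("sample weights are load-proportional and normalized per type", {
  inc <- matrix(0L, 4, 6, dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  inc[1, ] <- 1L
  inc[2, c(1, 2)] <- 1L
  inc[3, c(1, 4, 5)] <- 1L
  inc[4, c(1, 6)] <- 1L
  m <- mutation_matrix(inc, setNames(rep(c("A", "B"), each = 3),
                                     colnames(inc)))
  w <- compute_sample_weights(m)
  ct <- cancer_types(m)
  expect_equal(sum(w[ct == "A"]), 1)
  expect_equal(sum(w[ct == "B"]), 1)
  load <- colSums(m)
  # proportionality within a type: doubling load doubles unnormalized weight
  expect_equal(w[["s1"]] / w[["s2"]], load[["s1"]] / load[["s2"]])
  # uniform loads give uniform weights
  u <- tiny_matrix(matrix(1L, 2, 4, dimnames = list(c("a", "b"),
                                                    paste0("s", 1:4))))
  expect_true(all(compute_sample_weights(u) == 0.25))
})

test_that("rate bins split at 2% of samples, boundary inclusive-high", {
  inc <- matrix(0L, 3, 100, dimnames = list(c("low1", "at2", "high5"),
                                            sprintf("s%03d", 1:100)))
  inc["low1", 1] <- 1L
  inc["at2", 1:2] <- 1L
  inc["high5", 1:5] <- 1L
  bins <- assign_rate_bins(tiny_matrix(inc))
  expect_equal(unname(bins[c("low1", "at2", "high5")]),
               c("low", "high", "high"))
})

test_that("weighted sampling matches exact PPSWOR inclusion probabilities", {
  set.seed(17)
  weights <- setNames(c(0.05, 0.1, 0.1, 0.2, 0.25, 0.3), paste0("s", 1:6))
  k <- 3
  exact <- ppswor_inclusion(unname(weights), k)
  draws <- 20000
  freq <- setNames(numeric(6), names(weights))
  for (i in seq_len(draws)) {
    got <- sample_gene_null(k, weights)
    freq[got] <- freq[got] + 1
  }
  freq <- freq / draws
  se <- sqrt(exact * (1 - exact) / draws)
  expect_true(all(abs(freq - exact) < 4 * se))
  # rank agreement: inclusion frequency increases with weight
  expect_equal(order(freq), order(weights))
  # degenerate draws
  expect_identical(sample_gene_null(0, weights), character(0))
  expect_identical(sample_gene_null(6, weights), names(weights))
  expect_error(sample_gene_null(7, weights), "exceeds")
})

test_that("compiled resampler agrees with the PPSWOR oracle", {
  # 4 weighted samples; gene A has margin 2, gene B margin 1, gene C is load
  # ballast. Under the null, P(co(A,B) >= 1) = sum_s P(B draws s) * P(s in
  # A's resampled set), both factors exactly computable by the PPSWOR oracle.
  inc <- matrix(0L, 3, 4, dimnames = list(c("A", "B", "C"), paste0("s", 1:4)))
  inc["A", c(1, 2)] <- 1L
  inc["B", 1] <- 1L
  inc["C", ] <- 1L
  m <- tiny_matrix(inc)
  w <- unname(compute_sample_weights(m))
  pi_a <- ppswor_inclusion(w, 2)
  p_hit <- sum(w * pi_a)
  set.seed(10)
  N <- 4000
  out <- wesme_test(m, ladder = N, n_null_perms = 1, min_me_pretest = 1)
  p_co <- out$p[out$gene_a == "A" & out$gene_b == "B" & out$direction == "co"]
  expected <- (1 + N * p_hit) / (1 + N)
  se <- sqrt(p_hit * (1 - p_hit) / N)
  expect_lt(abs(p_co - expected), 4 * se)
  # and the whole run is seed-deterministic
  set.seed(10)
  out2 <- wesme_test(m, ladder = N, n_null_perms = 1, min_me_pretest = 1)
  expect_identical(out, out2)
})

test_that("a gene mutated in all samples forces p_co = 1", {
  set.seed(2)
  inc <- matrix(rbinom(40, 1, 0.4), 4, 10,
                dimnames = list(c("ALL", "g2", "g3", "g4"), paste0("s", 1:10)))
  inc["ALL", ] <- 1L
  inc[cbind(2:4, 1:3)] <- 1L  # avoid zero margins
  m <- tiny_matrix(inc)
  out <- wesme_test(m, ladder = c(100, 200), n_null_perms = 3)
  co_all <- out[out$direction == "co" &
                  (out$gene_a == "ALL" | out$gene_b == "ALL"), ]
  expect_true(all(co_all$p == 1))
})

test_that("escalation ladder stops at rung 1 for unremarkable pairs", {
  set.seed(4)
  m <- prune_matrix(random_matrix(10, 40, 0.25))$matrix
  out <- wesme_test(m, ladder = c(100, 1000), n_null_perms = 3)
  # escalation looks at the smaller of a pair's two interim P-values, so
  # restrict to pairs tested in both directions with both P-values lax
  key <- paste(out$gene_a, out$gene_b)
  both_dir <- names(table(key))[table(key) == 2]
  pmin_of <- tapply(out$p, key, min)
  lax <- out[key %in% both_dir & pmin_of[key] > 0.2, ]
  expect_gt(nrow(lax), 0)
  expect_true(all(lax$resamples_used == 100))
  # resamples never exceed the cap
  expect_true(all(out$resamples_used <= 1000))
  expect_error(wesme_test(m, ladder = c(100, 100)), "increasing")
})

test_that("pre-test count filters gate the tested directions", {
  set.seed(6)
  m <- prune_matrix(random_matrix(12, 30, 0.2))$matrix
  out <- wesme_test(m, ladder = c(50, 100), n_null_perms = 3)
  expect_true(all(out$co_obs[out$direction == "co"] >= 1))
  expect_true(all(out$me_obs[out$direction == "me"] >= 3))
  ps <- count_pair_stats(m)
  skipped_co <- ps[ps$co_obs == 0, ]
  if (nrow(skipped_co) > 0) {
    k <- paste(out$gene_a, out$gene_b, out$direction)
    expect_false(any(paste(skipped_co$gene_a, skipped_co$gene_b, "co") %in% k))
  }
})

test_that("binned null P-values partition into the three bin-pair sets", {
  set.seed(12)
  m <- prune_matrix(random_matrix(15, 60, 0.15))$matrix
  nulls <- binned_null_pvalues(m, n_null_perms = 10, ladder = c(50, 100))
  expect_true(all(nulls$co$key %in% c("high-high", "high-low", "low-low")))
  expect_true(all(nulls$me$key %in% c("high-high", "high-low", "low-low")))
  expect_true(all(nulls$co$p >= 1 / 101 & nulls$co$p <= 1))
  # single-bin matrix: all genes high -> only high-high present
  inc <- matrix(1L, 3, 6, dimnames = list(letters[1:3], paste0("s", 1:6)))
  inc[1, 1:3] <- 0L
  inc[2, 4:6] <- 0L
  nb <- binned_null_pvalues(tiny_matrix(inc), n_null_perms = 5,
                            ladder = c(20, 40))
  expect_true(all(c(nb$co$key, nb$me$key) == "high-high"))
})

test_that("pan-cancer pooling reduces to the per-type test for one type", {
  set.seed(19)
  m <- prune_matrix(random_matrix(10, 25, 0.25))$matrix
  set.seed(100)
  per_type <- wesme_test(m, ladder = c(50, 100), n_null_perms = 5)
  set.seed(100)
  pan <- pan_cancer_wesme(list(X = m), ladder = c(50, 100), n_null_perms = 5)
  expect_equal(pan$p, per_type$p)
  expect_equal(pan$co_obs, per_type$co_obs)
  expect_equal(pan$mode, rep("pan", nrow(pan)))
})

test_that("pan-cancer mode pools counts but resamples within types", {
  set.seed(23)
  m1 <- prune_matrix(random_matrix(8, 20, 0.3, type = "A"))$matrix
  inc2 <- unclass(prune_matrix(random_matrix(8, 20, 0.3, type = "B"))$matrix)
  colnames(inc2) <- sprintf("T%03d", seq_len(ncol(inc2)))
  m2 <- mutation_matrix(inc2, setNames(rep("B", ncol(inc2)), colnames(inc2)))
  out <- pan_cancer_wesme(list(A = m1, B = m2), ladder = c(50, 100),
                          n_null_perms = 5)
  # pooled observed counts equal the sum over types for shared genes
  shared <- intersect(rownames(m1), rownames(m2))
  if (length(shared) >= 2) {
    g <- sort(shared[1:2])
    co_pool <- sum(m1[g[1], ] * m1[g[2], ]) + sum(m2[g[1], ] * m2[g[2], ])
    row <- out[out$gene_a == g[1] & out$gene_b == g[2], ][1, ]
    expect_equal(row$co_obs, co_pool)
  }
  # duplicate sample IDs across types are fatal
  expect_error(pan_cancer_wesme(list(A = m1, B = m1)), "disjoint")
})

test_that("replicate runs are seed-deterministic with bounded support", {
  set.seed(3)
  m <- prune_matrix(random_matrix(10, 30, 0.25))$matrix
  r1 <- run_replicates(m, n_runs = 3, seeds = c(11, 12, 13),
                       ladder = c(50, 100), n_null_perms = 5)
  r2 <- run_replicates(m, n_runs = 3, seeds = c(11, 12, 13),
                       ladder = c(50, 100), n_null_perms = 5)
  expect_identical(r1$runs, r2$runs)
  expect_true(all(r1$support$support <= 3))
  expect_error(run_replicates(m, n_runs = 2, seeds = c(5, 5)), "distinct")
})
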