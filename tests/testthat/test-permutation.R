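# Fixed-margin permutation null model: margin conservation, sampler
# uniformity against exhaustive enumeration, and the +1/+1 empirical
# P-value estimator.

test_that("pair statistics count co-occurrence and exclusivity directly", {
  inc <- matrix(0L, 3, 4, dimnames = list(c("g1", "g2", "g3"),
                                          paste0("s", 1:4)))
  inc["g1", c(1, 2)] <- 1L   # {s1, s2}
  inc["g2", c(2, 3)] <- 1L   # {s2, s3}
  inc["g3", c(1, 2)] <- 1L   # identical to g1
  ps <- count_pair_stats(tiny_matrix(inc))
  g12 <- ps[ps$gene_a == "g1" & ps$gene_b == "g2", ]
  expect_equal(g12$co_obs, 1L)
  expect_equal(g12$me_obs, 2L)
  g13 <- ps[ps$gene_a == "g1" & ps$gene_b == "g3", ]
  expect_equal(g13$co_obs, 2L)  # identical sets of size 2
  expect_equal(g13$me_obs, 0L)
  # invariant: me = margin_a + margin_b - 2 co, co <= min margin
  expect_true(all(ps$me_obs == ps$margin_a + ps$margin_b - 2 * ps$co_obs))
  expect_true(all(ps$co_obs <= pmin(ps$margin_a, ps$margin_b)))
  # fewer than two genes: empty result
  expect_equal(nrow(count_pair_stats(tiny_matrix(inc[1, , drop = FALSE]))), 0)
})

test_that("permutation preserves all margins exactly, also blockwise", {
  set.seed(11)
  m <- prune_matrix(random_matrix(15, 30, 0.2))$matrix
  for (i in 1:25) {
    p <- sample_fixed_margin_matrix(m)
    expect_identical(rowSums(p), rowSums(m))
    expect_identical(colSums(p), colSums(m))
  }
  # two-block matrix: margins preserved within each block
  inc <- unclass(prune_matrix(random_matrix(10, 24, 0.3))$matrix)
  ct <- setNames(rep(c("A", "B"), each = 12), colnames(inc))
  m2 <- mutation_matrix(inc, ct)
  for (i in 1:25) {
    p <- sample_fixed_margin_matrix(m2, block_by_cancer_type = TRUE)
    for (ty in c("A", "B")) {
      sel <- cancer_types(m2) == ty
      expect_identical(rowSums(p[, sel]), rowSums(m2[, sel]))
    }
    expect_identical(colSums(p), colSums(m2))
  }
})

test_that("a margin-forced matrix is its own only permutation", {
  inc <- matrix(1L, 3, 3, dimnames = list(letters[1:3], LETTERS[1:3]))
  m <- tiny_matrix(inc)
  expect_identical(unclass(sample_fixed_margin_matrix(m))[, ],
                   unclass(m)[, ])
})

test_that("curveball sampling visits fixed-margin matrices uniformly", {
  # 3 x 3 instance with multiple fill-ins: enumerate the space, then check
  # long-run visit frequencies within 3 sigma of uniform
  inc <- matrix(0L, 3, 3, dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  inc[1, c(1, 2)] <- 1L
  inc[2, 2:3] <- 1L
  inc[3, 1] <- 1L
  keys <- character(0)
  enumerate_fixed_margin(rowSums(inc), colSums(inc), function(mm) {
    keys <<- c(keys, matrix_key(mm))
  })
  k_space <- length(keys)
  expect_gt(k_space, 1)
  set.seed(42)
  m <- tiny_matrix(inc)
  draws <- 3000
  visits <- setNames(numeric(k_space), keys)
  for (i in seq_len(draws)) {
    p <- sample_fixed_margin_matrix(m, n_trades = 40)
    visits[matrix_key(unclass(p)[, ])] <- visits[matrix_key(unclass(p)[, ])] + 1
  }
  expect_equal(sum(visits), draws)  # never left the margin-fixed space
  p0 <- 1 / k_space
  sigma <- sqrt(p0 * (1 - p0) / draws)
  expect_true(all(abs(visits / draws - p0) < 3 * sigma + 1e-12))
})

test_that("empirical P-values match the exhaustive enumeration oracle", {
  m <- oracle_matrix()
  oracle <- exact_pair_tails(unclass(m)[, ])
  set.seed(5)
  N <- 4000
  # generous thinning so the Monte-Carlo draws are close to independent and
  # the binomial standard error applies
  ens <- build_null_ensemble(m, N = N, n_pseudo = 10, thin = 5 * sum(m))
  ps <- empirical_pvalues(count_pair_stats(m), ens)
  grid <- pair_grid(rownames(m))
  for (r in seq_len(nrow(ps))) {
    i <- match(ps$gene_a[r], rownames(m))
    j <- match(ps$gene_b[r], rownames(m))
    for (dir in c("ge", "le")) {
      exact <- if (dir == "ge") oracle$p_ge(i, j, ps$co_obs[r]) else
        oracle$p_le(i, j, ps$co_obs[r])
      est <- if (dir == "ge") ps$p_co[r] else ps$p_me[r]
      expected <- (1 + N * exact) / (1 + N)
      se <- sqrt(exact * (1 - exact) / N)
      expect_lt(abs(est - expected), 3 * se + 2 / N)
    }
  }
})

test_that("two-gene matrices give p_co = p_me = 1 (co-count is margin-forced)", {
  set.seed(3)
  for (rep in 1:5) {
    inc <- matrix(rbinom(2 * 8, 1, 0.4), 2, 8,
                  dimnames = list(c("A", "B"), paste0("s", 1:8)))
    keep <- colSums(inc) > 0
    inc <- inc[, keep, drop = FALSE]
    if (ncol(inc) < 2 || any(rowSums(inc) == 0)) next
    m <- tiny_matrix(inc)
    ens <- build_null_ensemble(m, N = 200, n_pseudo = 5)
    ps <- empirical_pvalues(count_pair_stats(m), ens)
    expect_equal(ps$p_co, 1)
    expect_equal(ps$p_me, 1)
  }
})

test_that("P-value bounds of the +1/+1 estimator hold across random matrices", {
  set.seed(9)
  m <- prune_matrix(random_matrix(12, 25, 0.25))$matrix
  N <- 500
  ens <- build_null_ensemble(m, N = N, n_pseudo = 20)
  ps <- empirical_pvalues(count_pair_stats(m), ens)
  expect_true(all(ps$p_co >= 1 / (1 + N) & ps$p_co <= 1))
  expect_true(all(ps$p_me >= 1 / (1 + N) & ps$p_me <= 1))
  # p_co + p_me = (2 + N + ties) / (1 + N) > 1
  expect_true(all(ps$p_co + ps$p_me > 1))
  # histogram mass per pair sums to N
  expect_true(all(rowSums(ens$hist) == N))
})

test_that("null P-value sets stay in bounds and are seed-deterministic", {
  set.seed(21)
  m <- prune_matrix(random_matrix(10, 20, 0.3))$matrix
  set.seed(77)
  ens1 <- build_null_ensemble(m, N = 300, n_pseudo = 25)
  s1 <- null_pvalue_set(ens1)
  set.seed(77)
  ens2 <- build_null_ensemble(m, N = 300, n_pseudo = 25)
  s2 <- null_pvalue_set(ens2)
  expect_identical(s1, s2)
  expect_true(all(s1$co >= 1 / 301 & s1$co <= 1))
  expect_true(all(s1$me >= 1 / 301 & s1$me <= 1))
  expect_length(s1$co, nrow(ens1$hist) * 25)
  expect_error(build_null_ensemble(m, N = 0), "at least 1")
})

test_that("single-block pan mode equals unblocked permutation for one type", {
  set.seed(13)
  m <- prune_matrix(random_matrix(8, 16, 0.3))$matrix
  set.seed(1)
  a <- build_null_ensemble(m, N = 100, block_by_cancer_type = TRUE)
  set.seed(1)
  b <- build_null_ensemble(m, N = 100, block_by_cancer_type = FALSE)
  expect_identical(a$hist, b$hist)
})

test_that("monte-carlo tail probabilities agree with an external null sampler", {
  skip_if_not_installed("vegan")
  set.seed(31)
  m <- prune_matrix(random_matrix(6, 12, 0.35))$matrix
  ps <- count_pair_stats(m)
  # vegan's curveball null model as an independent sampler
  nm <- vegan::nullmodel(unclass(m)[, ], "curveball")
  sims <- stats::simulate(nm, nsim = 2000, burnin = 500, thin = 20)
  pair1 <- c(ps$gene_a[1], ps$gene_b[1])
  co_null <- apply(sims, 3, function(s)
    sum(s[pair1[1], ] * s[pair1[2], ]))
  p_vegan <- (1 + sum(co_null >= ps$co_obs[1])) / (1 + length(co_null))
  set.seed(8)
  ens <- build_null_ensemble(m, N = 2000)
  p_ours <- empirical_pvalues(ps, ens)$p_co[1]
  se <- sqrt(p_vegan * (1 - p_vegan) / 2000)
  expect_lt(abs(p_ours - p_vegan), 4 * se + 5 / 2000)
})
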