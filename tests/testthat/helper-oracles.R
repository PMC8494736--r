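# Independent oracles used to validate the samplers and the FDR machinery.
# These are deliberately brute-force and share no code with the package.

# Enumerate every binary matrix with the given row and column sums, calling
# `callback(mat)` once per matrix. Feasible only for tiny instances.
enumerate_fixed_margin <- function(rowsums, colsums, callback) {
  stopifnot(sum(rowsums) == sum(colsums))
  n <- length(rowsums)
  s <- length(colsums)
  mat <- matrix(0L, n, s)
  recurse <- function(r, remaining) {
    if (r > n) {
      callback(mat)
      return(invisible(NULL))
    }
    k <- rowsums[r]
    if (k == 0) {
      mat[r, ] <<- 0L
      return(recurse(r + 1L, remaining))
    }
    cols <- which(remaining > 0)
    if (length(cols) < k) return(invisible(NULL))
    for (cc in utils::combn(cols, k, simplify = FALSE)) {
      rem2 <- remaining
      rem2[cc] <- rem2[cc] - 1L
      if (max(rem2) > n - r) next  # a column cannot be filled any more
      mat[r, ] <<- 0L
      mat[r, cc] <<- 1L
      recurse(r + 1L, rem2)
    }
    invisible(NULL)
  }
  recurse(1L, as.integer(colsums))
  invisible(NULL)
}

# Exact null distribution of the co-occurrence count of every gene pair under
# the uniform fixed-margin model: returns list(n_matrices, tail) where
# tail(i, j, obs) gives P(co >= obs) and P(co <= obs).
exact_pair_tails <- function(mat) {
  n <- nrow(mat)
  counts <- list()
  total <- 0L
  enumerate_fixed_margin(rowSums(mat), colSums(mat), function(mm) {
    total <<- total + 1L
    co <- tcrossprod(mm)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        key <- paste(i, j)
        cvec <- counts[[key]]
        if (is.null(cvec)) cvec <- integer(0)
        c_ij <- co[i, j] + 1L
        if (length(cvec) < c_ij) cvec <- c(cvec, integer(c_ij - length(cvec)))
        cvec[c_ij] <- cvec[c_ij] + 1L
        counts[[key]] <<- cvec
      }
    }
  })
  list(
    n_matrices = total,
    p_ge = function(i, j, obs) {
      cvec <- counts[[paste(i, j)]]
      sum(cvec[seq_along(cvec) - 1L >= obs]) / total
    },
    p_le = function(i, j, obs) {
      cvec <- counts[[paste(i, j)]]
      sum(cvec[seq_along(cvec) - 1L <= obs]) / total
    })
}

# Count the distinct fixed-margin matrices and the visit distribution keys.
matrix_key <- function(mat) paste(mat, collapse = "")

# Exact inclusion probabilities of weighted sampling without replacement with
# sequential renormalization (PPSWOR), by enumerating ordered draws.
ppswor_inclusion <- function(weights, k) {
  n <- length(weights)
  incl <- numeric(n)
  recurse <- function(chosen, prob) {
    if (length(chosen) == k) {
      incl[chosen] <<- incl[chosen] + prob
      return(invisible(NULL))
    }
    rem <- setdiff(seq_len(n), chosen)
    tot <- sum(weights[rem])
    for (i in rem) recurse(c(chosen, i), prob * weights[i] / tot)
    invisible(NULL)
  }
  recurse(integer(0), 1)
  incl
}

# Literal transcription of the empirical-FDR definition, evaluated per
# observed value with no vectorized shortcuts.
fdr_oracle <- function(observed, null) {
  fdr <- vapply(observed, function(pstar) {
    v <- mean(null <= pstar) * length(observed)
    r <- sum(observed <= pstar)
    v / r
  }, numeric(1))
  q <- vapply(observed, function(pstar)
    min(1, min(fdr[observed >= pstar])), numeric(1))
  list(fdr = fdr, q = q)
}
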