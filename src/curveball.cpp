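// Fixed-margin randomization of binary mutation matrices via curveball
// trades, run independently within each sample block (cancer type), plus
// co-occurrence counting utilities. All randomness comes from R's RNG so
// set.seed() in R makes every path reproducible.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline int unif_index(int n) {
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

// Internal state: per (block, gene) list of member sample indices plus a flat
// gene x sample membership table for O(1) lookups.
struct CurveballState {
  int G, S, B;
  std::vector<std::vector<std::vector<int>>> rows; // [block][gene] -> samples
  std::vector<uint8_t> mem;                        // g * S + s
  std::vector<long> ones_per_block;

  CurveballState(const IntegerMatrix& m, const IntegerVector& block, int nblocks)
      : G(m.nrow()), S(m.ncol()), B(nblocks), mem((size_t)m.nrow() * m.ncol(), 0),
        ones_per_block(nblocks, 0) {
    rows.assign(B, std::vector<std::vector<int>>(G));
    for (int s = 0; s < S; ++s) {
      int b = block[s];
      for (int g = 0; g < G; ++g) {
        if (m(g, s) != 0) {
          rows[b][g].push_back(s);
          mem[(size_t)g * S + s] = 1;
          ones_per_block[b]++;
        }
      }
    }
  }

  // One curveball trade in block b; returns true when the trade could change
  // the matrix (both genes had swappable samples).
  bool trade(int b) {
    if (G < 2) return false;
    int g1 = unif_index(G);
    int g2 = unif_index(G - 1);
    if (g2 >= g1) ++g2;
    std::vector<int>& r1 = rows[b][g1];
    std::vector<int>& r2 = rows[b][g2];
    std::vector<int> only1, only2, shared1, shared2;
    only1.reserve(r1.size());
    only2.reserve(r2.size());
    for (int s : r1) {
      if (mem[(size_t)g2 * S + s]) shared1.push_back(s); else only1.push_back(s);
    }
    if (only1.empty()) return false;
    for (int s : r2) {
      if (!mem[(size_t)g1 * S + s]) only2.push_back(s);
    }
    if (only2.empty()) return false;
    for (int s : r2) {
      if (mem[(size_t)g1 * S + s]) shared2.push_back(s);
    }
    // pool the swappable samples and deal them back at random
    std::vector<int> pool(only1);
    pool.insert(pool.end(), only2.begin(), only2.end());
    for (int i = (int)pool.size() - 1; i > 0; --i) {
      int j = unif_index(i + 1);
      std::swap(pool[i], pool[j]);
    }
    size_t k1 = only1.size();
    for (int s : only1) mem[(size_t)g1 * S + s] = 0;
    for (int s : only2) mem[(size_t)g2 * S + s] = 0;
    r1 = shared1;
    r2 = shared2;
    for (size_t i = 0; i < pool.size(); ++i) {
      if (i < k1) {
        r1.push_back(pool[i]);
        mem[(size_t)g1 * S + pool[i]] = 1;
      } else {
        r2.push_back(pool[i]);
        mem[(size_t)g2 * S + pool[i]] = 1;
      }
    }
    return true;
  }

  // Perform n trades spread over blocks proportionally to their number of
  // 1-entries. Every random gene-pair draw counts as one trade, including
  // draws whose redeal cannot change the matrix: conditioning on swappable
  // pairs would break the detailed balance that makes the chain uniform
  // over the fixed-margin space.
  void run_trades(long n_trades) {
    long total = 0;
    for (int b = 0; b < B; ++b) total += ones_per_block[b];
    if (total == 0) return;
    for (int b = 0; b < B; ++b) {
      long target = (long)((double)n_trades * ones_per_block[b] / total + 0.5);
      if (ones_per_block[b] > 0 && target < 1) target = 1;
      for (long i = 0; i < target; ++i) trade(b);
    }
  }

  void fill_matrix(IntegerMatrix& out) const {
    std::fill(out.begin(), out.end(), 0);
    for (int b = 0; b < B; ++b)
      for (int g = 0; g < G; ++g)
        for (int s : rows[b][g]) out(g, s) = 1;
  }
};

// Accumulate per-pair co-occurrence counts for the current state into co_tmp,
// recording which flat pair indices were touched. Pair (a < b) has flat index
// b*(b-1)/2 + a.
static void accumulate_co(const CurveballState& st,
                          std::vector<std::vector<int>>& col_genes,
                          std::vector<int>& co_tmp,
                          std::vector<int>& touched) {
  for (int s = 0; s < st.S; ++s) col_genes[s].clear();
  for (int b = 0; b < st.B; ++b)
    for (int g = 0; g < st.G; ++g)
      for (int s : st.rows[b][g]) col_genes[s].push_back(g);
  for (int s = 0; s < st.S; ++s) {
    std::vector<int>& gl = col_genes[s];
    std::sort(gl.begin(), gl.end());
    for (size_t i = 0; i + 1 < gl.size(); ++i) {
      int a = gl[i];
      for (size_t j = i + 1; j < gl.size(); ++j) {
        int bb = gl[j];
        int idx = bb * (bb - 1) / 2 + a;
        if (co_tmp[idx] == 0) touched.push_back(idx);
        co_tmp[idx]++;
      }
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_curveball_permute(IntegerMatrix m, IntegerVector block,
                                    int nblocks, double n_trades) {
  RNGScope scope;
  CurveballState st(m, block, nblocks);
  st.run_trades((long)n_trades);
  IntegerMatrix out(m.nrow(), m.ncol());
  st.fill_matrix(out);
  out.attr("dimnames") = m.attr("dimnames");
  return out;
}

// Build the null ensemble: N curveball-permuted matrices (blockwise), with
// per-pair histograms of null co-occurrence counts and, for the permutation
// indices listed in pseudo_idx (1-based, sorted), the full per-pair co-count
// vectors retained as the pseudo-observed reservoir.
// [[Rcpp::export]]
List cpp_perm_null(IntegerMatrix m, IntegerVector block, int nblocks,
                   int n_perm, double burn_trades, double thin_trades,
                   IntegerVector pseudo_idx, int max_co) {
  RNGScope scope;
  CurveballState st(m, block, nblocks);
  const int G = m.nrow();
  const long npairs = (long)G * (G - 1) / 2;
  IntegerMatrix hist(npairs, max_co + 1);
  IntegerMatrix pseudo(npairs, pseudo_idx.size());
  std::vector<std::vector<int>> col_genes(m.ncol());
  std::vector<int> co_tmp(npairs, 0), touched;
  touched.reserve(4096);

  st.run_trades((long)burn_trades);
  int next_pseudo = 0;
  for (int i = 1; i <= n_perm; ++i) {
    st.run_trades((long)thin_trades);
    touched.clear();
    accumulate_co(st, col_genes, co_tmp, touched);
    for (int idx : touched) {
      int c = co_tmp[idx];
      hist(idx, c > max_co ? max_co : c)++;
    }
    if (next_pseudo < pseudo_idx.size() && pseudo_idx[next_pseudo] == i) {
      for (int idx : touched) pseudo(idx, next_pseudo) = co_tmp[idx];
      ++next_pseudo;
    }
    for (int idx : touched) co_tmp[idx] = 0;
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  // zero-count column = permutations in which the pair never co-occurred
  for (long p = 0; p < npairs; ++p) {
    int nonzero = 0;
    for (int c = 1; c <= max_co; ++c) nonzero += hist(p, c);
    hist(p, 0) = n_perm - nonzero;
  }
  return List::create(_["hist"] = hist, _["pseudo_co"] = pseudo);
}

// Co-occurrence counts of all gene pairs for a chain of fixed-margin
// permutations: one curveball chain (blockwise), co counts recorded every
// `thin` trades after `burn` burn-in trades. Feeds the empirical-FDR null.
// [[Rcpp::export]]
IntegerMatrix cpp_perm_co_chain(IntegerMatrix m, IntegerVector block,
                                int nblocks, int n_perm, double burn,
                                double thin) {
  RNGScope scope;
  CurveballState st(m, block, nblocks);
  const int G = m.nrow();
  const long npairs = (long)G * (G - 1) / 2;
  IntegerMatrix out(npairs, n_perm);
  std::vector<std::vector<int>> col_genes(m.ncol());
  std::vector<int> co_tmp(npairs, 0), touched;
  st.run_trades((long)burn);
  for (int j = 0; j < n_perm; ++j) {
    st.run_trades((long)thin);
    touched.clear();
    accumulate_co(st, col_genes, co_tmp, touched);
    for (int idx : touched) {
      out(idx, j) = co_tmp[idx];
      co_tmp[idx] = 0;
    }
    if (j % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Observed co-occurrence counts for all gene pairs, exploiting sparsity.
// [[Rcpp::export]]
IntegerVector cpp_co_counts(IntegerMatrix m) {
  const int G = m.nrow(), S = m.ncol();
  const long npairs = (long)G * (G - 1) / 2;
  IntegerVector co(npairs, 0);
  std::vector<int> gl;
  for (int s = 0; s < S; ++s) {
    gl.clear();
    for (int g = 0; g < G; ++g)
      if (m(g, s) != 0) gl.push_back(g);
    for (size_t i = 0; i + 1 < gl.size(); ++i)
      for (size_t j = i + 1; j < gl.size(); ++j)
        co[(long)gl[j] * (gl[j] - 1) / 2 + gl[i]]++;
  }
  return co;
}
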