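// Weighted-resampling (WeSME-style) null model with an adaptive resampling
// ladder. Each gene's mutated-sample set is redrawn without replacement,
// within each cancer type, with per-sample probabilities proportional to
// mutation load; genes are resampled independently and null co-occurrence
// counts are pooled over types. Sampling-without-replacement is implemented
// by rejection from the full weight distribution (skipping already-selected
// samples), which is equal in distribution to sequential weighted draws with
// renormalization.
//
// The entry point scores a whole ensemble of co-count vectors (the observed
// matrix plus the fixed-margin permuted matrices feeding the empirical FDR)
// against one shared pool of null draws, accumulated as per-pair co-count
// histograms with a snapshot at every rung of the ladder. Each scored matrix
// follows its own escalation path: its P-value for a pair is read from the
// histogram snapshot of the rung at which that matrix's interim P-value
// stopped being small enough to escalate. Sharing the null draws across the
// scored matrices is what makes 300-permutation FDR nulls affordable; every
// matrix's P-value still has the adaptive-ladder distribution.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Draw one index from the cumulative weight vector by binary search.
static inline int draw_weighted(const std::vector<double>& cum) {
  double u = unif_rand() * cum.back();
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// [[Rcpp::export]]
List cpp_wesme_ensemble(IntegerMatrix margins,   // G x T per-type gene margins
                        List weights,            // per type: its samples' weights
                        List sample_of_type,     // per type: global sample idx (0-based)
                        IntegerMatrix co_mat,    // npairs x M co counts to score
                        IntegerVector margin_sum,// npairs pooled margin sums
                        IntegerVector ladder,    // e.g. 100, 1000, 10000
                        double escalate_num,     // escalate while p < this/draws
                        int min_co_pretest, int min_me_pretest) {
  RNGScope scope;
  const int G = margins.nrow(), T = margins.ncol();
  const long npairs = (long)G * (G - 1) / 2;
  const int M = co_mat.ncol();
  const int n_stages = ladder.size();
  if (co_mat.nrow() != npairs || margin_sum.size() != npairs)
    stop("pair vector length mismatch");
  for (int s = 1; s < n_stages; ++s)
    if (ladder[s] <= ladder[s - 1]) stop("ladder must be strictly increasing");

  // per-type cumulative weights and sample indices, hoisted out of Rcpp
  // proxies before the hot loops
  std::vector<std::vector<double>> cum(T);
  std::vector<std::vector<int>> sot(T);
  std::vector<int> n_of_type(T);
  int S = 0;
  for (int t = 0; t < T; ++t) {
    NumericVector w = weights[t];
    IntegerVector s_t = sample_of_type[t];
    if (s_t.size() != w.size()) stop("weights / sample index length mismatch");
    sot[t].assign(s_t.begin(), s_t.end());
    n_of_type[t] = w.size();
    S += w.size();
    cum[t].resize(w.size());
    double acc = 0;
    for (int i = 0; i < w.size(); ++i) {
      if (w[i] < 0) stop("negative sample weight");
      acc += w[i];
      cum[t][i] = acc;
    }
    if (w.size() > 0 && acc <= 0) stop("all-zero weights within a type");
    for (int g = 0; g < G; ++g)
      if (margins(g, t) > n_of_type[t])
        stop("gene margin exceeds number of samples in its type");
  }
  const int words = (S + 63) / 64;
  std::vector<int> marg(G * T);
  for (int t = 0; t < T; ++t)
    for (int g = 0; g < G; ++g) marg[(size_t)t * G + g] = margins(g, t);
  const int* cm = &co_mat[0];  // column-major: cm[p + (size_t)j * npairs]
  const int* msum = &margin_sum[0];

  int maxco = 0;
  for (int g = 0; g < G; ++g) {
    int tot = 0;
    for (int t = 0; t < T; ++t) tot += margins(g, t);
    if (tot > maxco) maxco = tot;
  }
  const int H = maxco + 1;

  // histogram of null co counts per pair, plus cumulative snapshots per rung
  std::vector<int> hist((size_t)npairs * H, 0);
  std::vector<std::vector<int>> snap(n_stages);

  // which (pair, matrix) paths are still escalating, and where each stopped
  std::vector<uint8_t> alive((size_t)npairs * M, 0);
  std::vector<uint8_t> fstage((size_t)npairs * M, 0);
  std::vector<uint8_t> pair_active(npairs, 0);
  for (int j = 0; j < M; ++j) {
    const int* col = cm + (size_t)j * npairs;
    for (long p = 0; p < npairs; ++p) {
      int co = col[p];
      int me = msum[p] - 2 * co;
      if (co >= min_co_pretest || me >= min_me_pretest) {
        alive[(size_t)p * M + j] = 1;
        pair_active[p] = 1;
      }
    }
  }

  std::vector<uint8_t> gene_active(G, 0);
  std::vector<int> active_genes, active_pairs;
  std::vector<int> pair_a(npairs), pair_b(npairs);
  {
    long p = 0;
    for (int b = 1; b < G; ++b)
      for (int a = 0; a < b; ++a, ++p) {
        pair_a[p] = a;
        pair_b[p] = b;
      }
  }
  const int CHUNK = 256;
  std::vector<uint64_t> bits;   // [gene slot][draw][word]
  std::vector<int> gene_slot(G, -1);

  int done = 0;
  for (int stage = 0; stage < n_stages; ++stage) {
    // collect the genes and pairs still in play
    active_genes.clear();
    active_pairs.clear();
    std::fill(gene_active.begin(), gene_active.end(), 0);
    for (long p = 0; p < npairs; ++p) {
      if (!pair_active[p]) continue;
      active_pairs.push_back((int)p);
      gene_active[pair_a[p]] = 1;
      gene_active[pair_b[p]] = 1;
    }
    for (int g = 0; g < G; ++g) {
      gene_slot[g] = gene_active[g] ? (int)active_genes.size() : -1;
      if (gene_active[g]) active_genes.push_back(g);
    }
    if (active_pairs.empty()) break;

    int target = ladder[stage];
    bits.assign((size_t)active_genes.size() * CHUNK * words, 0);
    for (int first = done; first < target; first += CHUNK) {
      int nd = std::min(CHUNK, target - first);
      std::fill(bits.begin(), bits.end(), 0);
      // draw nd resampled mutated-sample sets per active gene
      for (size_t gi = 0; gi < active_genes.size(); ++gi) {
        int g = active_genes[gi];
        uint64_t* gb = &bits[gi * CHUNK * words];
        for (int d = 0; d < nd; ++d) {
          uint64_t* db = gb + (size_t)d * words;
          for (int t = 0; t < T; ++t) {
            int k = marg[(size_t)t * G + g];
            if (k <= 0) continue;
            const std::vector<int>& st = sot[t];
            int nt = n_of_type[t];
            if (k >= nt) {
              for (int i = 0; i < nt; ++i) {
                int s = st[i];
                db[s >> 6] |= (uint64_t)1 << (s & 63);
              }
            } else {
              int got = 0;
              while (got < k) {
                int i = draw_weighted(cum[t]);
                int s = st[i];
                uint64_t mask = (uint64_t)1 << (s & 63);
                if (db[s >> 6] & mask) continue;
                db[s >> 6] |= mask;
                ++got;
              }
            }
          }
        }
        Rcpp::checkUserInterrupt();
      }
      // pair-major co counting into the histograms
      for (int p : active_pairs) {
        const uint64_t* pa = &bits[(size_t)gene_slot[pair_a[p]] * CHUNK * words];
        const uint64_t* pb = &bits[(size_t)gene_slot[pair_b[p]] * CHUNK * words];
        int* hrow = &hist[(size_t)p * H];
        for (int d = 0; d < nd; ++d) {
          const uint64_t* wa = pa + (size_t)d * words;
          const uint64_t* wb = pb + (size_t)d * words;
          int co = 0;
          for (int w = 0; w < words; ++w)
            co += __builtin_popcountll(wa[w] & wb[w]);
          hrow[co]++;
        }
      }
    }
    done = target;
    // cumulative snapshot: snap[stage][p*H + c] = #draws with co <= c among
    // the pair's draws so far (pairs retired earlier keep their old rows)
    snap[stage] = hist;
    std::vector<int>& cs = snap[stage];
    for (long p = 0; p < npairs; ++p) {
      int* row = &cs[(size_t)p * H];
      for (int c = 1; c < H; ++c) row[c] += row[c - 1];
    }
    // escalation decisions per scored matrix
    bool last = (stage + 1 >= n_stages);
    for (int p : active_pairs) {
      const int* row = &cs[(size_t)p * H];
      int total_draws = row[H - 1];
      bool any = false;
      for (int j = 0; j < M; ++j) {
        size_t idx = (size_t)p * M + j;
        if (!alive[idx]) continue;
        int co = cm[p + (size_t)j * npairs];
        int me = msum[p] - 2 * co;
        int le = row[co];
        int ge = total_draws - (co > 0 ? row[co - 1] : 0);
        double pmin = 2.0;
        if (co >= min_co_pretest)
          pmin = std::min(pmin, (1.0 + ge) / (1.0 + total_draws));
        if (me >= min_me_pretest)
          pmin = std::min(pmin, (1.0 + le) / (1.0 + total_draws));
        fstage[idx] = (uint8_t)stage;
        if (!last && pmin < escalate_num / total_draws) {
          any = true;
        } else {
          alive[idx] = 0;
        }
      }
      pair_active[p] = any ? 1 : 0;
    }
  }

  if (snap[0].empty()) snap[0].assign((size_t)npairs * H, 0);

  // read out P-values from the snapshot each path stopped at
  NumericMatrix p_co(npairs, M), p_me(npairs, M);
  IntegerMatrix draws_used(npairs, M);
  for (long p = 0; p < npairs; ++p) {
    for (int j = 0; j < M; ++j) {
      size_t idx = (size_t)p * M + j;
      int st = fstage[idx];
      const int* row = &snap[st][(size_t)p * H];
      int total_draws = row[H - 1];
      int co = cm[p + (size_t)j * npairs];
      int le = row[co];
      int ge = total_draws - (co > 0 ? row[co - 1] : 0);
      p_co(p, j) = (1.0 + ge) / (1.0 + total_draws);
      p_me(p, j) = (1.0 + le) / (1.0 + total_draws);
      draws_used(p, j) = total_draws;
    }
  }
  return List::create(_["p_co"] = p_co, _["p_me"] = p_me,
                      _["draws"] = draws_used);
}
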