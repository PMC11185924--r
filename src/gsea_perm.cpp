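#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Running-sum enrichment score from sorted 1-based hit positions.
//
// Walking down a ranked list of N genes, hits increment the running sum by
// w_i / S (S = sum of hit weights; all weights 1 for the classic
// Kolmogorov-Smirnov statistic) and misses decrement by 1 / (N - m). The ES
// is the signed maximum deviation from zero. Local maxima occur immediately
// after hits and local minima immediately before hits, so only those 2m
// points need inspection.
static double es_from_hits(const std::vector<int>& pos,
                           const std::vector<double>& w,
                           int N) {
  const int m = (int)pos.size();
  const double miss = 1.0 / (double)(N - m);
  double S = 0.0;
  for (int i = 0; i < m; ++i) S += w[i];
  double cum = 0.0, maxdev = R_NegInf, mindev = R_PosInf;
  for (int i = 0; i < m; ++i) {
    // value just before the i-th hit (position pos[i]-1): skip when the hit
    // opens the list, matching a running sum evaluated at positions 1..N
    double before = cum - (double)(pos[i] - 1 - i) * miss;
    if (pos[i] > 1 && before < mindev) mindev = before;
    cum += w[i] / S;
    double after = cum - (double)(pos[i] - (i + 1)) * miss;
    if (after > maxdev) maxdev = after;
    if (after < mindev) mindev = after;  // degenerate lists; keeps bounds tight
  }
  // the path ends at ~0 after the last miss; include it as a minimum candidate
  if (0.0 < mindev) mindev = 0.0;
  // signed maximum deviation; exact |max| == |min| ties resolve to the
  // positive branch, with a small epsilon so different summation orders of
  // the same path cannot flip the sign
  if (maxdev >= -mindev - 1e-12) return maxdev;
  return mindev;
}

// [[Rcpp::export(name = ".cpp_es")]]
double cpp_es(IntegerVector hit_pos, NumericVector hit_w, int n_total) {
  std::vector<int> pos(hit_pos.begin(), hit_pos.end());
  std::vector<double> w(hit_w.begin(), hit_w.end());
  return es_from_hits(pos, w, n_total);
}

// Permutation null for one ranked gene list and one or more gene sets.
//
// labels: 0-based gene index occupying each position of the ranking.
// set_membership: n_genes x n_sets logical matrix.
// pos_weight: per-position hit weight (|ranking metric|^alpha; all 1 for
//   the classic statistic). Weights stay attached to positions: shuffling
//   moves gene labels, not the ranking values.
// n_shuffle: number of positions whose labels are cyclically deranged in a
//   uniformly random order each permutation (ceiling(shuffle_fraction * N)).
//
// Uses R's RNG, so results are reproducible from set.seed(). Returns an
// n_perm x n_sets matrix of enrichment scores.
// [[Rcpp::export(name = ".cpp_gsea_null")]]
NumericMatrix cpp_gsea_null(IntegerVector labels, LogicalMatrix set_membership,
                            NumericVector pos_weight, int n_perm, int n_shuffle) {
  const int N = labels.size();
  const int n_sets = set_membership.ncol();
  if (n_shuffle < 1 || n_shuffle > N)
    stop("n_shuffle must be between 1 and the ranking length");
  NumericMatrix out(n_perm, n_sets);

  std::vector<int> lab(labels.begin(), labels.end());
  // original hit positions per set (1-based, ascending by construction)
  std::vector< std::vector<int> > orig(n_sets);
  std::vector<int> set_n(n_sets, 0);
  for (int s = 0; s < n_sets; ++s) {
    for (int p = 0; p < N; ++p)
      if (set_membership(lab[p], s)) orig[s].push_back(p + 1);
    set_n[s] = (int)orig[s].size();
    if (set_n[s] == 0) stop("a gene set has no member in the ranking");
    if (set_n[s] == N) stop("a gene set covers the whole ranking (no misses)");
  }

  std::vector<int> pool(N);
  for (int i = 0; i < N; ++i) pool[i] = i;
  std::vector<char> is_sel(N, 0);
  std::vector<int> hits;
  std::vector<double> w;
  std::vector<std::pair<int,double> > hw;
  hits.reserve(N); w.reserve(N); hw.reserve(N);

  for (int it = 0; it < n_perm; ++it) {
    // partial Fisher-Yates: pool[0..n_shuffle) is a uniform random ordered
    // sample of positions; its order doubles as the random cycle order
    for (int i = 0; i < n_shuffle; ++i) {
      int j = i + (int)(unif_rand() * (double)(N - i));
      if (j > N - 1) j = N - 1;
      std::swap(pool[i], pool[j]);
    }
    // cyclic shift of labels along the sampled order: every selected label
    // moves (a derangement when n_shuffle > 1)
    int last = pool[n_shuffle - 1];
    int carry = lab[last];
    for (int i = n_shuffle - 1; i > 0; --i) lab[pool[i]] = lab[pool[i - 1]];
    lab[pool[0]] = carry;
    for (int i = 0; i < n_shuffle; ++i) is_sel[pool[i]] = 1;

    for (int s = 0; s < n_sets; ++s) {
      hw.clear();
      for (size_t k = 0; k < orig[s].size(); ++k) {
        int p = orig[s][k];
        if (!is_sel[p - 1])
          hw.push_back(std::make_pair(p, pos_weight[p - 1]));
      }
      for (int i = 0; i < n_shuffle; ++i) {
        int q = pool[i];
        if (set_membership(lab[q], s))
          hw.push_back(std::make_pair(q + 1, pos_weight[q]));
      }
      std::sort(hw.begin(), hw.end());
      hits.clear(); w.clear();
      for (size_t k = 0; k < hw.size(); ++k) {
        hits.push_back(hw[k].first);
        w.push_back(hw[k].second);
      }
      out(it, s) = es_from_hits(hits, w, N);
    }

    // restore: reverse rotation and clear selection marks
    carry = lab[pool[0]];
    for (int i = 0; i < n_shuffle - 1; ++i) lab[pool[i]] = lab[pool[i + 1]];
    lab[last] = carry;
    for (int i = 0; i < n_shuffle; ++i) is_sel[pool[i]] = 0;
  }
  return out;
}
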