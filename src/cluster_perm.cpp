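#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Union-find with path halving.
static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// Extremal (largest |.|, sign kept) cluster maxsum for each permutation's
// t-map. Grid index p = ch + t * nch (0-based); clusters connect
// suprathreshold points of equal sign through channel adjacency at the same
// time point and through temporal contiguity at the same channel.
// T: nperm x P matrix (P = nch * nt, channel fastest). adj: per-channel
// integer vectors of 1-based neighbour channel indices.
// [[Rcpp::export]]
NumericVector extremal_maxsums_cpp(NumericMatrix T, double t_crit, List adj,
                                   int nch, int nt) {
  const int nperm = T.nrow();
  const int P = nch * nt;
  std::vector<std::vector<int>> nb(nch);
  for (int c = 0; c < nch; ++c) {
    IntegerVector v = adj[c];
    nb[c].reserve(v.size());
    for (int k = 0; k < v.size(); ++k) nb[c].push_back(v[k] - 1);
  }
  NumericVector out(nperm);
  std::vector<int> parent(P);
  std::vector<int> supra;
  std::vector<double> tv(P);
  std::vector<double> sums(P);
  for (int b = 0; b < nperm; ++b) {
    supra.clear();
    for (int p = 0; p < P; ++p) {
      double x = T(b, p);
      tv[p] = x;
      if (std::abs(x) > t_crit) {
        parent[p] = p;
        supra.push_back(p);
      } else {
        parent[p] = -1;
      }
    }
    if (supra.empty()) { out[b] = 0.0; continue; }
    for (size_t k = 0; k < supra.size(); ++k) {
      int p = supra[k];
      int ch = p % nch;
      int t = p / nch;
      bool pos = tv[p] > 0;
      if (t + 1 < nt) {
        int q = p + nch;
        if (parent[q] >= 0 && (tv[q] > 0) == pos) {
          int rp = uf_find(parent, p), rq = uf_find(parent, q);
          if (rp != rq) parent[rq] = rp;
        }
      }
      for (size_t j = 0; j < nb[ch].size(); ++j) {
        int q = t * nch + nb[ch][j];
        if (parent[q] >= 0 && (tv[q] > 0) == pos) {
          int rp = uf_find(parent, p), rq = uf_find(parent, q);
          if (rp != rq) parent[rq] = rp;
        }
      }
    }
    double best = 0.0;
    for (size_t k = 0; k < supra.size(); ++k) sums[supra[k]] = 0.0;
    for (size_t k = 0; k < supra.size(); ++k) {
      int r = uf_find(parent, supra[k]);
      sums[r] += tv[supra[k]];
    }
    for (size_t k = 0; k < supra.size(); ++k) {
      int p = supra[k];
      if (uf_find(parent, p) == p) {
        if (std::abs(sums[p]) > std::abs(best)) best = sums[p];
      }
    }
    out[b] = best;
  }
  return out;
}
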