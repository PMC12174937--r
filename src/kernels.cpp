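#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Hexagonal lattice, flat-top offset layout, 1-based (i, j) indices at the R
// level.  Even columns (1-based) are shifted up by half a cell, so the row
// offsets of the lateral neighbours depend on column parity.  Offsets below
// are 0-based; parity is that of the 1-based column index j = jj + 1.
static inline void hex_offsets(int jj, int di[6], int dj[6]) {
  // cyclic order: N, NE, SE, S, SW, NW
  static const int di_even[6] = {-1, -1, 0, 1, 0, -1};
  static const int dj_even[6] = { 0,  1, 1, 0, -1, -1};
  static const int di_odd[6]  = {-1,  0, 1, 1,  1,  0};
  static const int dj_odd[6]  = { 0,  1, 1, 0, -1, -1};
  bool even = ((jj + 1) % 2) == 0;
  for (int k = 0; k < 6; ++k) {
    di[k] = even ? di_even[k] : di_odd[k];
    dj[k] = even ? dj_even[k] : dj_odd[k];
  }
}

// Connected components of a logical mask under hexagonal adjacency.
// Returns integer labels (1, 2, ...) with 0 for cells outside the mask.
// Column parity must be that of the grid the mask came from; if the caller
// padded the mask, the pad width in columns must be even to preserve parity.
// [[Rcpp::export]]
IntegerMatrix hex_label_components(LogicalMatrix mask) {
  int m = mask.nrow(), n = mask.ncol();
  IntegerMatrix lab(m, n);
  std::vector<int> qi(static_cast<size_t>(m) * n), qj(static_cast<size_t>(m) * n);
  int next = 0;
  int di[6], dj[6];
  for (int jj = 0; jj < n; ++jj) {
    for (int ii = 0; ii < m; ++ii) {
      if (!mask(ii, jj) || lab(ii, jj) != 0) continue;
      ++next;
      int head = 0, tail = 0;
      qi[tail] = ii; qj[tail] = jj; ++tail;
      lab(ii, jj) = next;
      while (head < tail) {
        int ci = qi[head], cj = qj[head]; ++head;
        hex_offsets(cj, di, dj);
        for (int k = 0; k < 6; ++k) {
          int ni = ci + di[k], nj = cj + dj[k];
          if (ni < 0 || ni >= m || nj < 0 || nj >= n) continue;
          if (mask(ni, nj) && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            qi[tail] = ni; qj[tail] = nj; ++tail;
          }
        }
      }
    }
  }
  return lab;
}

// Per-cell neighbour statistics on the hex grid: number of affected
// (value > 0) neighbours and the maximum absolute density difference with
// the six neighbours.  Off-grid neighbours carry density 0.
// [[Rcpp::export]]
List hex_neighbor_stats(NumericMatrix field) {
  int m = field.nrow(), n = field.ncol();
  IntegerMatrix na(m, n);
  NumericMatrix dmax(m, n);
  int di[6], dj[6];
  for (int jj = 0; jj < n; ++jj) {
    hex_offsets(jj, di, dj);
    for (int ii = 0; ii < m; ++ii) {
      int cnt = 0;
      double dm = 0.0, v = field(ii, jj);
      for (int k = 0; k < 6; ++k) {
        int ni = ii + di[k], nj = jj + dj[k];
        double w = 0.0;
        if (ni >= 0 && ni < m && nj >= 0 && nj < n) w = field(ni, nj);
        if (w > 0.0) ++cnt;
        double d = std::abs(v - w);
        if (d > dm) dm = d;
      }
      na(ii, jj) = cnt;
      dmax(ii, jj) = dm;
    }
  }
  return List::create(_["na"] = na, _["dmax"] = dmax);
}

// Discrete-time birth-death chains: logistic births b_n = n b (1 - n/C) bmod,
// linear deaths d_n = d n dmod; per-step probabilities b_n/N, d_n/N.
// Evolves each entry of x0 independently for N steps using R's RNG stream.
// [[Rcpp::export]]
IntegerVector bd_simulate_cpp(IntegerVector x0, double b, double d, int C,
                              int N, double bmod, double dmod) {
  int L = x0.size();
  IntegerVector out(L);
  double dt = 1.0 / N;
  for (int l = 0; l < L; ++l) {
    int n = x0[l];
    for (int s = 0; s < N; ++s) {
      if (n == 0) break;  // extinction is absorbing
      double bn = n * b * (1.0 - (double)n / C) * bmod;
      double dn = d * n * dmod;
      double u = unif_rand();
      if (u < bn * dt) {
        if (n < C) ++n;
      } else if (u < (bn + dn) * dt) {
        --n;
      }
    }
    out[l] = n;
  }
  return out;
}
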