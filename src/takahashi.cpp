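#include <Rcpp.h>
using namespace Rcpp;

// Position of row r in the (sorted) row indices of column j, or -1.
static inline int find_pos(const IntegerVector &p, const IntegerVector &i,
                           int j, int r) {
  int lo = p[j], hi = p[j + 1] - 1;
  while (lo <= hi) {
    int mid = (lo + hi) / 2;
    if (i[mid] == r) return mid;
    if (i[mid] < r) lo = mid + 1; else hi = mid - 1;
  }
  return -1;
}

// Takahashi selected inverse of C = L D L' from a simplicial LDL'
// factor in CSC layout (row indices sorted within each column, the
// diagonal stored first; x holds D on the diagonal and L strictly
// below). Returns the entries of Z = C^{-1} on the factor pattern.
//
// Recursion (columns descending): for r > j,
//   Z_rj = -sum_{k in pattern(col j), k > j} L_kj Z(r, k)
// and Z_jj = 1/d_j - sum_k L_kj Z_kj. Every Z(r, k) the recursion
// touches lies on the filled pattern (which is closed), so the inner
// sums run as two-pointer merges of column patterns instead of lookups.
// [[Rcpp::export]]
NumericVector takahashi_inverse(IntegerVector p, IntegerVector i,
                                NumericVector x, int n) {
  NumericVector z(x.size());
  const int *pp = INTEGER(p), *ii = INTEGER(i);
  const double *xx = REAL(x);
  double *zz = REAL(z);
  int maxc = 0;
  for (int j = 0; j < n; ++j) maxc = std::max(maxc, pp[j + 1] - pp[j]);
  std::vector<double> acc(maxc, 0.0);
  for (int j = n - 1; j >= 0; --j) {
    int start = pp[j] + 1, end = pp[j + 1];   // off-diagonal range
    int c = end - start;
    std::fill(acc.begin(), acc.begin() + c, 0.0);
    for (int t = 0; t < c; ++t) {
      int b = ii[start + t];
      double Lbj = xx[start + t];
      int pb = pp[b], pbe = pp[b + 1];
      int u = t;                               // idx' entries >= b
      while (pb < pbe && u < c) {
        int ra = ii[pb], rb = ii[start + u];
        if (ra == rb) {
          double Zab = zz[pb];
          acc[u] += Lbj * Zab;                 // target row ra, k = b
          if (ra != b) acc[t] += xx[start + u] * Zab;  // target row b, k = ra
          ++pb; ++u;
        } else if (ra < rb) ++pb; else ++u;
      }
    }
    for (int t = 0; t < c; ++t) zz[start + t] = -acc[t];
    double dj = xx[pp[j]];
    double accd = 0.0;
    for (int t = 0; t < c; ++t) accd += xx[start + t] * zz[start + t];
    zz[pp[j]] = 1.0 / dj - accd;
  }
  return z;
}

// Entries Z[rows, cols] (0-based, symmetric storage on the lower
// factor pattern) from a selected inverse; absent entries are 0.
// [[Rcpp::export]]
NumericVector pattern_lookup(IntegerVector p, IntegerVector i,
                             NumericVector z, IntegerVector rows,
                             IntegerVector cols) {
  int m = rows.size();
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    int a = rows[k], b = cols[k];
    if (a < b) std::swap(a, b);
    int pos = find_pos(p, i, b, a);
    out[k] = pos < 0 ? 0.0 : z[pos];
  }
  return out;
}
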