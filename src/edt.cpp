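#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact 1D squared distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher. d[q] = min_p (q - p)^2 + f[p].
// Cells with f == Inf carry no parabola; if all are Inf, d is all Inf.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; continue; }
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * (q - v[k]));
    while (k >= 0 && s <= z[k]) {
      --k;
      if (k >= 0)
        s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
            (2.0 * (q - v[k]));
    }
    if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; }
    else { ++k; v[k] = q; z[k] = s; z[k + 1] = INF; }
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    while (z[j + 1] < q) ++j;
    double dq = (double)q - (double)v[j];
    d[q] = dq * dq + f[v[j]];
  }
}

//' Squared Euclidean distance transform of a presence mask
//'
//' For every cell of a logical matrix, the squared distance (in cell units,
//' between cell centers) to the nearest TRUE cell. All cells are Inf when the
//' mask has no TRUE cell.
//'
//' @param presence logical matrix; TRUE marks source cells.
//' @return numeric matrix of squared distances in cell units.
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix edt_squared(LogicalMatrix presence) {
  const double INF = std::numeric_limits<double>::infinity();
  int nr = presence.nrow(), nc = presence.ncol();
  NumericMatrix out(nr, nc);

  std::vector<double> f(nr), d(nr);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = presence(r, c) ? 0.0 : INF;
    dt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) out(r, c) = d[r];
  }
  std::vector<double> f2(nc), d2(nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f2[c] = out(r, c);
    dt1d(f2, d2, nc);
    for (int c = 0; c < nc; ++c) out(r, c) = d2[c];
  }
  return out;
}
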