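#include <Rcpp.h>
using namespace Rcpp;

// Histogram of pairwise orientation differences per distance annulus.
// rows/cols: integer pixel coordinates of edge elements; ori: orientation
// in degrees [0, 360); annuli: outer radii (inner edge of annulus 0 is 0).
// Counts every ordered pair (i, j), i != j: the unordered loop adds both
// the difference d and its reverse 360 - d. Squared distances between
// integer pixel coordinates are themselves integers, so the annulus of a
// pair is read from a precomputed lookup table.
// [[Rcpp::export]]
NumericMatrix cpp_pair_orientation_hist(NumericVector rows, NumericVector cols,
                                        NumericVector ori, NumericVector annuli,
                                        int B) {
  const int n = rows.size();
  const int na = annuli.size();
  std::vector<double> r2(na);
  for (int a = 0; a < na; ++a) r2[a] = annuli[a] * annuli[a];
  const double rmax2 = r2[na - 1];
  const int tab_len = (int)rmax2 + 1;
  std::vector<unsigned char> tab(tab_len);
  for (int d = 0; d < tab_len; ++d) {
    int a = 0;
    while ((double)d > r2[a]) ++a;
    tab[d] = (unsigned char)a;
  }
  // orientation expressed in bin-width units, in [0, B)
  const double binw = 360.0 / B;
  std::vector<double> ob(n);
  for (int i = 0; i < n; ++i) {
    double v = ori[i] / binw;
    v -= B * std::floor(v / B);
    ob[i] = v;
  }
  std::vector<int> rr(n), cc(n);
  for (int i = 0; i < n; ++i) { rr[i] = (int)rows[i]; cc[i] = (int)cols[i]; }
  std::vector<double> counts((size_t)na * B, 0.0);
  const int irmax2 = (int)rmax2;
  for (int i = 0; i < n; ++i) {
    const int ri = rr[i], ci = cc[i];
    const double oi = ob[i];
    for (int j = i + 1; j < n; ++j) {
      const int dx = rr[j] - ri;
      const int dy = cc[j] - ci;
      const int d2 = dx * dx + dy * dy;
      if (d2 > irmax2 || d2 == 0) continue;
      const int a = tab[d2];
      double diff = ob[j] - oi;
      if (diff < 0.0) diff += B;
      int b1 = (int)diff; if (b1 >= B) b1 = B - 1;
      double rev = B - diff;
      if (rev >= B) rev -= B;
      int b2 = (int)rev; if (b2 >= B) b2 = B - 1;
      counts[(size_t)a * B + b1] += 1.0;
      counts[(size_t)a * B + b2] += 1.0;
    }
    if ((i & 8191) == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix out(na, B);
  for (int a = 0; a < na; ++a)
    for (int b = 0; b < B; ++b) out(a, b) = counts[(size_t)a * B + b];
  return out;
}
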