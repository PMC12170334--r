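#include <Rcpp.h>
using namespace Rcpp;

// Brute-force nearest neighbour between 3D point sets. The point counts in
// this package (1e3-2e4) keep the O(n m) scan cheaper in practice than
// building a spatial index per ICP iteration.
// [[Rcpp::export(name = ".nn_bruteforce")]]
IntegerVector nn_bruteforce(NumericMatrix query, NumericMatrix ref) {
  const int n = query.nrow(), m = ref.nrow();
  IntegerVector out(n);
  const double *qx = &query(0, 0), *qy = &query(0, 1), *qz = &query(0, 2);
  const double *rx = &ref(0, 0), *ry = &ref(0, 1), *rz = &ref(0, 2);
  for (int i = 0; i < n; ++i) {
    const double px = qx[i], py = qy[i], pz = qz[i];
    double best = R_PosInf;
    int arg = 0;
    for (int j = 0; j < m; ++j) {
      const double dx = rx[j] - px;
      const double dy = ry[j] - py;
      const double dz = rz[j] - pz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        arg = j;
      }
    }
    out[i] = arg + 1;
  }
  return out;
}
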