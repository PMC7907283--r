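#include <Rcpp.h>
using namespace Rcpp;

// Nearest-neighbour queries between two planar point sets.
//
// For every query point (qx, qy) find the closest reference point (rx, ry)
// by euclidean distance. Brute force O(n*m) but allocation-free per query,
// which is faster and far more memory-frugal than materialising the full
// distance matrix in R. Ties on distance resolve to the lowest reference
// index, so callers control tie-breaking by ordering the reference set
// (e.g. by cell_id).
//
// When `self` is true the two sets are the same pattern and the pair j == i
// is skipped, giving the classic nearest "other point" distance.

// [[Rcpp::export]]
List cpp_nn(NumericVector qx, NumericVector qy,
            NumericVector rx, NumericVector ry,
            bool self = false) {
  const R_xlen_t nq = qx.size(), nr = rx.size();
  if (qy.size() != nq || ry.size() != nr)
    stop("coordinate vectors must have matching lengths");
  NumericVector dist(nq);
  IntegerVector index(nq);
  for (R_xlen_t i = 0; i < nq; ++i) {
    double best = R_PosInf;
    R_xlen_t best_j = -1;
    const double xi = qx[i], yi = qy[i];
    for (R_xlen_t j = 0; j < nr; ++j) {
      if (self && j == i) continue;
      const double dx = xi - rx[j], dy = yi - ry[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) { best = d2; best_j = j; }
    }
    dist[i] = (best_j < 0) ? NA_REAL : std::sqrt(best);
    index[i] = (best_j < 0) ? NA_INTEGER : static_cast<int>(best_j + 1);
  }
  return List::create(_["dist"] = dist, _["index"] = index);
}
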