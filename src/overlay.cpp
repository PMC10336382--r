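// Joint-occupancy overlay of two piecewise-constant branch histories.
// Segments arrive flattened and grouped by branch (same branch order in
// both inputs); within a branch, segments run rootward to tipward.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix overlay_occupancy_cpp(const IntegerVector br_x,
                                    const IntegerVector st_x,
                                    const NumericVector du_x,
                                    const IntegerVector br_y,
                                    const IntegerVector st_y,
                                    const NumericVector du_y,
                                    const int KX, const int KY,
                                    const int n_edges) {
  NumericMatrix out(KX, KY);
  int ix = 0, iy = 0;
  const int nx = br_x.size(), ny = br_y.size();
  for (int e = 1; e <= n_edges; ++e) {
    double tx = 0.0, ty = 0.0;  // time consumed on this branch
    while (ix < nx && iy < ny && br_x[ix] == e && br_y[iy] == e) {
      double end_x = tx + du_x[ix];
      double end_y = ty + du_y[iy];
      double start = std::max(tx, ty);
      double end = std::min(end_x, end_y);
      if (end > start)
        out(st_x[ix] - 1, st_y[iy] - 1) += end - start;
      if (end_x <= end_y + 1e-12) {
        tx = end_x;
        ++ix;
      } else {
        ty = end_y;
        ++iy;
      }
    }
    // numerical guard: skip any residual segments of this branch
    while (ix < nx && br_x[ix] == e) ++ix;
    while (iy < ny && br_y[iy] == e) ++iy;
  }
  return out;
}
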