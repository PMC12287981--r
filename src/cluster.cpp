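#include <Rcpp.h>
using namespace Rcpp;

// Greedy sequential clustering of stationary positions: each point joins the
// nearest existing centroid within `radius`, else opens a new cluster.
// Centroids are running dwell-weighted means. Deterministic and order-stable.
// [[Rcpp::export]]
List greedy_cluster(NumericVector x, NumericVector y, NumericVector w,
                    double radius) {
  int n = x.size();
  IntegerVector assign(n);
  std::vector<double> cx, cy, cw;
  double r2 = radius * radius;
  for (int i = 0; i < n; ++i) {
    int best = -1;
    double bestd = R_PosInf;
    for (size_t c = 0; c < cx.size(); ++c) {
      double dx = x[i] - cx[c], dy = y[i] - cy[c];
      double d2 = dx * dx + dy * dy;
      if (d2 <= r2 && d2 < bestd) { bestd = d2; best = (int)c; }
    }
    if (best < 0) {
      cx.push_back(x[i]); cy.push_back(y[i]); cw.push_back(w[i]);
      assign[i] = (int)cx.size();
    } else {
      double wn = cw[best] + w[i];
      cx[best] = (cx[best] * cw[best] + x[i] * w[i]) / wn;
      cy[best] = (cy[best] * cw[best] + y[i] * w[i]) / wn;
      cw[best] = wn;
      assign[i] = best + 1;
    }
  }
  return List::create(_["assign"] = assign, _["cx"] = wrap(cx),
                      _["cy"] = wrap(cy), _["dwell"] = wrap(cw));
}
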