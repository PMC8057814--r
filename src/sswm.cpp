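#include <Rcpp.h>
using namespace Rcpp;

// One SSWM origin-fixation walk driven by the analytic DFE.
//
// Each proposal (one time unit) draws a variance fraction v from the DVF
// and an effect sigma ~ N(-2 v z, 4 v) in scaled units; beneficial
// proposals fix with probability min(1, fixScale * sigma). Only fixations
// are recorded (time, sigma, v); the z trajectory is reconstructed from
// the cumulative sum of fixed effects.
//
// kind: 0 = exponential(vBar) truncated to (0, vMax], 1 = point mass at
// vBar, 2 = tabulated inverse-CDF on (vGrid, cdfGrid).
// [[Rcpp::export(name = ".cppSswmAnalytic")]]
List cppSswmAnalytic(double z0, double nProposals, int kind, double vBar,
                     double vMax, NumericVector vGrid, NumericVector cdfGrid,
                     double fixScale) {
  std::vector<double> ft, fs, fv;
  double z = z0;
  R_xlen_t n = (R_xlen_t) nProposals;
  int ng = vGrid.size();
  for (R_xlen_t t = 1; t <= n; ++t) {
    double v;
    if (kind == 0) {
      do {
        v = R::exp_rand() * vBar;
      } while (v > vMax);
    } else if (kind == 1) {
      v = vBar;
    } else {
      double u = R::unif_rand();
      // binary search on the tabulated CDF, linear interpolation between knots
      int lo = 0, hi = ng - 1;
      while (hi - lo > 1) {
        int mid = (lo + hi) / 2;
        if (cdfGrid[mid] < u) lo = mid; else hi = mid;
      }
      double c0 = cdfGrid[lo], c1 = cdfGrid[hi];
      double w = (c1 > c0) ? (u - c0) / (c1 - c0) : 0.0;
      v = vGrid[lo] + w * (vGrid[hi] - vGrid[lo]);
    }
    double sigma = -2.0 * v * z + 2.0 * std::sqrt(v) * R::norm_rand();
    if (sigma > 0.0) {
      double p = fixScale * sigma;
      if (p >= 1.0 || R::unif_rand() < p) {
        z += sigma;
        ft.push_back((double) t);
        fs.push_back(sigma);
        fv.push_back(v);
      }
    }
  }
  return List::create(_["time"] = wrap(ft), _["sigma"] = wrap(fs),
                      _["v"] = wrap(fv), _["zFinal"] = z);
}
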