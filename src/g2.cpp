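#include <Rcpp.h>
using namespace Rcpp;

// Stratified G^2 statistic for x _||_ y | S on 0-based integer codes.
// Degrees of freedom are computed per stratum from the observed positive
// margins, so empty rows/columns/strata do not contribute.
// [[Rcpp::export]]
List g2_stat_cpp(IntegerVector x, IntegerVector y, IntegerMatrix S,
                 int cx, int cy, IntegerVector cardS) {
  const int n = x.size();
  const int q = S.ncol();
  double ns_d = 1.0;
  for (int j = 0; j < q; ++j) ns_d *= cardS[j];
  if (ns_d > 5e6) {
    // more strata than any sample could populate: every stratum holds at
    // most one observation, dof collapses to zero
    return List::create(_["statistic"] = 0.0, _["dof"] = 0.0);
  }
  int ns = (q == 0) ? 1 : (int)ns_d;
  if (ns < 1) ns = 1;

  std::vector<double> counts((size_t)cx * cy * ns, 0.0);
  for (int i = 0; i < n; ++i) {
    int s = 0, mult = 1;
    for (int j = 0; j < q; ++j) {
      s += S(i, j) * mult;
      mult *= cardS[j];
    }
    counts[(size_t)x[i] + (size_t)cx * ((size_t)y[i] + (size_t)cy * s)] += 1.0;
  }

  double g2 = 0.0;
  double dof = 0.0;
  std::vector<double> rm(cx), cm(cy);
  for (int t = 0; t < ns; ++t) {
    double N = 0.0;
    std::fill(rm.begin(), rm.end(), 0.0);
    std::fill(cm.begin(), cm.end(), 0.0);
    const size_t base = (size_t)cx * cy * t;
    for (int j = 0; j < cy; ++j)
      for (int i = 0; i < cx; ++i) {
        const double o = counts[base + i + (size_t)cx * j];
        rm[i] += o;
        cm[j] += o;
        N += o;
      }
    if (N <= 0.0) continue;
    int rpos = 0, cpos = 0;
    for (int i = 0; i < cx; ++i) if (rm[i] > 0.0) ++rpos;
    for (int j = 0; j < cy; ++j) if (cm[j] > 0.0) ++cpos;
    dof += (double)std::max(rpos - 1, 0) * (double)std::max(cpos - 1, 0);
    for (int j = 0; j < cy; ++j)
      for (int i = 0; i < cx; ++i) {
        const double o = counts[base + i + (size_t)cx * j];
        if (o > 0.0)
          g2 += 2.0 * o * std::log(o * N / (rm[i] * cm[j]));
      }
  }
  return List::create(_["statistic"] = g2, _["dof"] = dof);
}
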