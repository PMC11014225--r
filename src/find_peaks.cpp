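#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Local maxima with topographic prominence and prominence bases,
// following the usual definition: walk outward from a peak until a
// strictly higher point (or the trace edge) is met; the minimum on each
// side bounds the peak; prominence = height - max(left min, right min).
// Returns 1-based indices.
// [[Rcpp::export(name = ".find_peaks_cpp")]]
DataFrame find_peaks_cpp(NumericVector y, double min_prominence, double min_height) {
  const int n = y.size();
  std::vector<int> idx, lb, rb;
  std::vector<double> prom;

  for (int i = 1; i + 1 < n; ++i) {
    if (!(y[i] > y[i - 1] && y[i] > y[i + 1])) continue;
    if (y[i] < min_height) continue;

    // left walk
    double lmin = y[i];
    int lpos = i;
    for (int j = i - 1; j >= 0; --j) {
      if (y[j] > y[i]) break;
      if (y[j] < lmin) { lmin = y[j]; lpos = j; }
    }
    // right walk
    double rmin = y[i];
    int rpos = i;
    for (int j = i + 1; j < n; ++j) {
      if (y[j] > y[i]) break;
      if (y[j] < rmin) { rmin = y[j]; rpos = j; }
    }
    double pr = y[i] - std::max(lmin, rmin);
    if (pr < min_prominence) continue;
    idx.push_back(i + 1);
    lb.push_back(lpos + 1);
    rb.push_back(rpos + 1);
    prom.push_back(pr);
  }

  return DataFrame::create(_["index"] = idx, _["prominence"] = prom,
                           _["left_base"] = lb, _["right_base"] = rb);
}
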