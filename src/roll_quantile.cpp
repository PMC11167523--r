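#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Centered rolling quantile down each column, window truncated at the
// edges, quantile by linear interpolation between order statistics
// (h = (m - 1) * prob, the convention of stats::quantile type 7).
// [[Rcpp::export]]
NumericMatrix roll_quantile_col(NumericMatrix x, int halfWindow, double prob) {
    const int T = x.nrow(), n = x.ncol();
    NumericMatrix out(T, n);
    std::vector<double> buf;
    for (int j = 0; j < n; ++j) {
        const double *col = &x(0, j);
        for (int t = 0; t < T; ++t) {
            int lo = std::max(0, t - halfWindow);
            int hi = std::min(T - 1, t + halfWindow);
            int m = hi - lo + 1;
            buf.assign(col + lo, col + hi + 1);
            double h = (m - 1) * prob;
            int k = (int)std::floor(h);
            double g = h - k;
            std::nth_element(buf.begin(), buf.begin() + k, buf.end());
            double q = buf[k];
            if (g > 0.0 && k + 1 < m) {
                double next = *std::min_element(buf.begin() + k + 1, buf.end());
                q += g * (next - q);
            }
            out(t, j) = q;
        }
    }
    return out;
}
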