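#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

static double median_inplace(std::vector<double>& v) {
    const size_t n = v.size();
    const size_t h = n / 2;
    std::nth_element(v.begin(), v.begin() + h, v.end());
    double m = v[h];
    if (n % 2 == 0) {
        double lo = *std::max_element(v.begin(), v.begin() + h);
        m = 0.5 * (m + lo);
    }
    return m;
}

// Per-row medians of two column groups (1-based column indices).
// Used in the permutation loop where an R apply() would dominate runtime.
// [[Rcpp::export]]
NumericMatrix row_group_medians(NumericMatrix X, IntegerVector idx1,
                                IntegerVector idx2) {
    const int G = X.nrow();
    NumericMatrix out(G, 2);
    std::vector<double> buf1(idx1.size()), buf2(idx2.size());
    for (int g = 0; g < G; ++g) {
        for (int j = 0; j < idx1.size(); ++j) buf1[j] = X(g, idx1[j] - 1);
        for (int j = 0; j < idx2.size(); ++j) buf2[j] = X(g, idx2[j] - 1);
        out(g, 0) = median_inplace(buf1);
        out(g, 1) = median_inplace(buf2);
    }
    return out;
}
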