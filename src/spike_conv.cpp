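#include <Rcpp.h>
using namespace Rcpp;

// Accumulate sum_j (k_j * s_j)(t) for multichannel kernels: each spike of
// train j adds kernel j (n_ch x n_lag, stored as the j-th slice of a
// [n_kernels x n_ch x n_lag] array) at its bin. Spike bins are 1-based;
// contributions extending past n_time are truncated.
// [[Rcpp::export]]
NumericMatrix spike_conv_cpp(NumericVector kernels, List spike_bins,
                             int n_ch, int n_lag, int n_time) {
  const int n_k = spike_bins.size();
  NumericMatrix out(n_ch, n_time);
  const double* K = REAL(kernels);
  double* O = REAL(out);
  for (int j = 0; j < n_k; ++j) {
    IntegerVector b = spike_bins[j];
    for (int s = 0; s < b.size(); ++s) {
      const int t0 = b[s] - 1;                       // 0-based start bin
      const int lmax = std::min(n_lag, n_time - t0);
      for (int l = 0; l < lmax; ++l) {
        double* ocol = O + (size_t)(t0 + l) * n_ch;
        // kernel element (j, c, l) at K[j + n_k*(c + n_ch*l)]
        const double* kcl = K + (size_t)j + (size_t)n_k * (size_t)n_ch * l;
        for (int c = 0; c < n_ch; ++c)
          ocol[c] += kcl[(size_t)n_k * c];
      }
    }
  }
  return out;
}
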