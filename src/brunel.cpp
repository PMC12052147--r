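#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Sparse random balanced network of leaky integrate-and-fire neurons with
// instantaneous (delta) current jumps, fixed in-degree connectivity and
// external Poisson drive. Exact subthreshold propagator between jumps.
// Records spike times of the first n_record excitatory neurons and the
// per-step spike count of the whole excitatory population.
// [[Rcpp::export]]
List brunel_cpp(int n_e, int n_i, int c_e, int c_i,
                double J, double g, double nu_ext_per_ms,
                int delay_steps, double dt, int steps,
                double tau_m, double theta, double v_reset,
                int ref_steps, int n_record) {
  RNGScope scope;
  const int n = n_e + n_i;

  // fixed in-degree wiring: for each target draw c_e excitatory and c_i
  // inhibitory sources (with replacement, as in fixed-indegree samplers);
  // store as out-lists (CSR over sources) for spike propagation
  std::vector<int> out_count(n, 0);
  std::vector<int> src_flat((size_t)n * (c_e + c_i));
  std::vector<int> tgt_flat((size_t)n * (c_e + c_i));
  size_t idx = 0;
  for (int t = 0; t < n; ++t) {
    for (int k = 0; k < c_e; ++k) {
      int s = (int)(unif_rand() * n_e);
      if (s >= n_e) s = n_e - 1;
      src_flat[idx] = s; tgt_flat[idx] = t; ++out_count[s]; ++idx;
    }
    for (int k = 0; k < c_i; ++k) {
      int s = n_e + (int)(unif_rand() * n_i);
      if (s >= n) s = n - 1;
      src_flat[idx] = s; tgt_flat[idx] = t; ++out_count[s]; ++idx;
    }
  }
  std::vector<size_t> out_start(n + 1, 0);
  for (int s = 0; s < n; ++s) out_start[s + 1] = out_start[s] + out_count[s];
  std::vector<int> targets(idx);
  {
    std::vector<size_t> cur(out_start.begin(), out_start.end() - 1);
    for (size_t e = 0; e < idx; ++e) targets[cur[src_flat[e]]++] = tgt_flat[e];
  }
  src_flat.clear(); src_flat.shrink_to_fit();
  tgt_flat.clear(); tgt_flat.shrink_to_fit();

  const double prop = std::exp(-dt / tau_m);
  const double w_e = J, w_i = -g * J;
  const double lam = nu_ext_per_ms * dt;          // external spikes per step
  const int buflen = delay_steps + 1;

  std::vector<double> v(n, 0.0);
  std::vector<int> ref(n, 0);
  std::vector<double> buf((size_t)n * buflen, 0.0);
  std::vector<double> rec_times;
  std::vector<int> rec_ids;
  IntegerVector e_count(steps);
  std::vector<int> spikers;
  spikers.reserve(n);

  for (int step = 0; step < steps; ++step) {
    const int slot = step % buflen;
    const int dslot = (step + delay_steps) % buflen;
    spikers.clear();
    int ecnt = 0;
    for (int i = 0; i < n; ++i) {
      double* b = &buf[(size_t)i * buflen];
      const double inc = b[slot];
      b[slot] = 0.0;
      if (ref[i] > 0) { --ref[i]; v[i] = v_reset; continue; }
      double vi = v[i] * prop + inc + w_e * R::rpois(lam);
      if (vi >= theta) {
        spikers.push_back(i);
        if (i < n_e) {
          ++ecnt;
          if (i < n_record) {
            rec_times.push_back(step * dt);
            rec_ids.push_back(i + 1);
          }
        }
        vi = v_reset;
        ref[i] = ref_steps;
      }
      v[i] = vi;
    }
    e_count[step] = ecnt;
    for (size_t k = 0; k < spikers.size(); ++k) {
      const int s = spikers[k];
      const double w = (s < n_e) ? w_e : w_i;
      for (size_t e = out_start[s]; e < out_start[s + 1]; ++e)
        buf[(size_t)targets[e] * buflen + dslot] += w;
    }
  }
  return List::create(_["times"] = wrap(rec_times),
                      _["ids"] = wrap(rec_ids),
                      _["e_count"] = e_count);
}
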