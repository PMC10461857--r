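#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Forward-Euler leaky integrate-and-fire network with delta synapses,
// synaptic delay (ring buffer of spiker lists), refractory clamp at V_r and
// white-noise input drawn from R's RNG (so set.seed() in R controls the run).
//
// Connectivity: optional sparse E-I matrix in CSC layout (jp, ji, jx; column
// j = presynaptic neuron) plus optional factored low-rank part P = m n^T / N
// whose spike-triggered kick is m * (n^T s) / N per arriving spike vector s.
// Each presynaptic spike adds an instantaneous jump of J_ij mV to the
// postsynaptic potential tau_del later (the tau_m * J * delta current
// integrates to a J_ij jump).
//
// noise_convention: 1 -> V-jump sigma0 * sqrt(dt / tau_m) * eta  (stationary
// Var(V) = sigma0^2 / 2); 2 -> V-jump sigma0 * sqrt(dt) * eta.
// [[Rcpp::export]]
List lif_core_cpp(int N,
                  IntegerVector jp, IntegerVector ji, NumericVector jx,
                  bool has_ei,
                  NumericMatrix mfac, NumericMatrix nfac, bool has_lowrank,
                  NumericMatrix Imat, NumericMatrix umat, bool has_input,
                  double mu0, double sigma0, double tau_m,
                  double v_thr, double v_r, double tau_ref, double tau_del,
                  double dt, int n_steps,
                  NumericVector V0, int noise_convention, double rate_cap) {
  const int R = has_lowrank ? mfac.ncol() : 0;
  const int n_in = has_input ? Imat.ncol() : 0;
  const int D = std::max(1, (int)std::lround(tau_del / dt));
  const int ref_steps = (int)std::lround(tau_ref / dt);
  const double a = dt / tau_m;
  const double noise_scale =
      (noise_convention == 2) ? sigma0 * std::sqrt(dt)
                              : sigma0 * std::sqrt(dt / tau_m);

  std::vector<double> V(V0.begin(), V0.end());
  std::vector<int> ref(N, 0);
  std::vector<std::vector<int>> buf(D + 1);
  std::vector<double> kick(N, 0.0);
  std::vector<double> nsum(std::max(R, 1), 0.0);

  std::vector<double> spike_t;
  std::vector<int> spike_i;
  spike_t.reserve(1024);
  spike_i.reserve(1024);

  for (int t = 0; t < n_steps; ++t) {
    // deliver spikes scheduled for this step
    std::vector<int> &arriving = buf[t % (D + 1)];
    std::fill(kick.begin(), kick.end(), 0.0);
    if (!arriving.empty()) {
      if (has_ei) {
        for (int j : arriving)
          for (int k = jp[j]; k < jp[j + 1]; ++k) kick[ji[k]] += jx[k];
      }
      if (has_lowrank) {
        std::fill(nsum.begin(), nsum.end(), 0.0);
        for (int j : arriving)
          for (int r = 0; r < R; ++r) nsum[r] += nfac(j, r);
        for (int r = 0; r < R; ++r) nsum[r] /= (double)N;
        for (int i = 0; i < N; ++i) {
          double s = 0.0;
          for (int r = 0; r < R; ++r) s += mfac(i, r) * nsum[r];
          kick[i] += s;
        }
      }
      arriving.clear();
    }

    int n_spk = 0;
    std::vector<int> &outslot = buf[(t + D) % (D + 1)];
    for (int i = 0; i < N; ++i) {
      if (ref[i] > 0) {  // clamped at reset during refractoriness
        --ref[i];
        V[i] = v_r;
        continue;
      }
      double inp = mu0;
      for (int s = 0; s < n_in; ++s) inp += Imat(i, s) * umat(t, s);
      V[i] += a * (-V[i] + inp);
      if (sigma0 > 0.0) V[i] += noise_scale * norm_rand();
      V[i] += kick[i];
      if (V[i] >= v_thr) {
        spike_t.push_back((t + 1) * dt);
        spike_i.push_back(i + 1);  // 1-based for R
        V[i] = v_r;
        ref[i] = ref_steps;
        outslot.push_back(i);
        ++n_spk;
      }
    }
    if (rate_cap < R_PosInf) {
      double pop_rate = (double)n_spk / ((double)N * dt * 1e-3);  // spk/s
      if (pop_rate > rate_cap)
        stop("population rate runaway: %.0f spk/s at t = %.1f ms exceeds the "
             "cap of %.0f spk/s", pop_rate, (t + 1) * dt, rate_cap);
    }
  }

  return List::create(_["time"] = NumericVector(spike_t.begin(), spike_t.end()),
                      _["neuron"] = IntegerVector(spike_i.begin(), spike_i.end()),
                      _["V"] = NumericVector(V.begin(), V.end()));
}
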