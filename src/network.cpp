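// Forward-Euler integrator for a network of exponential integrate-and-fire
// neurons with difference-of-exponentials synapses and external Poisson
// drive. Synaptic state is kept per (kernel, target neuron) as a pair of
// exponential accumulators; the decay, current summation and membrane
// update are fused into a single pass per step so the state stays in
// cache. The spike-initiation exponential uses single precision: its
// relative error (~1e-7) is far below the Euler discretization error.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List simulate_eif_cpp(int n_neurons,
                      NumericVector tau_m,    // ms, per neuron
                      NumericVector E_L,      // mV
                      NumericVector V_T,      // mV
                      NumericVector V_th,     // mV
                      NumericVector Delta_T,  // mV
                      NumericVector V_re,     // mV
                      NumericVector tau_ref,  // ms
                      NumericVector mu,       // mV/ms static current
                      NumericVector ker_tau_r,    // kernel rise, ms
                      NumericVector ker_tau_d,    // kernel decay, ms
                      IntegerVector syn_offset,   // CSR by source, n_neurons + 1
                      IntegerVector syn_tgt,      // 0-based
                      NumericVector syn_w,        // mV (already 1/sqrt(N) scaled)
                      IntegerVector syn_ker,      // 0-based kernel id
                      int n_pois,
                      double pois_rate,           // Hz
                      IntegerVector pois_offset,
                      IntegerVector pois_tgt,
                      NumericVector pois_w,
                      IntegerVector pois_ker,
                      double mix_fast,            // mixed-kernel (id 3) split
                      double mix_slow,
                      double dt,                  // ms
                      double duration,            // ms
                      double record_start) {      // ms
  const int n_ker = ker_tau_r.size();
  const int n_steps = (int)std::round(duration / dt);
  const double p_pois = pois_rate * dt * 1e-3;

  std::vector<float> V(n_neurons);
  std::vector<int> refrac(n_neurons, 0);
  std::vector<float> inv_tau(n_neurons), vEL(n_neurons), vVT(n_neurons),
      vVth(n_neurons), vDT(n_neurons), invDT(n_neurons), vVre(n_neurons),
      vmu(n_neurons);
  std::vector<int> ref_steps(n_neurons);
  for (int j = 0; j < n_neurons; ++j) {
    V[j] = (float)E_L[j];
    inv_tau[j] = (float)(dt / tau_m[j]);
    vEL[j] = (float)E_L[j];
    vVT[j] = (float)V_T[j];
    vVth[j] = (float)V_th[j];
    vDT[j] = (float)Delta_T[j];
    invDT[j] = (float)(1.0 / Delta_T[j]);
    vVre[j] = (float)V_re[j];
    vmu[j] = (float)(dt * mu[j]);
    ref_steps[j] = (int)std::round(tau_ref[j] / dt);
  }

  std::vector< std::vector<float> > xd(n_ker), xr(n_ker);
  std::vector<float> dec_d(n_ker), dec_r(n_ker);
  std::vector<double> norm(n_ker);
  for (int k = 0; k < n_ker; ++k) {
    xd[k].assign(n_neurons, 0.0f);
    xr[k].assign(n_neurons, 0.0f);
    dec_d[k] = (float)std::exp(-dt / ker_tau_d[k]);
    dec_r[k] = (float)std::exp(-dt / ker_tau_r[k]);
    norm[k] = 1.0 / (ker_tau_d[k] - ker_tau_r[k]);
  }

  std::vector<double> out_t;
  std::vector<int> out_id;
  std::vector<int> spiked;
  spiked.reserve(1024);

  GetRNGstate();
  for (int s = 0; s < n_steps; ++s) {
    const double t = s * dt;
    // external Poisson spikes
    if (n_pois > 0 && p_pois > 0) {
      for (int p = 0; p < n_pois; ++p) {
        if (unif_rand() < p_pois) {
          for (int q = pois_offset[p]; q < pois_offset[p + 1]; ++q) {
            const int kk = pois_ker[q];
            const int tg = pois_tgt[q];
            if (kk == 3) {
              const float af = (float)(pois_w[q] * mix_fast * norm[0]);
              const float as = (float)(pois_w[q] * mix_slow * norm[2]);
              xd[0][tg] += af; xr[0][tg] += af;
              xd[2][tg] += as; xr[2][tg] += as;
            } else {
              const float amp = (float)(pois_w[q] * norm[kk]);
              xd[kk][tg] += amp;
              xr[kk][tg] += amp;
            }
          }
        }
      }
    }
    // fused decay + current + membrane update
    spiked.clear();
    {
      float *d0 = xd[0].data(), *r0 = xr[0].data();
      float *d1 = xd[1].data(), *r1 = xr[1].data();
      float *d2 = n_ker > 2 ? xd[2].data() : NULL;
      float *r2 = n_ker > 2 ? xr[2].data() : NULL;
      const float dd0 = dec_d[0], rr0 = dec_r[0];
      const float dd1 = dec_d[1], rr1 = dec_r[1];
      const float dd2 = n_ker > 2 ? dec_d[2] : 0.0f;
      const float rr2 = n_ker > 2 ? dec_r[2] : 0.0f;
      for (int j = 0; j < n_neurons; ++j) {
        d0[j] *= dd0; r0[j] *= rr0;
        d1[j] *= dd1; r1[j] *= rr1;
        float I = vmu[j] + dt * (d0[j] - r0[j] + d1[j] - r1[j]);
        if (d2) {
          d2[j] *= dd2; r2[j] *= rr2;
          I += dt * (d2[j] - r2[j]);
        }
        if (refrac[j] > 0) { --refrac[j]; V[j] = vVre[j]; continue; }
        float ex = (V[j] - vVT[j]) * invDT[j];
        if (ex > 30.0f) ex = 30.0f;  // membrane clamped pre-spike
        V[j] += inv_tau[j] * (-(V[j] - vEL[j]) + vDT[j] * expf(ex)) + I;
        if (V[j] > vVth[j]) {
          spiked.push_back(j);
          V[j] = vVre[j];
          refrac[j] = ref_steps[j];
          if (t >= record_start) {
            out_t.push_back(t - record_start);
            out_id.push_back(j);
          }
        }
      }
    }
    // propagate recurrent spikes
    for (size_t m = 0; m < spiked.size(); ++m) {
      const int j = spiked[m];
      for (int q = syn_offset[j]; q < syn_offset[j + 1]; ++q) {
        const int kk = syn_ker[q];
        const int tg = syn_tgt[q];
        if (kk == 3) {
          const float af = (float)(syn_w[q] * mix_fast * norm[0]);
          const float as = (float)(syn_w[q] * mix_slow * norm[2]);
          xd[0][tg] += af; xr[0][tg] += af;
          xd[2][tg] += as; xr[2][tg] += as;
        } else {
          const float amp = (float)(syn_w[q] * norm[kk]);
          xd[kk][tg] += amp;
          xr[kk][tg] += amp;
        }
      }
    }
    if (s % 20000 == 0) Rcpp::checkUserInterrupt();
  }
  PutRNGstate();

  return List::create(_["time_ms"] = NumericVector(out_t.begin(), out_t.end()),
                      _["neuron"] = IntegerVector(out_id.begin(), out_id.end()));
}
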