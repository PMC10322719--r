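#include <Rcpp.h>
using namespace Rcpp;

// Adaptive exponential integrate-and-fire, forward Euler.
// Units: mV, ms, pA, pF, nS (so dV/dt = pA/pF = mV/ms).
// I_inj: injected current per sample (pA), length n gives trace length.
// noise: pre-scaled current noise per sample (pA), length n or 0.
// A spike is registered when V crosses v_peak; V is reset and held for
// t_ref ms while w keeps evolving.
// [[Rcpp::export]]
List adex_integrate_cpp(NumericVector I_inj, NumericVector noise,
                        double dt,
                        double C, double gL, double EL,
                        double VT, double DeltaT,
                        double a, double tau_w, double b,
                        double Vreset, double Vpeak,
                        double V0, double w0, double t_ref) {
  const int n = I_inj.size();
  const bool has_noise = noise.size() == n;
  NumericVector V(n);
  std::vector<int> spikes;
  double v = V0, w = w0;
  int ref_until = -1;
  for (int i = 0; i < n; ++i) {
    if (i <= ref_until) {
      // refractory clamp: V pinned at reset, adaptation relaxes
      w += dt * (a * (v - EL) - w) / tau_w;
      V[i] = v;
      continue;
    }
    double ex = (v - VT) / DeltaT;
    if (ex > 20.0) ex = 20.0;  // cap the spike-initiation exponential
    double I = I_inj[i] + (has_noise ? noise[i] : 0.0);
    double dv = (-gL * (v - EL) + gL * DeltaT * std::exp(ex) - w + I) / C;
    double dw = (a * (v - EL) - w) / tau_w;
    v += dt * dv;
    w += dt * dw;
    if (v >= Vpeak) {
      spikes.push_back(i + 1);  // 1-based sample index
      v = Vreset;
      w += b;
      ref_until = i + (int)std::floor(t_ref / dt);
    }
    V[i] = v;
  }
  return List::create(_["V"] = V, _["spikes"] = wrap(spikes));
}
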