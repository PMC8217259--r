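// Core stepper for the stochastic modified-theta network.
//
// Phase dynamics (Stratonovich):
//   C dtheta = [-gL cos(th) + c1 I (1+cos th) + g (c2 (1+cos th) - sin th)] dt
//              + c1 sigma (1+cos th) o dW
// Two schemes target the same (Stratonovich) Fokker-Planck equation:
//   heun  - stochastic Heun (predictor/corrector), Stratonovich-consistent;
//   euler - Euler-Maruyama plus the explicit drift correction (w/2) dw/dth.
// A spike is an upward crossing of theta = pi within a step; the phase is
// wrapped by -2*pi. The shared conductance decays exactly over dt and is
// incremented by g_peak * P_syn * N * A * dt with A = spikes/(N*dt); the
// delta-kick variant instead keeps one conductance per neuron, kicked by
// g_peak per connected presynaptic spike.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Fields {
  double C, gL, c1, c2, sigma;
};

inline double drift(double th, double I, double g, const Fields& fl) {
  double c = std::cos(th);
  return (-fl.gL * c + fl.c1 * I * (1.0 + c) +
          g * (fl.c2 * (1.0 + c) - std::sin(th))) / fl.C;
}

inline double diffus(double th, const Fields& fl) {
  return fl.c1 * fl.sigma * (1.0 + std::cos(th)) / fl.C;
}

// (w/2) dw/dtheta, the Stratonovich drift correction
inline double strat_corr(double th, const Fields& fl) {
  double a = fl.c1 * fl.sigma / fl.C;
  return -0.5 * a * a * (1.0 + std::cos(th)) * std::sin(th);
}

} // namespace

// [[Rcpp::export(name = ".mt_run_cpp")]]
List mt_run_cpp(NumericVector theta0, NumericVector I, NumericVector gsyn0,
                double C, double gL, double VT, double VR, double Vsyn,
                double tau_d, double g_peak, double P_syn, double sigma,
                double dt, int nsteps, double t0,
                int scheme,          // 0 = heun, 1 = euler(+correction)
                int coupling,        // 0 = shared mean-field, 1 = delta-kick
                List adjacency,      // coupling == 1: targets per neuron (1-based)
                bool record_phases, int phase_stride) {
  const int N = theta0.size();
  Fields fl{C, gL, 2.0 / (VT - VR), (2.0 * Vsyn - VT - VR) / (VT - VR), sigma};
  const double dec = std::exp(-dt / tau_d);
  const double sqdt = std::sqrt(dt);

  std::vector<double> th(theta0.begin(), theta0.end());
  std::vector<double> g(gsyn0.begin(), gsyn0.end());
  if (coupling == 0 && (int)g.size() != 1)
    stop("shared coupling expects a single g_syn value");
  if (coupling == 1 && (int)g.size() != N)
    stop("delta-kick coupling expects one g_syn per neuron");

  NumericVector g_trace(nsteps), A_trace(nsteps);
  std::vector<double> spk_t;
  std::vector<int> spk_i, fired, kicks;
  fired.reserve(64);
  if (coupling == 1) kicks.assign(N, 0);

  int nsnap = record_phases ? (nsteps / phase_stride) : 0;
  NumericMatrix phases(record_phases ? nsnap : 0, record_phases ? N : 0);
  NumericVector snap_t(record_phases ? nsnap : 0);
  int isnap = 0;

  bool noisy = sigma > 0.0;

  for (int s = 0; s < nsteps; ++s) {
    fired.clear();
    for (int i = 0; i < N; ++i) {
      double gi = (coupling == 0) ? g[0] : g[i];
      double t_old = th[i];
      double dW = noisy ? R::norm_rand() * sqdt : 0.0;
      double t_new;
      if (scheme == 0) {  // stochastic Heun
        double u0 = drift(t_old, I[i], gi, fl);
        double w0 = diffus(t_old, fl);
        double tp = t_old + u0 * dt + w0 * dW;
        double u1 = drift(tp, I[i], gi, fl);
        double w1 = diffus(tp, fl);
        t_new = t_old + 0.5 * (u0 + u1) * dt + 0.5 * (w0 + w1) * dW;
      } else {            // Euler-Maruyama + Stratonovich correction
        double u0 = drift(t_old, I[i], gi, fl) + strat_corr(t_old, fl);
        t_new = t_old + u0 * dt + diffus(t_old, fl) * dW;
      }
      if (!std::isfinite(t_new))
        stop("non-finite phase at t=%.3f (neuron %d): reduce dt", t0 + s * dt, i + 1);
      if (t_new >= M_PI) {          // upward crossing of pi: spike + wrap
        t_new -= 2.0 * M_PI;
        fired.push_back(i);
        spk_t.push_back(t0 + (s + 1) * dt);
        spk_i.push_back(i + 1);
      } else if (t_new < -M_PI) {   // backward slip through the firing point
        t_new += 2.0 * M_PI;
      }
      th[i] = t_new;
    }

    int nspk = (int)fired.size();
    double A = nspk / ((double)N * dt);
    if (coupling == 0) {
      g[0] = g[0] * dec + g_peak * P_syn * (double)nspk; // = g_peak*P_syn*N*A*dt
      g_trace[s] = g[0];
    } else {
      std::fill(kicks.begin(), kicks.end(), 0);
      for (int k = 0; k < nspk; ++k) {
        IntegerVector tgt = adjacency[fired[k]];
        for (int m = 0; m < tgt.size(); ++m) ++kicks[tgt[m] - 1];
      }
      double gm = 0.0;
      for (int i = 0; i < N; ++i) {
        // same fused update as the shared-conductance branch, so that
        // P_syn = 1 reproduces it exactly
        g[i] = g[i] * dec + g_peak * (double)kicks[i];
        gm += g[i];
      }
      g_trace[s] = gm / N;          // population-mean conductance
    }
    A_trace[s] = A;

    if (record_phases && ((s + 1) % phase_stride == 0) && isnap < nsnap) {
      for (int i = 0; i < N; ++i) phases(isnap, i) = th[i];
      snap_t[isnap] = t0 + (s + 1) * dt;
      ++isnap;
    }
  }

  List out = List::create(
    _["theta"] = NumericVector(th.begin(), th.end()),
    _["g_syn"] = NumericVector(g.begin(), g.end()),
    _["g_trace"] = g_trace,
    _["A_trace"] = A_trace,
    _["spike_times"] = NumericVector(spk_t.begin(), spk_t.end()),
    _["spike_neuron"] = IntegerVector(spk_i.begin(), spk_i.end()));
  if (record_phases) {
    out["phase_snapshots"] = phases;
    out["snapshot_times"] = snap_t;
  }
  return out;
}
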