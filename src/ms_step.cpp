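// Explicit operator-split monodomain stepper with Mitchell-Schaeffer
// kinetics. The diffusion operator arrives as a symmetric sparse stiffness
// matrix (dgCMatrix slots) scaled so that dV/dt_diff = -(K V) / mass is in
// 1/ms units; reaction and diffusion share the same forward-Euler step,
// which is stable at desk-scale mesh resolutions (dt well below the
// Gershgorin bound checked on the R side).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List ms_run_cpp(IntegerVector Kp, IntegerVector Ki, NumericVector Kx,
                NumericVector mass,
                NumericVector V0, NumericVector h0,
                NumericVector tau_in, NumericVector tau_out,
                NumericVector tau_open, NumericVector tau_close,
                double v_gate,
                LogicalVector active,
                double dt, int n_steps, int out_every,
                NumericVector stim_amp, double stim_t0, double stim_dur) {
  const int nv = V0.size();
  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> h(h0.begin(), h0.end());
  std::vector<double> lap(nv);

  const int n_frames = n_steps / out_every + 1;
  NumericMatrix frames(nv, n_frames);
  int frame = 0;
  for (int v = 0; v < nv; ++v) frames(v, 0) = V[v];
  frame = 1;

  const bool has_stim = stim_amp.size() == nv && stim_dur > 0;
  double diverged_at = -1.0;

  for (int step = 1; step <= n_steps; ++step) {
    const double t = step * dt;
    // lap = K V (CSC of a symmetric matrix)
    std::fill(lap.begin(), lap.end(), 0.0);
    for (int j = 0; j < nv; ++j) {
      const double vj = V[j];
      if (vj == 0.0) continue;
      for (int k = Kp[j]; k < Kp[j + 1]; ++k) lap[Ki[k]] += Kx[k] * vj;
    }
    const bool stim_on = has_stim && t >= stim_t0 && t < stim_t0 + stim_dur;
    for (int v = 0; v < nv; ++v) {
      if (!active[v]) { V[v] = 0.0; h[v] = 1.0; continue; }
      const double vv = V[v];
      double dv = -lap[v] / mass[v]
        + h[v] * vv * vv * (1.0 - vv) / tau_in[v]
        - vv / tau_out[v];
      if (stim_on) dv += stim_amp[v];
      V[v] = vv + dt * dv;
      if (vv < v_gate) h[v] += dt * (1.0 - h[v]) / tau_open[v];
      else h[v] -= dt * h[v] / tau_close[v];
    }
    if (step % 200 == 0) {
      for (int v = 0; v < nv; ++v) {
        if (!std::isfinite(V[v]) || std::fabs(V[v]) > 50.0) {
          diverged_at = t;
          break;
        }
      }
      if (diverged_at >= 0) break;
    }
    if (step % out_every == 0 && frame < n_frames) {
      for (int v = 0; v < nv; ++v) frames(v, frame) = V[v];
      ++frame;
    }
  }

  return List::create(
    _["frames"] = frames,
    _["V"] = NumericVector(V.begin(), V.end()),
    _["h"] = NumericVector(h.begin(), h.end()),
    _["diverged_at"] = diverged_at);
}
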