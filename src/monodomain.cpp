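// Explicit monodomain time stepping on a triangulated surface.
//
// The diffusion operator A = -M^{-1} K (lumped mass M, anisotropic P1 FEM
// stiffness K) is assembled in R and passed in compressed sparse column
// form.  The reaction term is a two-variable phenomenological atrial cell
// model (modified Mitchell-Schaeffer) on the normalized potential
// v in [0, 1]:
//
//   dv/dt = (A v) + exc/tau_in * h v^2 (1 - v) - v/tau_out + I_stim
//   dh/dt = (1 - h)/tau_open          if v <  v_gate
//         = -h/(tau_close * apd)      if v >= v_gate
//
// Per-vertex excitability and APD scalings implement ionic remodeling and
// ERP variants.  Inactive (ablated) vertices are clamped at rest.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List monodomain_run(IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                    NumericVector v0, NumericVector h0,
                    LogicalVector active,
                    NumericVector inv_tau_in,    // exc_scale / tau_in
                    double inv_tau_out,
                    double inv_tau_open,
                    NumericVector inv_tau_close, // 1/(tau_close*apd_scale)
                    double v_gate,
                    double dt, int n_steps, int sample_every,
                    NumericMatrix stim_windows,  // k x 3: start, dur, amp
                    List stim_verts) {           // k IntegerVectors, 1-based
  const int n = v0.size();
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> h(h0.begin(), h0.end());
  std::vector<double> dvdiff(n);

  const int n_frames = n_steps / sample_every + 1;
  NumericMatrix vm(n_frames, n);
  for (int i = 0; i < n; ++i) vm(0, i) = v[i];
  int frame = 1;

  const int n_stim = stim_windows.nrow();
  std::vector<std::vector<int>> sverts(n_stim);
  for (int s = 0; s < n_stim; ++s) {
    IntegerVector iv = stim_verts[s];
    sverts[s].assign(iv.begin(), iv.end());
  }

  const int* ap = Ap.begin();
  const int* ai = Ai.begin();
  const double* ax = Ax.begin();
  const int* act = active.begin();
  const double* iti = inv_tau_in.begin();
  const double* itc = inv_tau_close.begin();
  double* vv = v.data();
  double* hh = h.data();
  double* dd = dvdiff.data();

  for (int step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    // diffusion: dvdiff = A v  (CSC traversal)
    std::fill(dvdiff.begin(), dvdiff.end(), 0.0);
    for (int col = 0; col < n; ++col) {
      const double vc = vv[col];
      if (vc == 0.0) continue;
      const int k1 = ap[col + 1];
      for (int k = ap[col]; k < k1; ++k)
        dd[ai[k]] += ax[k] * vc;
    }
    // reaction + update
    for (int i = 0; i < n; ++i) {
      if (!act[i]) { vv[i] = 0.0; continue; }
      const double vi = vv[i];
      const double hi = hh[i];
      const double dv = dd[i] + iti[i] * hi * vi * vi * (1.0 - vi)
        - vi * inv_tau_out;
      const double dh = (vi < v_gate) ? (1.0 - hi) * inv_tau_open
                                      : -hi * itc[i];
      vv[i] = vi + dt * dv;
      double hn = hi + dt * dh;
      if (hn < 0.0) hn = 0.0;
      if (hn > 1.0) hn = 1.0;
      hh[i] = hn;
    }
    // stimuli (applied as an explicit increment after the update)
    for (int s = 0; s < n_stim; ++s) {
      const double s0 = stim_windows(s, 0), sd = stim_windows(s, 1);
      if (t >= s0 && t < s0 + sd) {
        const double amp = stim_windows(s, 2) * dt;
        for (size_t q = 0; q < sverts[s].size(); ++q) {
          const int vi = sverts[s][q] - 1;
          if (act[vi]) {
            vv[vi] += amp;
            if (vv[vi] > 1.0) vv[vi] = 1.0;
          }
        }
      }
    }
    if ((step + 1) % sample_every == 0) {
      for (int i = 0; i < n; ++i) vm(frame, i) = vv[i];
      ++frame;
    }
    if ((step & 255) == 0) {
      for (int i = 0; i < n; ++i) {
        if (!R_finite(vv[i])) {
          return List::create(_["error"] = true,
                              _["time"] = t, _["vertex"] = i + 1);
        }
      }
    }
  }
  return List::create(_["error"] = false,
                      _["vm"] = vm,
                      _["v"] = NumericVector(v.begin(), v.end()),
                      _["h"] = NumericVector(h.begin(), h.end()));
}
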