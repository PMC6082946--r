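#include <Rcpp.h>
using namespace Rcpp;

// Astrocyte constant vector layout (see astro_pars_vec() on the R side):
// 0 tau_c, 1 er_flux_gain, 2 c_influx, 3 sm_influx, 4 tau_ce,
// 5 ex_amp, 6 ex_half, 7 leak, 8 tau_sm, 9 drive_gain,
// 10 drive_threshold, 11 tau_gm, 12 gm_half

static inline double exchange_flux(double c, double ce,
                                   const NumericVector& ap) {
  double c2 = c * c, ce2 = ce * ce, c4 = c2 * c2;
  return ap[5] * c2 / (1.0 + c2) -
         (ce2 / (1.0 + ce2)) * (c4 / (ap[6] + c4)) -
         ap[7] * ce;
}

static inline void astro_step(double* st, double drive, double dt_s,
                              const NumericVector& ap) {
  double c = st[0], ce = st[1], sm = st[2], gm = st[3];
  double f = exchange_flux(c, ce, ap);
  double dc = (-c - ap[1] * f + ap[2] + ap[3] * sm) / ap[0];
  double dce = f / ap[4];
  double dsm = (drive * (1.0 - sm) - sm / 3.0) / ap[8];
  double dgm = ((1.0 + std::tanh(10.0 * (c - ap[12]))) * (1.0 - gm) -
                gm / 3.0) / ap[11];
  st[0] = c + dt_s * dc;
  st[1] = ce + dt_s * dce;
  st[2] = std::min(1.0, std::max(0.0, sm + dt_s * dsm));
  st[3] = std::min(1.0, std::max(0.0, gm + dt_s * dgm));
}

// Integrate the astrocyte alone under a prescribed drive activation.
// [[Rcpp::export]]
DataFrame astro_trace_cpp(NumericVector init, NumericVector drive,
                          double dt_s, NumericVector ap, double t0 = 0.0) {
  int n = drive.size();
  NumericVector tc(n), cc(n), cec(n), smc(n), gmc(n);
  double st[4] = {init[0], init[1], init[2], init[3]};
  for (int t = 0; t < n; ++t) {
    astro_step(st, drive[t], dt_s, ap);
    if (!R_finite(st[0]) || !R_finite(st[1]))
      stop("non-finite astrocyte state at step %d", t + 1);
    tc[t] = t0 + (t + 1) * dt_s;
    cc[t] = st[0]; cec[t] = st[1]; smc[t] = st[2]; gmc[t] = st[3];
  }
  return DataFrame::create(_["time_s"] = tc, _["c"] = cc, _["ce"] = cec,
                           _["sm"] = smc, _["gm"] = gmc);
}

// One protocol segment of the coupled network-astrocyte loop.
//
// Per outer step (dt_ms): synaptic current from the previous step's
// spikes, noisy external drive, uniform gliotransmitter current; two
// half-step Euler updates of v, one full step of u; threshold detection
// at 30 mV and reset; then one astrocyte Euler step (dt_s seconds)
// driven by the rectified astro-drive draw.
//
// noise: n x nsteps standard-normal matrix (row i = neuron i).
// astro_noise: length-nsteps standard-normal astro-drive stream.
// astro_state: (c, ce, sm, gm), modified through the segment.
// glio_gain = k_glio * glio_release_scale (applied to delta * Gm).
// astro_exc_only: restrict I_astro to excitatory targets.
// noise_shared: all excitatory neurons share row 0's draw, all
// inhibitory neurons share row n_exc's draw.
// [[Rcpp::export]]
List sim_segment_cpp(NumericVector v_in, NumericVector u_in,
                     NumericVector a, NumericVector b,
                     NumericVector c_reset, NumericVector d_jump,
                     NumericMatrix S, NumericMatrix noise,
                     NumericVector astro_noise,
                     LogicalVector fired_in, NumericVector astro_in,
                     int n_exc, double k_exc, double k_inh, double delta,
                     double glio_gain, double dt_ms, double dt_s,
                     int t_offset_ms, NumericVector ap,
                     bool astro_exc_only, bool noise_shared,
                     bool record_astro) {
  int n = v_in.size();
  int nsteps = noise.ncol();
  NumericVector v = clone(v_in), u = clone(u_in);
  LogicalVector fired = clone(fired_in);
  double ast[4] = {astro_in[0], astro_in[1], astro_in[2], astro_in[3]};

  std::vector<int> sp_t, sp_id;
  sp_t.reserve(nsteps * 16);
  sp_id.reserve(nsteps * 16);
  IntegerVector psc(nsteps);
  NumericMatrix atrace(record_astro ? nsteps : 0, 5);
  std::vector<double> Isyn(n);

  for (int t = 0; t < nsteps; ++t) {
    std::fill(Isyn.begin(), Isyn.end(), 0.0);
    for (int j = 0; j < n; ++j) {
      if (fired[j]) {
        const double* col = &S(0, j);
        for (int i = 0; i < n; ++i) Isyn[i] += col[i];
      }
    }
    double i_astro = glio_gain * delta * ast[3];
    if (record_astro) {
      atrace(t, 0) = ast[0]; atrace(t, 1) = ast[1];
      atrace(t, 2) = ast[2]; atrace(t, 3) = ast[3];
      atrace(t, 4) = i_astro;
    }
    double f_exc_shared = noise(0, t);
    double f_inh_shared = (n_exc < n) ? noise(n_exc, t) : 0.0;
    int nfired = 0;
    for (int i = 0; i < n; ++i) {
      bool exc = i < n_exc;
      double f = noise_shared ? (exc ? f_exc_shared : f_inh_shared)
                              : noise(i, t);
      double I = Isyn[i] + delta * (exc ? k_exc : k_inh) * f;
      if (!astro_exc_only || exc) I += i_astro;
      double vi = v[i], ui = u[i];
      vi += 0.5 * dt_ms * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + I);
      vi += 0.5 * dt_ms * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + I);
      ui += dt_ms * a[i] * (b[i] * vi - ui);
      if (!R_finite(vi) || !R_finite(ui))
        stop("non-finite membrane state for neuron %d at t = %d ms",
             i + 1, t_offset_ms + t);
      if (vi >= 30.0) {
        sp_t.push_back(t_offset_ms + t);
        sp_id.push_back(i);
        ++nfired;
        fired[i] = true;
        vi = c_reset[i];
        ui += d_jump[i];
      } else {
        fired[i] = false;
      }
      v[i] = vi;
      u[i] = ui;
    }
    psc[t] = nfired;
    double drive = 1.0 + std::tanh(ap[9] * (k_exc * std::fabs(astro_noise[t]) -
                                            ap[10]));
    astro_step(ast, drive, dt_s, ap);
    if (!R_finite(ast[0]) || !R_finite(ast[1]))
      stop("non-finite astrocyte state at t = %d ms", t_offset_ms + t);
  }

  return List::create(
      _["spike_time_ms"] = wrap(sp_t), _["spike_id"] = wrap(sp_id),
      _["psc"] = psc, _["astro_trace"] = atrace, _["v"] = v, _["u"] = u,
      _["fired"] = fired,
      _["astro_state"] = NumericVector::create(ast[0], ast[1], ast[2],
                                               ast[3]));
}
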