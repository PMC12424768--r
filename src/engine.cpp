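// Fixed-step conductance-based network integrator.
//
// Units: mV, ms, nS, pF  (so nS * mV = pA and pA / pF = mV/ms).
// Voltage uses a forward-Euler update; gating variables use exponential
// Euler, x <- xinf + (x - xinf) * exp(-dt / tau), which is exact for the
// linearized gating ODE and unconditionally stable.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Gating kinetics
// ---------------------------------------------------------------------------

// Guard against the 0/0 singularity of (V + s)/(1 - exp(-(V + s)/k)) forms.
static inline double vtrap(double x, double k) {
  // returns x / (1 - exp(-x / k)); limit k as x -> 0
  if (std::fabs(x / k) < 1e-6) return k * (1.0 + x / (2.0 * k));
  return x / (1.0 - std::exp(-x / k));
}

// Fast-spiking interneuron: Wang-Buzsaki formalism.
// m is instantaneous; h and n are states with temperature factor phi.
struct FSRates {
  static inline double minf(double V) {
    double am = 0.1 * vtrap(V + 35.0, 10.0);
    double bm = 4.0 * std::exp(-(V + 60.0) / 18.0);
    return am / (am + bm);
  }
  static inline void h_rate(double V, double phi, double &inf, double &tau) {
    double a = 0.07 * std::exp(-(V + 58.0) / 20.0);
    double b = 1.0 / (1.0 + std::exp(-(V + 28.0) / 10.0));
    inf = a / (a + b);
    tau = 1.0 / (phi * (a + b));
  }
  static inline void n_rate(double V, double phi, double &inf, double &tau) {
    double a = 0.01 * vtrap(V + 34.0, 10.0);
    double b = 0.125 * std::exp(-(V + 44.0) / 80.0);
    inf = a / (a + b);
    tau = 1.0 / (phi * (a + b));
  }
};

// Stellate cell: HH-type spiking currents plus persistent Na and a
// two-component (fast/slow) hyperpolarization-activated H conductance that
// confers theta-band subthreshold resonance.
struct STRates {
  static inline void m_rate(double V, double &inf, double &tau) {
    double a = 0.1 * vtrap(V + 23.0, 10.0);
    double b = 4.0 * std::exp(-(V + 48.0) / 18.0);
    inf = a / (a + b);
    tau = 1.0 / (a + b);
  }
  static inline void h_rate(double V, double &inf, double &tau) {
    double a = 0.07 * std::exp(-(V + 37.0) / 20.0);
    double b = 1.0 / (1.0 + std::exp(-(V + 7.0) / 10.0));
    inf = a / (a + b);
    tau = 1.0 / (a + b);
  }
  static inline void n_rate(double V, double &inf, double &tau) {
    double a = 0.01 * vtrap(V + 27.0, 10.0);
    double b = 0.125 * std::exp(-(V + 37.0) / 80.0);
    inf = a / (a + b);
    tau = 1.0 / (a + b);
  }
  static inline double pinf(double V) {
    return 1.0 / (1.0 + std::exp(-(V + 38.0) / 6.5));
  }
  static inline void hf_rate(double V, double &inf, double &tau) {
    inf = 1.0 / (1.0 + std::exp((V + 79.2) / 9.78));
    tau = 0.51 / (std::exp((V - 1.7) / 10.0) + std::exp(-(V + 340.0) / 52.0)) + 1.0;
  }
  static inline void hs_rate(double V, double &inf, double &tau) {
    inf = 1.0 / (1.0 + std::exp((V + 71.3) / 7.9));
    tau = 5.6 / (std::exp((V - 1.7) / 14.0) + std::exp(-(V + 260.0) / 43.0)) + 1.0;
  }
};

// Parameter column layout (shared by both cell types; unused entries 0):
// 0 C, 1 gNa, 2 gK, 3 gL, 4 ENa, 5 EK, 6 EL, 7 phi, 8 gNaP, 9 gHf, 10 gHs,
// 11 EH
enum ParCol { C_M = 0, G_NA, G_K, G_L, E_NA, E_K, E_L, PHI, G_NAP, G_HF,
              G_HS, E_H, N_PAR };

// Ionic current (pA, outward positive) and in-place gating update for one
// cell over one step of size dt at voltage V.
static inline double ionic_current_fs(const double *p, double V,
                                      double *g, double dt) {
  double m = FSRates::minf(V);
  double hinf, htau, ninf, ntau;
  FSRates::h_rate(V, p[PHI], hinf, htau);
  FSRates::n_rate(V, p[PHI], ninf, ntau);
  double I = p[G_NA] * m * m * m * g[0] * (V - p[E_NA]) +
             p[G_K] * g[1] * g[1] * g[1] * g[1] * (V - p[E_K]) +
             p[G_L] * (V - p[E_L]);
  g[0] = hinf + (g[0] - hinf) * std::exp(-dt / htau);
  g[1] = ninf + (g[1] - ninf) * std::exp(-dt / ntau);
  return I;
}

static inline double ionic_current_st(const double *p, double V,
                                      double *g, double dt) {
  double minf, mtau, hinf, htau, ninf, ntau, hfinf, hftau, hsinf, hstau;
  STRates::m_rate(V, minf, mtau);
  STRates::h_rate(V, hinf, htau);
  STRates::n_rate(V, ninf, ntau);
  STRates::hf_rate(V, hfinf, hftau);
  STRates::hs_rate(V, hsinf, hstau);
  double m = g[2], h = g[0], n = g[1], hf = g[3], hs = g[4];
  double I = p[G_NA] * m * m * m * h * (V - p[E_NA]) +
             p[G_K] * n * n * n * n * (V - p[E_K]) +
             p[G_NAP] * STRates::pinf(V) * (V - p[E_NA]) +
             (p[G_HF] * hf + p[G_HS] * hs) * (V - p[E_H]) +
             p[G_L] * (V - p[E_L]);
  g[2] = minf + (m - minf) * std::exp(-dt / mtau);
  g[0] = hinf + (h - hinf) * std::exp(-dt / htau);
  g[1] = ninf + (n - ninf) * std::exp(-dt / ntau);
  g[3] = hfinf + (hf - hfinf) * std::exp(-dt / hftau);
  g[4] = hsinf + (hs - hsinf) * std::exp(-dt / hstau);
  return I;
}

static void init_gates_fs(const double *p, double V, double *g) {
  double inf, tau;
  FSRates::h_rate(V, p[PHI], inf, tau); g[0] = inf;
  FSRates::n_rate(V, p[PHI], inf, tau); g[1] = inf;
  g[2] = g[3] = g[4] = 0.0;
}

static void init_gates_st(const double *p, double V, double *g) {
  double inf, tau;
  STRates::h_rate(V, inf, tau);  g[0] = inf;
  STRates::n_rate(V, inf, tau);  g[1] = inf;
  STRates::m_rate(V, inf, tau);  g[2] = inf;
  STRates::hf_rate(V, inf, tau); g[3] = inf;
  STRates::hs_rate(V, inf, tau); g[4] = inf;
}

// ---------------------------------------------------------------------------
// Single-cell simulation (used for f-I curves, impedance probes, oracles)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List simulate_cell_cpp(int cell_type, NumericVector params, double v0,
                       double dt, int n_steps, NumericVector i_inj,
                       NumericVector g_drive, double e_drive,
                       double spike_threshold, double refractory_ms) {
  if (params.size() < N_PAR) stop("parameter vector too short");
  const double *p = REAL(params);
  double V = v0;
  double g[5];
  if (cell_type == 0) init_gates_fs(p, V, g); else init_gates_st(p, V, g);

  bool has_inj = i_inj.size() > 0;
  bool has_drv = g_drive.size() > 0;
  if (has_inj && i_inj.size() < n_steps + 1) stop("i_inj too short");
  if (has_drv && g_drive.size() < n_steps + 1) stop("g_drive too short");

  NumericVector vtrace(n_steps + 1);
  std::vector<double> spikes;
  vtrace[0] = V;
  double last_spike = -1e9;
  double v_prev = V;
  int refr_steps = (int)std::round(refractory_ms / dt);

  for (int s = 0; s < n_steps; ++s) {
    double I_ion = (cell_type == 0) ? ionic_current_fs(p, V, g, dt)
                                    : ionic_current_st(p, V, g, dt);
    double I_ext = has_inj ? i_inj[s] : 0.0;
    double I_syn = has_drv ? g_drive[s] * (V - e_drive) : 0.0;
    double Vn = V + dt * (-I_ion - I_syn + I_ext) / p[C_M];
    if (!std::isfinite(Vn) || std::fabs(Vn) > 200.0)
      stop("numerical blow-up: |V| > 200 mV at t = %f ms", s * dt);
    double t = (s + 1) * dt;
    if (v_prev < spike_threshold && Vn >= spike_threshold &&
        t - last_spike >= refr_steps * dt) {
      spikes.push_back(t);
      last_spike = t;
    }
    v_prev = Vn;
    V = Vn;
    vtrace[s + 1] = V;
  }
  return List::create(_["v"] = vtrace, _["spikes"] = wrap(spikes));
}

// ---------------------------------------------------------------------------
// Network simulation
// ---------------------------------------------------------------------------
//
// Synaptic conductances are aggregated per postsynaptic cell into two
// channels:
//   AMPA: single-exponential, state y;        g = y
//   GABA: bi-exponential, states x (rise), y; g = norm * (y - x)
// A presynaptic spike adds the edge weight (times the bi-exponential peak
// normalizer for GABA) to the states at the next time step, so each event
// contributes a conductance waveform whose peak equals the edge weight.

// [[Rcpp::export]]
List run_network_cpp(IntegerVector cell_type,        // 0 FS, 1 stellate
                     NumericMatrix params,           // n_cells x N_PAR
                     LogicalVector is_clamped,       // readouts
                     double v_hold,
                     IntegerVector edge_pre,         // 0-based
                     IntegerVector edge_post,
                     NumericVector edge_weight,      // nS (peak)
                     IntegerVector edge_channel,     // 0 AMPA, 1 GABA
                     NumericVector edge_delay,       // ms
                     NumericVector ampa_tau_d,       // per cell, ms
                     NumericVector gaba_tau_r,
                     NumericVector gaba_tau_d,
                     NumericVector gaba_e_rev,       // per cell, mV
                     double ampa_e_rev,
                     NumericVector drive_g_peak,     // per cell, nS
                     double f_theta,                 // Hz
                     double drive_e_rev,
                     NumericMatrix noise,            // (n_steps+1) x n_noise
                     IntegerVector noise_col,        // per cell, 0-based; -1 none
                     double dt, int n_steps,
                     int record_every,
                     IntegerVector record_v_cells,   // 0-based ids, may be empty
                     NumericVector v_init,
                     double spike_threshold,
                     double refractory_ms) {
  const int n_cells = cell_type.size();
  const int n_edges = edge_pre.size();
  if (params.nrow() != n_cells || params.ncol() < N_PAR)
    stop("bad params matrix");
  if (noise.ncol() > 0 && noise.nrow() < n_steps + 1)
    stop("noise matrix too short");

  // CSR adjacency by presynaptic cell
  std::vector<int> deg(n_cells, 0);
  for (int e = 0; e < n_edges; ++e) deg[edge_pre[e]]++;
  std::vector<int> ptr(n_cells + 1, 0);
  for (int i = 0; i < n_cells; ++i) ptr[i + 1] = ptr[i] + deg[i];
  std::vector<int> adj_post(n_edges), adj_ch(n_edges), adj_dl(n_edges);
  std::vector<double> adj_w(n_edges);
  int max_delay = 0;
  {
    std::vector<int> fill(ptr.begin(), ptr.end() - 1);
    for (int e = 0; e < n_edges; ++e) {
      int k = fill[edge_pre[e]]++;
      adj_post[k] = edge_post[e];
      adj_ch[k] = edge_channel[e];
      adj_w[k] = edge_weight[e];
      int d = (edge_delay.size() > 0)
                  ? (int)std::round(edge_delay[e] / dt) : 0;
      if (d < 0) d = 0;
      adj_dl[k] = d;
      if (d > max_delay) max_delay = d;
    }
  }
  // ring buffer of future synaptic increments (per delay slot, per cell,
  // per channel); slot 0 of the ring is delivered at the end of the
  // current step
  const int ring_len = max_delay + 1;
  std::vector<double> ring(3LL * ring_len * n_cells, 0.0);
  int ring_cur = 0;
  // layout: ring[(slot * 3 + ch) * n_cells + cell], ch: 0 ampa, 1 gaba_x,
  // 2 gaba_y

  // per-cell synaptic state and precomputed decay factors
  std::vector<double> sy_ampa(n_cells, 0.0);
  std::vector<double> sx_gaba(n_cells, 0.0), sy_gaba(n_cells, 0.0);
  std::vector<double> dec_ampa(n_cells), dec_gx(n_cells), dec_gy(n_cells),
      gaba_norm(n_cells);
  for (int i = 0; i < n_cells; ++i) {
    dec_ampa[i] = std::exp(-dt / ampa_tau_d[i]);
    dec_gx[i] = std::exp(-dt / gaba_tau_r[i]);
    dec_gy[i] = std::exp(-dt / gaba_tau_d[i]);
    double tr = gaba_tau_r[i], td = gaba_tau_d[i];
    double tp = tr * td / (td - tr) * std::log(td / tr);
    gaba_norm[i] = 1.0 / (std::exp(-tp / td) - std::exp(-tp / tr));
  }

  // membrane state
  std::vector<double> V(n_cells), v_prev(n_cells);
  std::vector<double> gates(5 * n_cells, 0.0);
  for (int i = 0; i < n_cells; ++i) {
    V[i] = (v_init.size() == n_cells) ? v_init[i] : params(i, E_L);
    if (is_clamped[i]) V[i] = v_hold;
    v_prev[i] = V[i];
    double prow[N_PAR];
    for (int c = 0; c < N_PAR; ++c) prow[c] = params(i, c);
    if (cell_type[i] == 0) init_gates_fs(prow, V[i], &gates[5 * i]);
    else init_gates_st(prow, V[i], &gates[5 * i]);
  }
  std::vector<double> last_spike(n_cells, -1e9);

  // recording
  int n_rec = n_steps / record_every + 1;
  int n_clamp = 0;
  std::vector<int> clamp_ids;
  for (int i = 0; i < n_cells; ++i)
    if (is_clamped[i]) { clamp_ids.push_back(i); ++n_clamp; }
  NumericMatrix clamp_rec(n_rec, n_clamp);
  NumericMatrix v_rec(record_v_cells.size() > 0 ? n_rec : 0,
                      record_v_cells.size());
  NumericVector rec_time(n_rec);

  std::vector<int> spike_cell;
  std::vector<double> spike_time;
  std::vector<int> pending;  // cells that spiked this step

  const double two_pi_f = 2.0 * M_PI * f_theta / 1000.0;  // per ms

  // helper to record at step index s (state corresponds to time s*dt)
  auto record_state = [&](int s) {
    if (s % record_every != 0) return;
    int r = s / record_every;
    double t = s * dt;
    rec_time[r] = t;
    for (int k = 0; k < n_clamp; ++k) {
      int i = clamp_ids[k];
      double g_gaba = gaba_norm[i] * (sy_gaba[i] - sx_gaba[i]);
      double g_ampa = sy_ampa[i];
      double gd = drive_g_peak[i] * 0.5 * (1.0 - std::cos(two_pi_f * t));
      if (noise_col[i] >= 0) gd += noise(s, noise_col[i]);
      if (gd < 0) gd = 0;
      double I = g_gaba * (v_hold - gaba_e_rev[i]) +
                 g_ampa * (v_hold - ampa_e_rev) +
                 gd * (v_hold - drive_e_rev);
      clamp_rec(r, k) = I;
    }
    for (int k = 0; k < record_v_cells.size(); ++k)
      v_rec(r, k) = V[record_v_cells[k]];
  };

  record_state(0);

  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt;
    double theta_shape = 0.5 * (1.0 - std::cos(two_pi_f * t));

    pending.clear();
    for (int i = 0; i < n_cells; ++i) {
      if (is_clamped[i]) continue;
      double g_gaba = gaba_norm[i] * (sy_gaba[i] - sx_gaba[i]);
      double g_ampa = sy_ampa[i];
      double gd = drive_g_peak[i] * theta_shape;
      if (noise_col[i] >= 0) gd += noise(s, noise_col[i]);
      if (gd < 0) gd = 0;

      const double *p = &params(0, 0);
      // params is column-major; gather row i
      double prow[N_PAR];
      for (int c = 0; c < N_PAR; ++c) prow[c] = p[c * n_cells + i];

      double I_ion = (cell_type[i] == 0)
                         ? ionic_current_fs(prow, V[i], &gates[5 * i], dt)
                         : ionic_current_st(prow, V[i], &gates[5 * i], dt);
      double I_syn = g_gaba * (V[i] - gaba_e_rev[i]) +
                     g_ampa * (V[i] - ampa_e_rev) +
                     gd * (V[i] - drive_e_rev);
      double Vn = V[i] + dt * (-I_ion - I_syn) / prow[C_M];
      if (!std::isfinite(Vn) || std::fabs(Vn) > 200.0)
        stop("numerical blow-up in cell %d at t = %f ms", i + 1, t);
      double tn = t + dt;
      if (v_prev[i] < spike_threshold && Vn >= spike_threshold &&
          tn - last_spike[i] >= refractory_ms) {
        spike_cell.push_back(i);
        spike_time.push_back(tn);
        last_spike[i] = tn;
        pending.push_back(i);
      }
      v_prev[i] = Vn;
      V[i] = Vn;
    }

    // decay synaptic states to time (s+1)*dt
    for (int i = 0; i < n_cells; ++i) {
      sy_ampa[i] *= dec_ampa[i];
      sx_gaba[i] *= dec_gx[i];
      sy_gaba[i] *= dec_gy[i];
    }
    // schedule this step's spikes into the delay ring
    for (size_t q = 0; q < pending.size(); ++q) {
      int pre = pending[q];
      for (int k = ptr[pre]; k < ptr[pre + 1]; ++k) {
        int slot = (ring_cur + adj_dl[k]) % ring_len;
        double *base = &ring[(size_t)slot * 3 * n_cells];
        int post = adj_post[k];
        double w = adj_w[k];
        if (adj_ch[k] == 0) {
          base[post] += w;
        } else {
          base[n_cells + post] += w;
          base[2 * n_cells + post] += w;
        }
      }
    }
    // deliver the increments due now (take effect from next step)
    {
      double *base = &ring[(size_t)ring_cur * 3 * n_cells];
      for (int i = 0; i < n_cells; ++i) {
        sy_ampa[i] += base[i];
        sx_gaba[i] += base[n_cells + i];
        sy_gaba[i] += base[2 * n_cells + i];
        base[i] = base[n_cells + i] = base[2 * n_cells + i] = 0.0;
      }
      ring_cur = (ring_cur + 1) % ring_len;
    }
    record_state(s + 1);
  }

  return List::create(
      _["spike_cell"] = wrap(spike_cell), _["spike_time"] = wrap(spike_time),
      _["time"] = rec_time, _["clamp"] = clamp_rec,
      _["clamp_cells"] = wrap(clamp_ids), _["v"] = v_rec);
}
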