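// Conductance-based cortical network core: four-compartment pyramidal cells
// and two-compartment interneurons with Naf/Nap/Kdr/Ks/KCa/Hva channels,
// dual-exponential AMPA/NMDA/GABA-A synapses with NMDA magnesium block,
// axial coupling, background noise events, a stimulus current and an
// mGluR5-type after-depolarization.  Exponential-Euler updates for gates and
// membrane potential at a fixed step; gating functions are tabulated over a
// voltage grid (linear interpolation) for speed.  Fully deterministic: all
// randomness (noise event times, lesions, connectivity subsets) is drawn on
// the R side and passed in as data.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const double VGRID_MIN = -400.0, VGRID_MAX = 100.0, VGRID_STEP = 0.05;
const int VGRID_N = static_cast<int>((VGRID_MAX - VGRID_MIN) / VGRID_STEP) + 1;

struct GateTab {
  std::vector<double> xinf, fdecay;  // fdecay = exp(-dt/tau)
  GateTab() : xinf(VGRID_N), fdecay(VGRID_N) {}
};

inline double linoid(double V, double c, double th, double k) {
  double x = V - th, d = -1.0 + std::exp(-x / k);
  if (std::fabs(d) < 1e-7) return -c * k;
  return c * x / d;
}
inline double linoid_p(double V, double c, double th, double k) {
  double x = V - th, d = -1.0 + std::exp(x / k);
  if (std::fabs(d) < 1e-7) return c * k;
  return c * x / d;
}

enum {G_NAF_M, G_NAF_H, G_NAP_M, G_NAP_H, G_KDR_M, G_HVA_M, G_HVA_H,
      G_KS_M, G_KS_H, G_KCA_M, G_INAF_M, G_INAF_H, G_IKDR_M, NGATE};

void build_tables(std::vector<GateTab>& tab, double dt) {
  tab.assign(NGATE, GateTab());
  for (int i = 0; i < VGRID_N; ++i) {
    double V = VGRID_MIN + i * VGRID_STEP;
    double a, b, xi, tau;
    // pyramidal fast sodium
    a = linoid(V, -0.2816, -28.0, 9.3); b = linoid_p(V, 0.2464, -1.0, 6.0);
    tab[G_NAF_M].xinf[i] = a / (a + b); tab[G_NAF_M].fdecay[i] = std::exp(-dt * (a + b));
    a = 0.098 * std::exp(-(V + 43.1) / 20.0);
    b = 1.4 / (1.0 + std::exp(-(V + 13.1) / 10.0));
    tab[G_NAF_H].xinf[i] = a / (a + b); tab[G_NAF_H].fdecay[i] = std::exp(-dt * (a + b));
    // persistent sodium
    a = linoid(V, -0.2816, -17.0, 9.3); b = linoid_p(V, 0.2464, 10.0, 6.0);
    tab[G_NAP_M].xinf[i] = a / (a + b); tab[G_NAP_M].fdecay[i] = std::exp(-dt * (a + b));
    a = 2.0e-5 * std::exp(-(V + 42.8477) / 4.0248);
    b = 0.014286 / (1.0 + std::exp(-(V - 413.9284) / 148.2589));
    tab[G_NAP_H].xinf[i] = a / (a + b); tab[G_NAP_H].fdecay[i] = std::exp(-dt * (a + b));
    // delayed rectifier
    a = linoid(V, -0.018, 13.0, 25.0); b = linoid_p(V, 0.0054, 23.0, 12.0);
    tab[G_KDR_M].xinf[i] = a / (a + b); tab[G_KDR_M].fdecay[i] = std::exp(-dt * (a + b));
    // high-voltage-activated calcium
    xi = 1.0 / (1.0 + std::exp(-(V + 24.6) / 11.3));
    tau = 1.25 / std::cosh(0.031 * (V + 37.1));
    tab[G_HVA_M].xinf[i] = xi; tab[G_HVA_M].fdecay[i] = std::exp(-dt / tau);
    xi = 1.0 / (1.0 + std::exp((V + 12.6) / 18.9));
    tab[G_HVA_H].xinf[i] = xi; tab[G_HVA_H].fdecay[i] = std::exp(-dt / 420.0);
    // slowly inactivating potassium
    xi = 1.0 / (1.0 + std::exp(-(V + 34.0) / 6.5));
    tab[G_KS_M].xinf[i] = xi; tab[G_KS_M].fdecay[i] = std::exp(-dt / 6.0);
    xi = 1.0 / (1.0 + std::exp((V + 65.0) / 6.6));
    tau = 200.0 + 3200.0 / (1.0 + std::exp(-(V + 63.6) / 4.0));
    tab[G_KS_H].xinf[i] = xi; tab[G_KS_H].fdecay[i] = std::exp(-dt / tau);
    // calcium-dependent potassium (indexed by the Ca-shifted potential Vs)
    {
      double d = -1.0 + std::exp(-(V + 18.0) / 12.0);
      a = (std::fabs(d) < 1e-7) ? 0.00642 * 12.0 : (-0.00642 * V - 0.1152) / d;
      if (a < 0.0) a = 0.0;
      b = 1.7 * std::exp(-(V + 152.0) / 30.0);
      tau = 1.0 / (a + b); if (tau < 1.1) tau = 1.1;
      tab[G_KCA_M].xinf[i] = a / (a + b); tab[G_KCA_M].fdecay[i] = std::exp(-dt / tau);
    }
    // interneuron sodium / delayed rectifier
    a = 4.2 * std::exp((V + 34.5) / 11.57); b = 4.2 * std::exp(-(V + 34.5) / 27.0);
    tab[G_INAF_M].xinf[i] = a / (a + b); tab[G_INAF_M].fdecay[i] = std::exp(-dt * (a + b));
    a = 0.09 * std::exp(-(V + 45.0) / 33.0); b = 0.09 * std::exp((V + 45.0) / 12.2);
    tab[G_INAF_H].xinf[i] = a / (a + b); tab[G_INAF_H].fdecay[i] = std::exp(-dt * (a + b));
    a = 0.3 * std::exp((V + 35.0) / 10.67); b = 0.3 * std::exp(-(V + 35.0) / 42.68);
    tab[G_IKDR_M].xinf[i] = a / (a + b); tab[G_IKDR_M].fdecay[i] = std::exp(-dt * (a + b));
  }
}

inline void lookup(const GateTab& t, double V, double& xinf, double& f) {
  double pos = (V - VGRID_MIN) / VGRID_STEP;
  if (pos < 0.0) pos = 0.0;
  if (pos > VGRID_N - 1.001) pos = VGRID_N - 1.001;
  int i = static_cast<int>(pos);
  double w = pos - i;
  xinf = t.xinf[i] * (1.0 - w) + t.xinf[i + 1] * w;
  f = t.fdecay[i] * (1.0 - w) + t.fdecay[i + 1] * w;
}

inline void gate_step(const GateTab& t, double V, double& x) {
  double xi, f;
  lookup(t, V, xi, f);
  x = xi + (x - xi) * f;
}

}  // namespace

// [[Rcpp::export]]
List cpp_run_network(List comp, List axial, IntegerVector soma_of_neuron,
                     List syn, List kin, List noise, List stim, List adp,
                     double duration_ms, double dt, double delay_ms,
                     List ca_par, IntegerVector record_v_comps,
                     double record_every_ms) {
  NumericVector area = comp["area"], gnaf = comp["gnaf"], gnap = comp["gnap"],
    ghva = comp["ghva"], gkdr = comp["gkdr"], gks = comp["gks"],
    gkca = comp["gkca"], gl = comp["gl"], el = comp["el"],
    kdr_scale = comp["kdr_scale"];
  IntegerVector ctype = comp["type"], cneuron = comp["neuron"];
  const int ncomp = area.size();
  const int nneuron = soma_of_neuron.size();

  IntegerVector ax_a = axial["a"], ax_b = axial["b"];
  NumericVector ax_g = axial["g_uS"];

  IntegerVector s_pre = syn["pre"], s_comp = syn["comp"], s_kind = syn["kind"];
  NumericVector s_g = syn["g_uS"];
  const int nsyn = s_pre.size();
  // CSR of synapses by presynaptic neuron
  std::vector<int> syn_start(nneuron + 1, 0), syn_order(nsyn);
  for (int i = 0; i < nsyn; ++i) ++syn_start[s_pre[i] + 1];
  for (int n = 0; n < nneuron; ++n) syn_start[n + 1] += syn_start[n];
  {
    std::vector<int> fill(syn_start.begin(), syn_start.end() - 1);
    for (int i = 0; i < nsyn; ++i) syn_order[fill[s_pre[i]]++] = i;
  }

  NumericVector tau_rise = kin["tau_rise"], tau_decay = kin["tau_decay"];
  const double e_exc = as<double>(kin["e_exc"]);
  const double e_gaba_pyr = as<double>(kin["e_gaba_pyr"]);
  const double e_gaba_int = as<double>(kin["e_gaba_int"]);
  const double mg_mM = as<double>(kin["mg_mM"]);
  const double e_na = as<double>(kin["e_na"]), e_k = as<double>(kin["e_k"]),
    e_ca = as<double>(kin["e_ca"]);
  const double v_thresh = as<double>(kin["spike_threshold"]);
  const double refract_ms = as<double>(kin["refractory_ms"]);

  IntegerVector noise_step = noise["step"], noise_comp = noise["comp"];
  const double noise_g = as<double>(noise["g_uS"]);
  NumericVector noise_w = noise["w"];  // per-event relative weight

  IntegerVector stim_comps = stim["comps"];
  const double stim_amp = as<double>(stim["amp_nA"]);
  const double stim_t0 = as<double>(stim["t0_ms"]), stim_dur = as<double>(stim["dur_ms"]);

  IntegerVector adp_comps = adp["comps"];
  const double adp_amp = as<double>(adp["amp_nA"]), adp_tau = as<double>(adp["tau_ms"]);
  const double adp_t0 = as<double>(adp["t0_ms"]);

  const double k_ca = as<double>(ca_par["k_ca"]), tau_ca = as<double>(ca_par["tau_ca"]),
    ca0 = as<double>(ca_par["ca0"]);
  // second, slowly accumulating pool: negligible on the normal span scale,
  // it caps the lifetime of any pathologically persistent burst
  const double k_ca2 = as<double>(ca_par["k_ca2"]), tau_ca2 = as<double>(ca_par["tau_ca2"]);

  std::vector<GateTab> tab;
  build_tables(tab, dt);

  // Mg-block table over the voltage grid
  std::vector<double> mgtab(VGRID_N);
  for (int i = 0; i < VGRID_N; ++i) {
    double V = VGRID_MIN + i * VGRID_STEP;
    mgtab[i] = 1.0 / (1.0 + (mg_mM / 3.57) * std::exp(-0.062 * V));
  }
  auto mg_at = [&](double V) {
    double pos = (V - VGRID_MIN) / VGRID_STEP;
    if (pos < 0.0) pos = 0.0;
    if (pos > VGRID_N - 1.001) pos = VGRID_N - 1.001;
    int i = static_cast<int>(pos);
    double w = pos - i;
    return mgtab[i] * (1.0 - w) + mgtab[i + 1] * w;
  };

  // state
  std::vector<double> V(ncomp), cai(ncomp, ca0), cai2(ncomp, 0.0);
  std::vector<double> gate(ncomp * 10);
  for (int c = 0; c < ncomp; ++c) {
    V[c] = el[c];
    if (ctype[c] == 0) {
      double xi, f;
      const int gt[10] = {G_NAF_M, G_NAF_H, G_NAP_M, G_NAP_H, G_KDR_M,
                          G_HVA_M, G_HVA_H, G_KS_M, G_KS_H, G_KCA_M};
      for (int g = 0; g < 10; ++g) {
        double vv = (gt[g] == G_KCA_M)
          ? V[c] + 40.0 * std::log10(1e4 * std::max(cai[c], 1e-8)) : V[c];
        lookup(tab[gt[g]], vv, xi, f);
        gate[c * 10 + g] = xi;
      }
    } else {
      double xi, f;
      lookup(tab[G_INAF_M], V[c], xi, f); gate[c * 10 + 0] = xi;
      lookup(tab[G_INAF_H], V[c], xi, f); gate[c * 10 + 1] = xi;
      lookup(tab[G_IKDR_M], V[c], xi, f); gate[c * 10 + 2] = xi;
    }
  }

  // synaptic accumulators: per comp per kind, decay (D) and rise (R) parts
  std::vector<double> accD(ncomp * 3, 0.0), accR(ncomp * 3, 0.0);
  double fd[3], fr[3];
  for (int k = 0; k < 3; ++k) {
    fd[k] = std::exp(-dt / tau_decay[k]);
    fr[k] = std::exp(-dt / tau_rise[k]);
  }

  const long nsteps = static_cast<long>(std::lround(duration_ms / dt));
  const int delay_steps = std::max(1, static_cast<int>(std::lround(delay_ms / dt)));
  // delivery ring buffer of synapse indices
  std::vector<std::vector<int> > ring(delay_steps + 1);

  std::vector<double> last_spike(nneuron, -1e9);
  std::vector<double> prev_soma_v(nneuron);
  for (int n = 0; n < nneuron; ++n) prev_soma_v[n] = V[soma_of_neuron[n]];

  std::vector<double> spike_t;
  std::vector<int> spike_n;

  // per-comp injected current flags
  std::vector<double> inj_stim(ncomp, 0.0);  // nA when stimulus active
  for (int i = 0; i < stim_comps.size(); ++i) inj_stim[stim_comps[i]] = stim_amp;
  std::vector<char> has_adp(ncomp, 0);
  for (int i = 0; i < adp_comps.size(); ++i) has_adp[adp_comps[i]] = 1;

  const long rec_every = std::max(1L, static_cast<long>(std::lround(record_every_ms / dt)));
  const int nrecc = record_v_comps.size();
  const long nrec = nrecc > 0 ? nsteps / rec_every + 1 : 0;
  NumericMatrix vout(nrec, nrecc);
  NumericVector vtime(nrec);
  long rec_i = 0;

  int noise_i = 0;
  const int n_noise = noise_step.size();
  std::vector<double> newV(ncomp), gs(ncomp), ges(ncomp), in(ncomp);

  for (long step = 0; step <= nsteps; ++step) {
    const double t = step * dt;

    // deliver queued synaptic events
    std::vector<int>& due = ring[step % (delay_steps + 1)];
    for (size_t e = 0; e < due.size(); ++e) {
      int i = due[e];
      int idx = s_comp[i] * 3 + s_kind[i];
      accD[idx] += s_g[i];
      accR[idx] += s_g[i];
    }
    due.clear();

    // background noise events (AMPA-kind conductance kicks)
    while (noise_i < n_noise && noise_step[noise_i] <= step) {
      int idx = noise_comp[noise_i] * 3 + 0;
      const double g = noise_g * noise_w[noise_i];
      accD[idx] += g;
      accR[idx] += g;
      ++noise_i;
    }

    if (nrecc > 0 && step % rec_every == 0 && rec_i < nrec) {
      vtime[rec_i] = t;
      for (int j = 0; j < nrecc; ++j) vout(rec_i, j) = V[record_v_comps[j]];
      ++rec_i;
    }

    if (step == nsteps) break;

    const bool stim_on = (t >= stim_t0 && t < stim_t0 + stim_dur);
    const double adp_now = (adp_amp != 0.0 && t >= adp_t0)
      ? adp_amp * ((t - adp_t0) / adp_tau) * std::exp(1.0 - (t - adp_t0) / adp_tau)
      : 0.0;

    // membrane + gate update per compartment
    for (int c = 0; c < ncomp; ++c) {
      const double v = V[c];
      double gsum = gl[c], gesum = gl[c] * el[c], inj = 0.0;  // mS/cm^2, mS/cm^2*mV, uA/cm^2
      double* g = &gate[c * 10];

      if (ctype[c] == 0) {
        gate_step(tab[G_NAF_M], v, g[0]);
        gate_step(tab[G_NAF_H], v, g[1]);
        double gna = gnaf[c] * g[0] * g[0] * g[0] * g[1];
        if (gnap[c] > 0.0) {
          gate_step(tab[G_NAP_M], v, g[2]);
          gate_step(tab[G_NAP_H], v, g[3]);
          gna += gnap[c] * g[2] * g[3];
        }
        gate_step(tab[G_KDR_M], v, g[4]);
        double gk = gkdr[c] * kdr_scale[c] * g[4] * g[4] * g[4] * g[4];
        gate_step(tab[G_KS_M], v, g[7]);
        gate_step(tab[G_KS_H], v, g[8]);
        gk += gks[c] * g[7] * g[8];
        double vs = v + 40.0 * std::log10(1e4 * std::max(cai[c] + cai2[c], 1e-8));
        gate_step(tab[G_KCA_M], vs, g[9]);
        gk += gkca[c] * g[9] * g[9];
        gate_step(tab[G_HVA_M], v, g[5]);
        gate_step(tab[G_HVA_H], v, g[6]);
        const double ghva_now = ghva[c] * g[5] * g[5] * g[6] * g[6];
        gsum += gna + gk + ghva_now;
        gesum += gna * e_na + gk * e_k + ghva_now * e_ca;
        // calcium pool driven by the HVA current
        const double i_hva = ghva_now * (v - e_ca);
        cai[c] += dt * (-k_ca * i_hva - (cai[c] - ca0) / tau_ca);
        if (cai[c] < 1e-8) cai[c] = 1e-8;
        if (k_ca2 > 0.0) {
          cai2[c] += dt * (-k_ca2 * i_hva - cai2[c] / tau_ca2);
          if (cai2[c] < 0.0) cai2[c] = 0.0;
        }
      } else {
        gate_step(tab[G_INAF_M], v, g[0]);
        gate_step(tab[G_INAF_H], v, g[1]);
        gate_step(tab[G_IKDR_M], v, g[2]);
        const double gna = gnaf[c] * g[0] * g[0] * g[0] * g[1];
        const double gk = gkdr[c] * kdr_scale[c] * g[2] * g[2] * g[2] * g[2];
        gsum += gna + gk;
        gesum += gna * e_na + gk * e_k;
      }

      // synaptic conductances (uS -> mS/cm^2 via area)
      const double a_cm2 = area[c];
      const double to_density = 1e-3 / a_cm2;
      const double g_ampa = (accD[c * 3 + 0] - accR[c * 3 + 0]) * to_density;
      double g_nmda = (accD[c * 3 + 1] - accR[c * 3 + 1]) * to_density;
      const double g_gaba = (accD[c * 3 + 2] - accR[c * 3 + 2]) * to_density;
      if (g_nmda > 0.0) g_nmda *= mg_at(v);
      const double e_gaba = (ctype[c] == 0) ? e_gaba_pyr : e_gaba_int;
      gsum += g_ampa + g_nmda + g_gaba;
      gesum += (g_ampa + g_nmda) * e_exc + g_gaba * e_gaba;

      // injected currents (nA -> uA/cm^2)
      if (stim_on && inj_stim[c] != 0.0) inj += inj_stim[c] * 1e-3 / a_cm2;
      if (has_adp[c] && adp_now != 0.0) inj += adp_now * 1e-3 / a_cm2;

      gs[c] = gsum; ges[c] = gesum; in[c] = inj;
    }

    // axial coupling as a conductance to the neighbour's current potential
    for (int e = 0; e < ax_a.size(); ++e) {
      const int ia = ax_a[e], ib = ax_b[e];
      const double guS = ax_g[e];
      const double ga = guS * 1e-3 / area[ia], gb = guS * 1e-3 / area[ib];
      gs[ia] += ga; ges[ia] += ga * V[ib];
      gs[ib] += gb; ges[ib] += gb * V[ia];
    }
    for (int c = 0; c < ncomp; ++c) {
      const double gt = gs[c];
      const double vinf = (ges[c] + in[c]) / gt;
      newV[c] = vinf + (V[c] - vinf) * std::exp(-dt * gt);  // Cm = 1 uF/cm^2
      if (newV[c] > 200.0 || newV[c] < -200.0 || !std::isfinite(newV[c]))
        stop("numerical instability at t = %f ms, compartment %d (neuron %d)",
             t, c + 1, cneuron[c] + 1);
    }
    std::swap(V, newV);

    // decay synaptic accumulators
    for (int c = 0; c < ncomp; ++c)
      for (int k = 0; k < 3; ++k) {
        accD[c * 3 + k] *= fd[k];
        accR[c * 3 + k] *= fr[k];
      }

    // spike detection at somata, queue deliveries
    const double t_next = (step + 1) * dt;
    for (int n = 0; n < nneuron; ++n) {
      const double vs = V[soma_of_neuron[n]];
      if (prev_soma_v[n] < v_thresh && vs >= v_thresh &&
          t_next - last_spike[n] >= refract_ms) {
        last_spike[n] = t_next;
        spike_t.push_back(t_next);
        spike_n.push_back(n + 1);
        std::vector<int>& slot = ring[(step + delay_steps) % (delay_steps + 1)];
        for (int s = syn_start[n]; s < syn_start[n + 1]; ++s)
          slot.push_back(syn_order[s]);
      }
      prev_soma_v[n] = vs;
    }
  }

  List vrec = R_NilValue;
  if (nrecc > 0) {
    if (rec_i < nrec) {
      vtime = NumericVector(vtime.begin(), vtime.begin() + rec_i);
      NumericMatrix v2(rec_i, nrecc);
      for (long r = 0; r < rec_i; ++r)
        for (int j = 0; j < nrecc; ++j) v2(r, j) = vout(r, j);
      vout = v2;
    }
    vrec = List::create(_["time_ms"] = vtime, _["v"] = vout);
  }
  return List::create(_["spike_time_ms"] = wrap(spike_t),
                      _["spike_neuron"] = wrap(spike_n),
                      _["voltage"] = vrec);
}
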