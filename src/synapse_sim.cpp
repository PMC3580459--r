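// Receptor-competition synapse core: competitive mass-action binding at one
// or more receptor pools driven by a quantal-release / exponential-decay
// free-transmitter time course, with autoreceptor feedback on release and
// spike-history facilitation/depression.  RK4 at a fixed step.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pool {
  std::vector<double> kon, kd, conc, bound;
  int nt_idx;  // index of the neurotransmitter ligand, -1 if none
  double free_frac() const {
    double s = 0.0;
    for (double b : bound) s += b;
    return 1.0 - s;
  }
  // dR_i/dt = kon_i C_i R_f - kon_i Kd_i R_i, R_total = 1
  void deriv(const std::vector<double>& R, double nt,
             std::vector<double>& dR) const {
    double rf = 1.0;
    for (double b : R) rf -= b;
    for (size_t i = 0; i < R.size(); ++i) {
      double C = (static_cast<int>(i) == nt_idx) ? nt : conc[i];
      dR[i] = kon[i] * C * rf - kon[i] * kd[i] * R[i];
    }
  }
  // nt_half / nt_full: free transmitter at the half and full step (the
  // decay law is known in closed form, so the RK4 stages see the exact
  // time-varying concentration)
  void rk4(double nt, double nt_half, double nt_full, double dt) {
    size_t n = bound.size();
    std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n);
    deriv(bound, nt, k1);
    for (size_t i = 0; i < n; ++i) tmp[i] = bound[i] + 0.5 * dt * k1[i];
    deriv(tmp, nt_half, k2);
    for (size_t i = 0; i < n; ++i) tmp[i] = bound[i] + 0.5 * dt * k2[i];
    deriv(tmp, nt_half, k3);
    for (size_t i = 0; i < n; ++i) tmp[i] = bound[i] + dt * k3[i];
    deriv(tmp, nt_full, k4);
    for (size_t i = 0; i < n; ++i) {
      bound[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (bound[i] < 0.0) {
        if (bound[i] < -1e-9)
          stop("integration fault: negative bound amount (dt too large)");
        bound[i] = 0.0;
      }
    }
  }
  void set_equilibrium(double nt) {
    double s = 1.0;
    for (size_t i = 0; i < bound.size(); ++i) {
      double C = (static_cast<int>(i) == nt_idx) ? nt : conc[i];
      s += C / kd[i];
    }
    for (size_t i = 0; i < bound.size(); ++i) {
      double C = (static_cast<int>(i) == nt_idx) ? nt : conc[i];
      bound[i] = (C / kd[i]) / s;
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_simulate_synapse(List pools_in, int presyn_idx,
                          double r0, double rmax, double S, double B0,
                          double lag_ms, double wf, double wd,
                          double kf, double kdep,
                          NumericVector spike_times, double halflife_ms,
                          double duration_ms, double dt, double q_inc,
                          double nt0, bool equilibrate, double eq_conc,
                          double avg_start_ms, double record_every_ms) {
  const int npool = pools_in.size();
  std::vector<Pool> pools(npool);
  for (int p = 0; p < npool; ++p) {
    List pl = pools_in[p];
    NumericVector kon = pl["kon"], kd = pl["kd"], conc = pl["conc"];
    pools[p].kon.assign(kon.begin(), kon.end());
    pools[p].kd.assign(kd.begin(), kd.end());
    pools[p].conc.assign(conc.begin(), conc.end());
    pools[p].bound.assign(kon.size(), 0.0);
    pools[p].nt_idx = as<int>(pl["nt_idx"]);
  }
  if (equilibrate)
    for (auto& p : pools) p.set_equilibrium(eq_conc);

  const long nsteps = static_cast<long>(std::ceil(duration_ms / dt));
  const double decay = std::exp(-std::log(2.0) * dt / halflife_ms);
  const long lag_steps = std::max(1L, static_cast<long>(std::lround(lag_ms / dt)));
  const long rec_every = std::max(1L, static_cast<long>(std::lround(record_every_ms / dt)));
  const long nrec = nsteps / rec_every + 1;

  // ring buffer of presynaptic autoreceptor activation for the release lag
  std::vector<double> abuf(lag_steps, B0);
  long abuf_pos = 0, abuf_filled = 0;

  NumericVector time_out(nrec), free_out(nrec);
  std::vector<NumericMatrix> occ_out;
  for (int p = 0; p < npool; ++p)
    occ_out.push_back(NumericMatrix(nrec, pools[p].bound.size()));
  std::vector<std::vector<double> > act_sum(npool);
  for (int p = 0; p < npool; ++p) act_sum[p].assign(pools[p].bound.size(), 0.0);
  double free_sum = 0.0;
  long n_avg = 0;
  double peak_free = 0.0;

  double nt = nt0;
  // facilitation/depression running sums over past spikes
  double Sf = 0.0, Sd = 0.0;
  double last_spike = R_NegInf;
  int next_spike = 0;
  const int nspk = spike_times.size();
  long rec_i = 0;

  for (long step = 0; step <= nsteps; ++step) {
    double t = step * dt;
    // presynaptic release events due at this step
    while (next_spike < nspk && spike_times[next_spike] <= t + 0.5 * dt) {
      double ts = spike_times[next_spike];
      // oldest entry in the ring buffer is the activation lag_steps ago;
      // before enough history exists the tonic level B0 is used
      double A = B0;
      if (presyn_idx >= 0 && abuf_filled >= lag_steps)
        A = abuf[abuf_pos];
      double AS = std::pow(A, S), B0S = std::pow(B0, S);
      double r = r0 * (1.0 + rmax * (1.0 - 2.0 * AS / (AS + B0S)));
      double fac = 1.0;
      if (std::isfinite(last_spike)) {
        double gap = ts - last_spike;
        Sf = (Sf + 1.0) * std::exp(-kf * gap);
        Sd = (Sd + 1.0) * std::exp(-kdep * gap);
        fac = 1.0 + wf * Sf - wd * Sd;
        if (fac < 0.0) fac = 0.0;
      }
      last_spike = ts;
      nt += r * fac * q_inc;
      ++next_spike;
    }

    // record
    if (step % rec_every == 0 && rec_i < nrec) {
      time_out[rec_i] = t;
      free_out[rec_i] = nt;
      for (int p = 0; p < npool; ++p)
        for (size_t i = 0; i < pools[p].bound.size(); ++i)
          occ_out[p](rec_i, i) = pools[p].bound[i];
      ++rec_i;
    }
    if (nt > peak_free) peak_free = nt;
    if (t >= avg_start_ms) {
      free_sum += nt;
      for (int p = 0; p < npool; ++p)
        for (size_t i = 0; i < pools[p].bound.size(); ++i)
          act_sum[p][i] += pools[p].bound[i];
      ++n_avg;
    }
    if (step == nsteps) break;

    // advance binding and free transmitter
    const double decay_half = std::sqrt(decay);
    for (auto& p : pools) p.rk4(nt, nt * decay_half, nt * decay, dt);
    nt *= decay;

    // push current autoreceptor activation into the lag buffer
    double a_now = B0;
    if (presyn_idx >= 0) {
      const Pool& pp = pools[presyn_idx];
      a_now = (pp.nt_idx >= 0) ? pp.bound[pp.nt_idx] : 0.0;
    }
    abuf[abuf_pos] = a_now;
    abuf_pos = (abuf_pos + 1) % lag_steps;
    if (abuf_filled < lag_steps) ++abuf_filled;
  }

  if (rec_i < nrec) {
    time_out = NumericVector(time_out.begin(), time_out.begin() + rec_i);
    free_out = NumericVector(free_out.begin(), free_out.begin() + rec_i);
    for (int p = 0; p < npool; ++p) {
      NumericMatrix m = occ_out[p];
      NumericMatrix m2(rec_i, m.ncol());
      for (long r = 0; r < rec_i; ++r)
        for (int c = 0; c < m.ncol(); ++c) m2(r, c) = m(r, c);
      occ_out[p] = m2;
    }
  }

  List occ_list(npool), mean_list(npool);
  for (int p = 0; p < npool; ++p) {
    occ_list[p] = occ_out[p];
    NumericVector mv(pools[p].bound.size());
    for (size_t i = 0; i < pools[p].bound.size(); ++i)
      mv[i] = n_avg > 0 ? act_sum[p][i] / n_avg : NA_REAL;
    mean_list[p] = mv;
  }
  return List::create(_["time_ms"] = time_out, _["free_nM"] = free_out,
                      _["occupancy"] = occ_list,
                      _["mean_activation"] = mean_list,
                      _["mean_free_nM"] = n_avg > 0 ? free_sum / n_avg : NA_REAL,
                      _["peak_free_nM"] = peak_free);
}
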