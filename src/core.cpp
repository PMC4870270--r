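// Simulation cores. All randomness comes from R's RNG so that runs are
// reproducible under set.seed() from the R side.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline double heav(double x) { return x >= 0.0 ? 1.0 : 0.0; }
static inline double pospart(double x) { return x > 0.0 ? x : 0.0; }
static inline double fcubic(double x) { return -x * (x - 1.0) * (x + 1.0); }

// logistic activity-dependent unbinding rate, k0 + m / (1 + exp((I0-I)/r))
static inline double unbind_rate(double IA, double k0, double m, double I0,
                                 double r) {
  return k0 + m / (1.0 + std::exp((I0 - IA) / r));
}

struct PoolPar {
  double k1, k3, k0, m, r, I02, I04;
  double N_A_tot;
};

static PoolPar read_pool(const List& p) {
  PoolPar q;
  q.k1 = as<double>(p["k1"]);  q.k3 = as<double>(p["k3"]);
  q.k0 = as<double>(p["k0"]);  q.m = as<double>(p["m"]);
  q.r = as<double>(p["r"]);    q.I02 = as<double>(p["I0_2"]);
  q.I04 = as<double>(p["I0_4"]); q.N_A_tot = as<double>(p["N_A_tot"]);
  return q;
}

// Fisher-Yates permutation using R's RNG
static void rand_perm(std::vector<int>& idx) {
  const int n = (int)idx.size();
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
}

// ---------------------------------------------------------------------------
// Full extended write-protected model: LIF neuron at dt_fine, triplet traces
// event-driven, synapse/pool layer every steps_per_slow fine steps.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_run_full(List spike_trains, double duration, double dt_fine,
                  int steps_per_slow, List neuron_par, List triplet_par,
                  List wp_par, List pool_par, NumericVector psi_window,
                  NumericVector dopamine_window, IntegerVector init_big,
                  bool gated_noise, IntegerVector force_unbound,
                  double record_dt, int record_synapse = -1,
                  double snapshot_t = -1.0) {
  const int n_syn = spike_trains.size();
  if ((int)init_big.size() != n_syn || (int)force_unbound.size() != n_syn)
    stop("init_big/force_unbound length must match number of synapses");

  // neuron parameters
  const double tau_m = as<double>(neuron_par["tau_m"]);
  const double V_rest = as<double>(neuron_par["V_rest"]);
  const double V_exc = as<double>(neuron_par["V_exc"]);
  const double V_adapt = as<double>(neuron_par["V_adapt"]);
  const double tau_thr = as<double>(neuron_par["tau_thr"]);
  const double th_rest = as<double>(neuron_par["theta_rest"]);
  const double th_spike = as<double>(neuron_par["theta_spike"]);
  const double tau_ampa = as<double>(neuron_par["tau_ampa"]);
  const double tau_nmda = as<double>(neuron_par["tau_nmda"]);
  const double beta_f = as<double>(neuron_par["beta_ampa_frac"]);
  const double tau_adapt = as<double>(neuron_par["tau_adapt"]);
  const double g_spike = as<double>(neuron_par["g_spike"]);

  // triplet parameters
  const double A_plus = as<double>(triplet_par["A_plus"]);
  const double A_minus = as<double>(triplet_par["A_minus"]);
  const double tau_x = as<double>(triplet_par["tau_x"]);
  const double tau_y = as<double>(triplet_par["tau_y"]);
  const double tau_tr = as<double>(triplet_par["tau_triplet"]);
  const double tau_A = as<double>(triplet_par["tau_A"]);

  // write-protected parameters
  const double tau_w = as<double>(wp_par["tau_w"]);
  const double tau_T = as<double>(wp_par["tau_T"]);
  const double tau_z = as<double>(wp_par["tau_z"]);
  const double a_wT = as<double>(wp_par["a_wT"]);
  const double a_Tz = as<double>(wp_par["a_Tz"]);
  const double a_Tw = as<double>(wp_par["a_Tw"]);
  const double a_zT = as<double>(wp_par["a_zT"]);
  const double a_b = as<double>(wp_par["a_b"]);
  const double sigma = as<double>(wp_par["sigma"]);
  const double tau_g = as<double>(wp_par["tau_gamma"]);
  const double th_g = as<double>(wp_par["theta_gamma"]);
  const double kappa = as<double>(wp_par["kappa"]);
  const double k_up = as<double>(wp_par["k_up"]);
  const double k_down = as<double>(wp_par["k_down"]);
  const double th_act = as<double>(wp_par["theta_act"]);
  const double w_minus = as<double>(wp_par["w_minus"]);
  const double k_w = as<double>(wp_par["k_w"]);
  const double g0 = as<double>(wp_par["g0"]);

  const PoolPar pp = read_pool(pool_par);

  const double dt_slow = dt_fine * steps_per_slow;
  const long n_steps = (long)std::llround(duration / dt_fine);
  const double sq_dt = std::sqrt(dt_slow);
  const double dIA = std::exp(-dt_slow / tau_A);

  // presynaptic events -> (step, synapse), sorted by step
  std::vector<long> ev_step;
  std::vector<int> ev_syn;
  {
    long total = 0;
    for (int j = 0; j < n_syn; ++j)
      total += ((NumericVector)spike_trains[j]).size();
    ev_step.reserve(total); ev_syn.reserve(total);
    std::vector<std::pair<long, int> > ev; ev.reserve(total);
    for (int j = 0; j < n_syn; ++j) {
      NumericVector tj = spike_trains[j];
      for (int k = 0; k < tj.size(); ++k) {
        long s = (long)std::llround(tj[k] / dt_fine);
        if (s >= 0 && s < n_steps) ev.push_back(std::make_pair(s, j));
      }
    }
    std::sort(ev.begin(), ev.end());
    for (size_t k = 0; k < ev.size(); ++k) {
      ev_step.push_back(ev[k].first); ev_syn.push_back(ev[k].second);
    }
  }

  // state
  std::vector<double> w(n_syn), Tt(n_syn), z(n_syn), gam(n_syn, 0.0),
      IA(n_syn, 0.0), xval(n_syn, 0.0), accP(n_syn, 0.0), accM(n_syn, 0.0),
      dg(n_syn);
  std::vector<long> xlast(n_syn, 0);
  std::vector<int> b(n_syn);
  for (int j = 0; j < n_syn; ++j) {
    const bool big = init_big[j] != 0;
    w[j] = Tt[j] = z[j] = big ? 1.0 : -1.0;
    b[j] = (big && !force_unbound[j]) ? 1 : 0;
  }
  double p_gate = 0.0;
  long n_bound = 0;
  for (int j = 0; j < n_syn; ++j) n_bound += b[j];
  double N_A = pp.N_A_tot - n_bound, N_As = 0.0;
  bool psi_prev = false;
  const bool has_psi = psi_window.size() == 2;
  const bool has_dop = dopamine_window.size() == 2;

  for (int j = 0; j < n_syn; ++j)
    dg[j] = g0 * (w_minus + (w[j] + 1.0) * (k_w * w_minus - w_minus) / 2.0);

  // neuron state
  double V = V_rest, th = th_rest, g_ampa = 0.0, g_nmda = 0.0, g_adapt = 0.0;
  double y_minus = 0.0, y_trip = 0.0;
  long y_last = 0;

  // recording
  const long rec_every = std::max(1L, (long)std::llround(record_dt / dt_fine));
  const long n_rec = n_steps / rec_every + 1;
  std::vector<double> r_t, r_mw, r_NA, r_NAs, r_nb, r_nbig, r_IA, r_p, r_rate;
  std::vector<double> r_wj, r_zj, r_Tj, r_bj;
  r_t.reserve(n_rec);
  long spikes_since_rec = 0;
  List snapshot = R_NilValue;
  const long snap_step = snapshot_t >= 0 ?
      (long)std::llround(snapshot_t / dt_fine) : -1;

  std::vector<int> perm(n_syn);
  std::vector<int> pending; pending.reserve(64);
  size_t ev_i = 0;
  const double skip_x_steps = 14.0 * tau_x / dt_fine;

  RNGScope rng;

  for (long i = 0; i <= n_steps; ++i) {
    const double t = i * dt_fine;

    // presynaptic events of this step: depression induction + conductance
    double sum_dg = 0.0;
    pending.clear();
    while (ev_i < ev_step.size() && ev_step[ev_i] == i) {
      const int j = ev_syn[ev_i];
      const double ym = y_minus * std::exp(-(double)(i - y_last) *
                                           dt_fine / tau_y);
      accM[j] += A_minus * ym;
      sum_dg += dg[j];
      pending.push_back(j);
      ++ev_i;
    }

    // neuron update (forward Euler; conductance jump precedes decay)
    g_ampa += sum_dg;
    g_ampa -= g_ampa * dt_fine / tau_ampa;
    g_nmda += (g_ampa - g_nmda) * dt_fine / tau_nmda;
    g_adapt -= g_adapt * dt_fine / tau_adapt;
    const double g_exc = beta_f * g_ampa + (1.0 - beta_f) * g_nmda;
    // exponential integrator for the membrane: exact for conductances held
    // over the step, unconditionally stable at large total conductance
    {
      const double gtot = 1.0 + g_exc + g_adapt;
      const double Veq = (V_rest + g_exc * V_exc + g_adapt * V_adapt) / gtot;
      V = Veq + (V - Veq) * std::exp(-gtot * dt_fine / tau_m);
    }
    th += dt_fine / tau_thr * (th_rest - th);

    if (!std::isfinite(V)) stop("numerical divergence in membrane potential V at t=%g", t);

    bool post = false;
    if (V >= th) {
      post = true;
      // potentiation induction reads the slow trace before its increment
      const double y_trip_now = y_trip *
          std::exp(-(double)(i - y_last) * dt_fine / tau_tr);
      if (y_trip_now > 1e-14) {
        for (int j = 0; j < n_syn; ++j) {
          if ((double)(i - xlast[j]) > skip_x_steps) continue;
          const double xv = xval[j] *
              std::exp(-(double)(i - xlast[j]) * dt_fine / tau_x);
          if (xv > 1e-14) accP[j] += A_plus * xv * y_trip_now;
        }
      }
      // postsynaptic trace increments (after the pre-increment read)
      y_minus = y_minus * std::exp(-(double)(i - y_last) * dt_fine / tau_y)
          + 1.0;
      y_trip = y_trip_now + 1.0;
      y_last = i;
      V = V_rest; th = th_spike; g_adapt += g_spike;
      ++spikes_since_rec;
    }

    // presynaptic trace increments
    for (size_t q = 0; q < pending.size(); ++q) {
      const int j = pending[q];
      xval[j] = xval[j] * std::exp(-(double)(i - xlast[j]) * dt_fine / tau_x)
          + 1.0;
      xlast[j] = i;
    }

    // slow (synapse + pool) layer
    if (i > 0 && i % steps_per_slow == 0) {
      const bool psi = has_psi && t >= psi_window[0] && t < psi_window[1];
      if (psi && !psi_prev) N_A = 0.0;               // PSI onset: pool emptied
      if (!psi && psi_prev) {                        // offset: replenished
        N_A = pp.N_A_tot - N_As - (double)n_bound;
        if (N_A < 0) N_A = 0.0;
      }
      psi_prev = psi;

      const double D = (has_dop && t >= dopamine_window[0] &&
                        t < dopamine_window[1]) ? 1.0 : 0.0;
      p_gate += dt_slow * (D * k_up * (1.0 - p_gate) - k_down * p_gate);

      for (int j = 0; j < n_syn; ++j) {
        IA[j] = IA[j] * dIA + accP[j] + accM[j];
        const double wj = w[j], Tj = Tt[j], zj = z[j];
        const double Ig = (accP[j] * heav(wj - zj) +
                           accM[j] * heav(zj - wj)) * (1.0 - gam[j]);
        const double G = heav(gam[j] - th_g);
        const double ngate = gated_noise ? heav(IA[j] - th_act) : 1.0;
        w[j] = wj + dt_slow * (fcubic(wj) / tau_w +
                 a_Tw / (4.0 * tau_w) * (1.0 - G) * (Tj - wj))
             + ngate * sigma * sq_dt * norm_rand();
        // accumulated induction drives enter as impulses; large impulses
        // (HFS) are applied in saturating sub-chunks so the weight cannot
        // overshoot its well
        {
          const double tot = accP[j] + accM[j];
          if (tot > 0.0) {
            const int K = std::max(1, (int)std::ceil(tot / 0.05));
            const double ip = accP[j] / K, im = accM[j] / K;
            for (int k = 0; k < K; ++k)
              w[j] += ip * (1.0 + pospart(zj - w[j])) * (1.0 - w[j])
                    - im * (1.0 + pospart(w[j] - zj)) * (1.0 + w[j]);
          }
        }
        Tt[j] = Tj + dt_slow * (fcubic(Tj) / tau_T +
                  a_wT / (4.0 * tau_T) * G * (wj - Tj) +
                  a_zT / (4.0 * tau_T) * (1.0 - p_gate) * (zj - Tj))
              + ngate * sigma * sq_dt * norm_rand();
        z[j] = zj + dt_slow * (fcubic(zj) / tau_z +
                 a_Tz / (4.0 * tau_z) * p_gate * (Tj - zj) +
                 a_b / tau_z * heav(zj) * ((double)b[j] - 1.0))
             + sigma * sq_dt * norm_rand();
        gam[j] += kappa * Ig - gam[j] * dt_slow / tau_g;
        if (gam[j] < 0.0) gam[j] = 0.0;
        if (gam[j] > 1.0) gam[j] = 1.0;
        if (!std::isfinite(w[j]) || !std::isfinite(Tt[j]) ||
            !std::isfinite(z[j]))
          stop("numerical divergence in synapse %d at t=%g", j + 1, t);
        accP[j] = 0.0; accM[j] = 0.0;
        double d = g0 * (w_minus + (w[j] + 1.0) *
                         (k_w * w_minus - w_minus) / 2.0);
        dg[j] = d > 0.0 ? d : 0.0;
      }

      // stabilizer pool: synapses processed in a fresh random order
      rand_perm(perm);
      for (int q = 0; q < n_syn; ++q) {
        const int j = perm[q];
        const bool big = z[j] >= 0.0;
        if (b[j] == 0) {
          if (!big || force_unbound[j]) continue;
          const double r_on = pp.k1 * N_A + pp.k3 * N_As;
          const double pb = r_on * dt_slow;
          if (pb > 1.0)
            stop("binding probability %g exceeds 1; use a smaller synapse time step", pb);
          if (unif_rand() < pb) {
            b[j] = 1; ++n_bound;
            if (unif_rand() < pp.k1 * N_A / r_on) N_A -= 1.0;
            else N_As -= 1.0;
          }
        } else {
          const double k2 = unbind_rate(IA[j], pp.k0, pp.m, pp.I02, pp.r);
          const double k4 = unbind_rate(IA[j], pp.k0, pp.m, pp.I04, pp.r);
          const double pu = (k2 + k4) * dt_slow;
          if (pu > 1.0)
            stop("unbinding probability %g exceeds 1; use a smaller synapse time step", pu);
          if (unif_rand() < pu) {
            b[j] = 0; --n_bound;
            if (unif_rand() < k2 / (k2 + k4)) {
              if (!psi) N_A += 1.0;  // susceptible entity degrades under PSI
            } else N_As += 1.0;
          }
        }
      }
    }

    // recording
    if (i % rec_every == 0 || i == n_steps) {
      double mw = 0.0, mIA = 0.0; long nbig = 0;
      for (int j = 0; j < n_syn; ++j) {
        mw += w[j]; mIA += IA[j];
        if (z[j] >= 0.0) ++nbig;
      }
      r_t.push_back(t);
      r_mw.push_back(mw / n_syn);
      r_NA.push_back(N_A); r_NAs.push_back(N_As);
      r_nb.push_back((double)n_bound); r_nbig.push_back((double)nbig);
      r_IA.push_back(mIA / n_syn); r_p.push_back(p_gate);
      r_rate.push_back(spikes_since_rec / (rec_every * dt_fine));
      spikes_since_rec = 0;
      if (record_synapse >= 0 && record_synapse < n_syn) {
        r_wj.push_back(w[record_synapse]); r_zj.push_back(z[record_synapse]);
        r_Tj.push_back(Tt[record_synapse]);
        r_bj.push_back((double)b[record_synapse]);
      }
    }
    if (snap_step >= 0 && i == snap_step) {
      double mIA = 0.0; long nbig = 0;
      for (int j = 0; j < n_syn; ++j) {
        mIA += IA[j];
        if (z[j] >= 0.0) ++nbig;
      }
      snapshot = List::create(
        _["t"] = t, _["N_big"] = (double)nbig, _["n_bound"] = (double)n_bound,
        _["N_A"] = N_A, _["N_A_star"] = N_As, _["I_A"] = mIA / n_syn);
    }
  }

  List out = List::create(
    _["t"] = r_t, _["mean_w"] = r_mw, _["N_A"] = r_NA, _["N_A_star"] = r_NAs,
    _["n_bound"] = r_nb, _["N_big"] = r_nbig, _["I_A"] = r_IA,
    _["p"] = r_p, _["post_rate"] = r_rate);
  List fin = List::create(
    _["w"] = NumericVector(w.begin(), w.end()),
    _["T"] = NumericVector(Tt.begin(), Tt.end()),
    _["z"] = NumericVector(z.begin(), z.end()),
    _["gamma"] = NumericVector(gam.begin(), gam.end()),
    _["I_A"] = NumericVector(IA.begin(), IA.end()),
    _["b"] = IntegerVector(b.begin(), b.end()),
    _["N_A"] = N_A, _["N_A_star"] = N_As);
  List res = List::create(_["series"] = out, _["final"] = fin,
                          _["snapshot"] = snapshot);
  if (record_synapse >= 0) {
    res["synapse_trace"] = List::create(
      _["w"] = r_wj, _["T"] = r_Tj, _["z"] = r_zj, _["b"] = r_bj);
  }
  return res;
}

// ---------------------------------------------------------------------------
// Reduced two-dimensional reservoir model.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_run_reduced(double duration, double dt, NumericVector pulses,
                     NumericVector psi_window, List pool_par, double phi,
                     double theta_big, double eta, double omega, double tau_A,
                     double n_ASyn0, double n_A_star0, double N_big0,
                     double I_A0, double record_dt) {
  const PoolPar pp = read_pool(pool_par);
  const long n_steps = (long)std::llround(duration / dt);
  const bool has_psi = psi_window.size() == 2;
  const double decA = std::exp(-dt / tau_A);
  const long Lphi = (long)std::llround(phi / dt);
  const long Leta = (long)std::llround(eta / dt);
  if (Leta < 1) stop("eta must be at least one time step");

  // ring buffer of n_ASyn holding the last phi seconds
  const long L = Lphi + 1;
  std::vector<double> buf((size_t)L, n_ASyn0);

  double nS = n_ASyn0, nR = n_A_star0, Nb = N_big0, IA = I_A0;
  const long rec_every = std::max(1L, (long)std::llround(record_dt / dt));
  std::vector<double> r_t, r_nS, r_nR, r_nA, r_Nb, r_IA;
  size_t pi = 0;
  bool warned = false;

  for (long i = 0; i <= n_steps; ++i) {
    const double t = i * dt;
    if (i % rec_every == 0 || i == n_steps) {
      const bool psi_now = has_psi && t >= psi_window[0] && t < psi_window[1];
      double nA_now = psi_now ? 0.0 :
          std::max(0.0, pp.N_A_tot - nS - nR);
      r_t.push_back(t); r_nS.push_back(nS); r_nR.push_back(nR);
      r_nA.push_back(nA_now); r_Nb.push_back(Nb); r_IA.push_back(IA);
    }
    if (i == n_steps) break;

    // activity filter: pulses in (t, t+dt]
    IA *= decA;
    while (pi < (size_t)pulses.size() && pulses[pi] <= t + dt) {
      if (pulses[pi] > t) IA += omega / tau_A;
      ++pi;
    }

    const bool psi = has_psi && (t + dt) > psi_window[0] &&
                     (t + dt) <= psi_window[1];
    const double nA = psi ? 0.0 : std::max(0.0, pp.N_A_tot - nS - nR);
    const double k2 = unbind_rate(IA, pp.k0, pp.m, pp.I02, pp.r);
    const double k4 = unbind_rate(IA, pp.k0, pp.m, pp.I04, pp.r);
    const double dnS = -(k2 + k4) * nS + (pp.k1 * nA + pp.k3 * nR) * (Nb - nS);
    const double dnR = -pp.k3 * nR * (Nb - nS) + k4 * nS;
    nS += dt * dnS;
    nR += dt * dnR;
    if (nS < 0.0 || nR < 0.0) {
      if (!warned) { warned = true; }
      if (nS < 0.0) nS = 0.0;
      if (nR < 0.0) nR = 0.0;
    }

    // delayed-slope decay of the number of big synapses
    // buf[(i) % L] holds n_ASyn at step i; need steps i-Lphi and i-Lphi+Leta
    buf[(size_t)(i % L)] = nS;
    if (i >= Lphi) {
      const double a = buf[(size_t)((i - Lphi) % L)];
      const double bb = buf[(size_t)((i - Lphi + Leta) % L)];
      const double s = (bb - a) / eta;
      if (s <= theta_big) {
        Nb += dt * s;
        if (Nb < 0.0) Nb = 0.0;
      }
    }
  }

  return List::create(
    _["t"] = r_t, _["n_ASyn"] = r_nS, _["n_A_star"] = r_nR, _["n_A"] = r_nA,
    _["N_big"] = r_Nb, _["I_A"] = r_IA, _["warned_negative"] = warned,
    _["final"] = List::create(_["n_ASyn"] = nS, _["n_A_star"] = nR,
                              _["N_big"] = Nb, _["I_A"] = IA));
}

// conditional sequential binomial split of a multinomial step
static inline int draw_bin(int n, double p) {
  if (n <= 0 || p <= 0.0) return 0;
  if (p >= 1.0) return n;
  return (int)R::rbinom((double)n, p);
}

// ---------------------------------------------------------------------------
// Extended seven-state model. Synapses are exchangeable, so the per-synapse
// scheme is simulated exactly on state counts with (sequential) binomial
// draws. Stabilizer binding/unbinding runs on a finer substep because the
// state-based rate column is too fast for first-order probabilities at the
// state step.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_run_sb(double duration, double dt, double pool_dt,
                NumericVector I_A_series, List sb_par, List pool_par,
                double hfs_time, NumericVector psi_window,
                bool gated_beta, double record_dt) {
  const double alpha0 = as<double>(sb_par["alpha"]);
  const double beta = as<double>(sb_par["beta"]);
  const double tau_e = as<double>(sb_par["tau_e"]);
  const double tau_l = as<double>(sb_par["tau_l"]);
  const double tau_r = as<double>(sb_par["tau_r"]);
  const double alpha_hfs = as<double>(sb_par["alpha_post_hfs"]);
  const int n_syn = as<int>(sb_par["n_synapses"]);
  const int n_weak0 = as<int>(sb_par["n_weak0"]);
  const bool six_to_three = as<bool>(sb_par["six_to_three"]);
  const double th_act = as<double>(sb_par["theta_act"]);
  const double p_denom = as<double>(sb_par["p_denom"]);
  const double p_tau = as<double>(sb_par["p_tau"]);
  const double c_denom = as<double>(sb_par["c_denom"]);
  const double c_tau = as<double>(sb_par["c_tau"]);
  const double rate_unit = as<double>(sb_par["rate_unit"]);
  const PoolPar pp = read_pool(pool_par);

  const long n_steps = (long)std::llround(duration / dt);
  if ((long)I_A_series.size() < n_steps + 1)
    stop("I_A_series must have one value per state step");
  const bool has_psi = psi_window.size() == 2;
  const int nsub = std::max(1, (int)std::lround(dt / pool_dt));
  const double dts = dt / nsub;

  int N[8] = {0, 0, 0, 0, 0, 0, 0, 0};  // 1-based states
  N[3] = n_weak0; N[4] = n_syn - n_weak0;
  double N_A = pp.N_A_tot, N_As = 0.0;
  bool psi_prev = false, hfs_done = false;

  const long rec_every = std::max(1L, (long)std::llround(record_dt / dt));
  std::vector<double> r_t, r_fepsp, r_NA, r_NAs;
  std::vector<int> r_N[8];

  RNGScope rng;

  for (long i = 0; i <= n_steps; ++i) {
    const double t = i * dt;

    // instantaneous HFS pulse: all weak-basal synapses become strong-basal
    if (!hfs_done && hfs_time >= 0 && t >= hfs_time) {
      N[4] += N[3]; N[3] = 0; hfs_done = true;
    }

    if (i % rec_every == 0 || i == n_steps) {
      double weak = N[1] + N[2] + N[3];
      double strong = N[4] + N[5] + N[6] + N[7];
      r_t.push_back(t);
      r_fepsp.push_back((weak + 2.0 * strong) / 1200.0 * 100.0);
      r_NA.push_back(N_A); r_NAs.push_back(N_As);
      for (int s = 1; s <= 7; ++s) r_N[s].push_back(N[s]);
    }
    if (i == n_steps) break;

    const double IA = I_A_series[i];
    const bool psi = has_psi && t >= psi_window[0] && t < psi_window[1];
    if (psi && !psi_prev) N_A = 0.0;
    if (!psi && psi_prev) {
      N_A = pp.N_A_tot - N_As - N[7];
      if (N_A < 0) N_A = 0.0;
    }
    psi_prev = psi;

    // time-dependent potentiation/consolidation rates after HFS
    double p_rate = 0.0, c_rate = 0.0, alpha = alpha0;
    if (hfs_done) {
      const double dth = t - hfs_time;
      p_rate = dth / p_denom * std::exp(1.0 - dth / p_tau) * rate_unit;
      c_rate = dth / c_denom * std::exp(1.0 - dth / c_tau) * rate_unit;
      alpha = alpha_hfs;
    }
    const double beta_eff = gated_beta ? beta * heav(IA - th_act) : beta;

    // transitions among states 1..6 plus the slow decay of state 7,
    // all computed from the counts at the start of the step
    const int d13 = draw_bin(N[1], tau_l * dt);
    const int d23 = draw_bin(N[2], tau_e * dt);
    const int d34 = draw_bin(N[3], alpha * dt);
    int d43 = draw_bin(N[4], beta_eff * dt);
    int d45 = draw_bin(N[4] - d43, p_rate * dt / (1.0 - beta_eff * dt));
    const int d54 = draw_bin(N[5], tau_e * dt);
    int d56 = draw_bin(N[5] - d54, c_rate * dt / (1.0 - tau_e * dt));
    const int d6x = draw_bin(N[6], tau_l * dt);
    const int d7x = draw_bin(N[7], tau_r * dt);

    N[1] -= d13; N[3] += d13;
    N[2] -= d23; N[3] += d23;
    N[3] -= d34; N[4] += d34;
    N[4] -= d43 + d45; N[3] += d43; N[5] += d45;
    N[5] -= d54 + d56; N[4] += d54; N[6] += d56;
    N[6] -= d6x; N[7] -= d7x;
    if (six_to_three) { N[3] += d6x + d7x; } else { N[4] += d6x + d7x; }
    // a decaying bound synapse releases its entity into the susceptible pool
    if (!psi) N_A += d7x;

    // stabilizer binding/unbinding on the pool substep (6 <-> 7)
    for (int s = 0; s < nsub; ++s) {
      const double r_on = pp.k1 * N_A + pp.k3 * N_As;
      const double pb = r_on * dts;
      const double k2 = unbind_rate(IA, pp.k0, pp.m, pp.I02, pp.r);
      const double k4 = unbind_rate(IA, pp.k0, pp.m, pp.I04, pp.r);
      const double pu = (k2 + k4) * dts;
      if (pb > 1.0 || pu > 1.0)
        stop("pool transition probability exceeds 1; use a smaller pool_dt");
      const int binds = draw_bin(N[6], pb);
      const int unbinds = draw_bin(N[7], pu);
      int from_A = 0;
      if (binds > 0 && r_on > 0)
        from_A = draw_bin(binds, pp.k1 * N_A / r_on);
      if (from_A > (int)N_A) from_A = (int)N_A;  // integer pool floor
      int from_As = binds - from_A;
      if (from_As > (int)N_As) { from_As = (int)N_As; }
      const int bound = from_A + from_As;
      N[6] -= bound; N[7] += bound;
      N_A -= from_A; N_As -= from_As;
      const int to_A = draw_bin(unbinds, k2 / (k2 + k4));
      N[7] -= unbinds; N[6] += unbinds;
      if (!psi) N_A += to_A;
      N_As += unbinds - to_A;
    }
  }

  List out = List::create(
    _["t"] = r_t, _["fepsp"] = r_fepsp, _["N_A"] = r_NA, _["N_A_star"] = r_NAs,
    _["N1"] = r_N[1], _["N2"] = r_N[2], _["N3"] = r_N[3], _["N4"] = r_N[4],
    _["N5"] = r_N[5], _["N6"] = r_N[6], _["N7"] = r_N[7]);
  return out;
}

// ---------------------------------------------------------------------------
// Pool-only stochastic simulation with frozen co-activity: used to verify
// the closed-form reservoir laws and binding equilibria.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_run_pool(double duration, double dt, int n_syn, double I_A,
                  List pool_par, bool psi_active, IntegerVector init_bound,
                  double record_dt, double init_N_A_star = 0.0) {
  const PoolPar pp = read_pool(pool_par);
  const long n_steps = (long)std::llround(duration / dt);
  std::vector<int> b(init_bound.begin(), init_bound.end());
  if ((int)b.size() != n_syn) stop("init_bound length mismatch");
  long n_bound = 0;
  for (int j = 0; j < n_syn; ++j) n_bound += b[j];
  double N_A = psi_active ? 0.0 :
      std::max(0.0, pp.N_A_tot - n_bound - init_N_A_star);
  double N_As = init_N_A_star;
  const double k2 = unbind_rate(I_A, pp.k0, pp.m, pp.I02, pp.r);
  const double k4 = unbind_rate(I_A, pp.k0, pp.m, pp.I04, pp.r);

  const long rec_every = std::max(1L, (long)std::llround(record_dt / dt));
  std::vector<double> r_t, r_NA, r_NAs, r_nb;
  std::vector<int> perm(n_syn);
  double bound_time = 0.0;

  RNGScope rng;
  for (long i = 0; i <= n_steps; ++i) {
    if (i % rec_every == 0 || i == n_steps) {
      r_t.push_back(i * dt); r_NA.push_back(N_A); r_NAs.push_back(N_As);
      r_nb.push_back((double)n_bound);
    }
    if (i == n_steps) break;
    bound_time += (double)n_bound * dt;
    rand_perm(perm);
    for (int q = 0; q < n_syn; ++q) {
      const int j = perm[q];
      if (b[j] == 0) {
        const double r_on = pp.k1 * N_A + pp.k3 * N_As;
        const double pb = r_on * dt;
        if (pb > 1.0) stop("binding probability exceeds 1; use a smaller dt");
        if (r_on > 0 && unif_rand() < pb) {
          b[j] = 1; ++n_bound;
          if (unif_rand() < pp.k1 * N_A / r_on) N_A -= 1.0;
          else N_As -= 1.0;
        }
      } else {
        const double pu = (k2 + k4) * dt;
        if (pu > 1.0) stop("unbinding probability exceeds 1; use a smaller dt");
        if (unif_rand() < pu) {
          b[j] = 0; --n_bound;
          if (unif_rand() < k2 / (k2 + k4)) {
            if (!psi_active) N_A += 1.0;
          } else N_As += 1.0;
        }
      }
    }
  }
  return List::create(
    _["t"] = r_t, _["N_A"] = r_NA, _["N_A_star"] = r_NAs, _["n_bound"] = r_nb,
    _["mean_bound_fraction"] = bound_time / (duration * n_syn));
}
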