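// Fixed-step integrators for the energy-constrained hybrid neuron models.
// The smooth flow is advanced with RK4 (or Euler); spike/reset/death rules
// are applied at the end of every step, matching common clock-driven
// simulator semantics.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Pars {
  double Cm, gL, E0, Eu, Ef, Ed, Vth, Vr, eps0, epsc, alpha, tau_e, delta, Ie;
  double DeltaT, Vpeak, a, b, tau_w, gamma, IKATP;
  bool madexp;
};

static Pars unpack(const NumericVector& par, bool madexp) {
  Pars p;
  p.Cm = par[0]; p.gL = par[1]; p.E0 = par[2]; p.Eu = par[3]; p.Ef = par[4];
  p.Ed = par[5]; p.Vth = par[6]; p.Vr = par[7]; p.eps0 = par[8];
  p.epsc = par[9]; p.alpha = par[10]; p.tau_e = par[11]; p.delta = par[12];
  p.Ie = par[13]; p.DeltaT = par[14]; p.Vpeak = par[15]; p.a = par[16];
  p.b = par[17]; p.tau_w = par[18]; p.gamma = par[19]; p.IKATP = par[20];
  p.madexp = madexp;
  return p;
}

static inline double eff_leak(const Pars& p, double eps) {
  return p.E0 + (p.Eu - p.E0) * (1.0 - eps / p.eps0);
}

static inline double katp(const Pars& p, double eps) {
  if (p.epsc <= 0.0) return 0.0;
  return p.epsc / (p.epsc + 2.0 * eps) * p.IKATP;
}

// alpha may be overridden by a time schedule
static inline void rhs(const Pars& p, double alpha, double V, double eps,
                       double w, double I, double& dV, double& de,
                       double& dw) {
  const double EL = eff_leak(p, eps);
  const double u = 1.0 - eps / (alpha * p.eps0);
  if (p.madexp) {
    // above the spike-detection ceiling the upswing is "in spike": its
    // energetic/adaptation cost is the discrete reset (delta, b), so the
    // slow variables see V capped at Vpeak
    const double Vc = V < p.Vpeak ? V : p.Vpeak;
    const double cons = (Vc - p.Ef) / (p.Ed - p.Ef);
    double ex = (V - p.Vth) / p.DeltaT;
    if (ex > 20.0) ex = 20.0;  // overflow guard; V is cut at Vpeak anyway
    dV = (p.gL * (EL - V) +
          p.gL * p.DeltaT * ((eps - p.epsc) / p.eps0) * std::exp(ex) -
          w + I) / p.Cm;
    de = (u * u * u - cons - w / p.gamma) / p.tau_e;
    dw = (p.a * (Vc - EL) - w + katp(p, eps)) / p.tau_w;
  } else {
    const double cons = (V - p.Ef) / (p.Ed - p.Ef);
    dV = (p.gL * (EL - V) + I) / p.Cm;
    de = (u * u * u - cons) / p.tau_e;
    dw = 0.0;
  }
}

// piecewise-linear alpha(t); constant extrapolation beyond the knots
static inline double alpha_at(const NumericVector& at, const NumericVector& av,
                              double base, double t) {
  const int n = at.size();
  if (n == 0) return base;
  if (t <= at[0]) return av[0];
  if (t >= at[n - 1]) return av[n - 1];
  int i = 1;
  while (at[i] < t) ++i;
  const double f = (t - at[i - 1]) / (at[i] - at[i - 1]);
  return av[i - 1] + f * (av[i] - av[i - 1]);
}

static inline double seg_current(const NumericVector& s0,
                                 const NumericVector& s1,
                                 const NumericVector& amp, double t) {
  double I = 0.0;
  for (int i = 0; i < s0.size(); ++i)
    if (t >= s0[i] && t < s1[i]) I += amp[i];
  return I;
}

// [[Rcpp::export]]
List integrate_neuron_cpp(int model, NumericVector par, double V0, double e0,
                          double w0, double duration, double dt,
                          NumericVector seg_start, NumericVector seg_stop,
                          NumericVector seg_amp, double pois_rate,
                          double pois_weight, bool pois_delta, double tau_syn,
                          NumericVector alpha_t, NumericVector alpha_v,
                          double refractory, bool euler, int rec_every) {
  const Pars p = unpack(par, model == 1);
  const long nsteps = (long)std::ceil(duration / dt - 1e-9);
  const long nrec = nsteps / rec_every + 1;
  NumericVector rt(nrec), rV(nrec), re(nrec), rw(nrec);
  std::vector<double> spikes;
  double V = V0, eps = e0, w = w0, Isyn = 0.0, refr = 0.0;
  double death_time = -1.0;
  bool alive = true;
  const double lam = pois_rate * dt * 1e-3;  // rate in Hz, dt in ms
  const double sdec = std::exp(-dt / tau_syn);
  const double hdec = std::exp(-0.5 * dt / tau_syn);

  long ri = 0;
  rt[0] = 0.0; rV[0] = V; re[0] = eps; rw[0] = w; ri = 1;

  for (long step = 0; step < nsteps; ++step) {
    const double t = step * dt;
    if (alive) {
      // Poisson arrivals credited at the start of the step
      if (lam > 0.0) {
        const int narr = (int)R::rpois(lam);
        if (narr > 0) {
          if (pois_delta) V += narr * pois_weight / p.Cm;
          else Isyn += narr * pois_weight;
        }
      }
      const double al0 = alpha_at(alpha_t, alpha_v, p.alpha, t);
      if (refr > 0.0) {
        // membrane clamped at Vr; energy/adaptation keep evolving
        double dV, de, dw;
        rhs(p, al0, p.Vr, eps, w, 0.0, dV, de, dw);
        eps += dt * de; w += dt * dw; V = p.Vr;
        refr -= dt;
      } else if (euler) {
        double dV, de, dw;
        const double I = seg_current(seg_start, seg_stop, seg_amp, t) +
                         p.Ie + Isyn;
        rhs(p, al0, V, eps, w, I, dV, de, dw);
        V += dt * dV; eps += dt * de; w += dt * dw;
      } else {
        // RK4: the step current is held constant over the step (evaluated
        // at the step start, as in clock-driven simulators), while the
        // synaptic current decays analytically within the step
        const double alh = alpha_at(alpha_t, alpha_v, p.alpha,
                                    t + 0.5 * dt);
        const double al1 = alpha_at(alpha_t, alpha_v, p.alpha, t + dt);
        const double Iseg = seg_current(seg_start, seg_stop, seg_amp, t) +
                            p.Ie;
        const double I0 = Iseg + Isyn;
        const double Ih = Iseg + Isyn * hdec;
        const double I1 = Iseg + Isyn * sdec;
        double k1V, k1e, k1w, k2V, k2e, k2w, k3V, k3e, k3w, k4V, k4e, k4w;
        rhs(p, al0, V, eps, w, I0, k1V, k1e, k1w);
        rhs(p, alh, V + 0.5 * dt * k1V, eps + 0.5 * dt * k1e,
            w + 0.5 * dt * k1w, Ih, k2V, k2e, k2w);
        rhs(p, alh, V + 0.5 * dt * k2V, eps + 0.5 * dt * k2e,
            w + 0.5 * dt * k2w, Ih, k3V, k3e, k3w);
        rhs(p, al1, V + dt * k3V, eps + dt * k3e, w + dt * k3w, I1,
            k4V, k4e, k4w);
        V += dt / 6.0 * (k1V + 2 * k2V + 2 * k3V + k4V);
        eps += dt / 6.0 * (k1e + 2 * k2e + 2 * k3e + k4e);
        w += dt / 6.0 * (k1w + 2 * k2w + 2 * k3w + k4w);
      }
      Isyn *= sdec;
      if (!std::isfinite(V) || !std::isfinite(eps) || !std::isfinite(w))
        stop("integration diverged at step %ld (t = %.4f ms); reduce dt",
             step, t);
      // end-of-step discrete rules
      const bool fire = p.madexp ? (V >= p.Vpeak)
                                 : (V >= p.Vth && eps >= p.epsc);
      if (fire && refr <= 0.0) {
        spikes.push_back(t + dt);
        V = p.Vr;
        eps -= p.delta;
        if (p.madexp) w += p.b;
        refr = refractory;
      }
      if (eps <= 0.0 && V >= p.Ed) {  // death: state freezes
        alive = false;
        death_time = t + dt;
      }
    }
    if ((step + 1) % rec_every == 0 && ri < nrec) {
      rt[ri] = t + dt; rV[ri] = V; re[ri] = eps; rw[ri] = w; ++ri;
    }
  }
  return List::create(_["t"] = rt, _["V"] = rV, _["eps"] = re, _["w"] = rw,
                      _["spikes"] = NumericVector(spikes.begin(),
                                                  spikes.end()),
                      _["death_time"] = death_time);
}

// ---------------------------------------------------------------------------
// Recurrent network of eLIF neurons with current-based exponential synapses,
// uniform transmission delay, and independent per-neuron Poisson background.
// Synchronous clock-driven Euler update; spikes delivered via a ring buffer.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List simulate_network_cpp(NumericVector par, IntegerVector ptr,
                          IntegerVector idx, NumericVector wsyn,
                          NumericVector V0, NumericVector e0,
                          double duration, double dt, int delay_steps,
                          double tau_syn, double bg_rate, double bg_weight,
                          IntegerVector stim_idx, double stim_mult,
                          double stim_start, double stim_stop,
                          double refractory, IntegerVector rec_idx,
                          int rec_every) {
  const Pars p = unpack(par, false);
  const int N = V0.size();
  const long nsteps = (long)std::ceil(duration / dt - 1e-9);
  const int buflen = delay_steps + 1;
  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> eps(e0.begin(), e0.end());
  std::vector<double> Isyn(N, 0.0), refr(N, 0.0);
  std::vector<char> alive(N, 1);
  std::vector<double> buf((size_t)buflen * N, 0.0);
  std::vector<std::vector<double> > trains(N);
  const double sdec = std::exp(-dt / tau_syn);
  const double lam1 = bg_rate * dt * 1e-3;  // per neuron per step

  std::vector<char> is_stim(N, 0);
  for (int k = 0; k < stim_idx.size(); ++k) is_stim[stim_idx[k]] = 1;
  const int nstim = stim_idx.size();

  const int nrecN = rec_idx.size();
  const long nrec = nrecN ? nsteps / rec_every + 1 : 0;
  NumericMatrix recV(nrec, nrecN), recE(nrec, nrecN);
  NumericVector rect(nrec);
  long ri = 0;
  if (nrecN) {
    rect[0] = 0.0;
    for (int j = 0; j < nrecN; ++j) {
      recV(0, j) = V[rec_idx[j]]; recE(0, j) = eps[rec_idx[j]];
    }
    ri = 1;
  }

  for (long step = 0; step < nsteps; ++step) {
    const double t = step * dt;
    const int slot = step % buflen;
    // deliver delayed recurrent input, decay, then add fresh Poisson events
    double* row = &buf[(size_t)slot * N];
    for (int i = 0; i < N; ++i) {
      Isyn[i] = Isyn[i] * sdec + row[i];
      row[i] = 0.0;
    }
    // aggregated Poisson background: iid across neurons, so draw the total
    // event count per group and scatter uniformly
    const bool stim_on = stim_mult != 1.0 && t >= stim_start && t < stim_stop;
    if (lam1 > 0.0) {
      const double lam_base = lam1 * (stim_on ? (N - nstim) : N);
      int ntot = (int)R::rpois(lam_base);
      for (int k = 0; k < ntot; ++k) {
        int i = (int)(unif_rand() * N);
        if (i >= N) i = N - 1;
        if (stim_on && is_stim[i]) { --k; continue; }  // redraw outside group
        Isyn[i] += bg_weight;
      }
      if (stim_on && nstim) {
        int ns = (int)R::rpois(lam1 * stim_mult * nstim);
        for (int k = 0; k < ns; ++k) {
          int j = (int)(unif_rand() * nstim);
          if (j >= nstim) j = nstim - 1;
          Isyn[stim_idx[j]] += bg_weight;
        }
      }
    }
    // Euler update + discrete rules
    const int dslot = (step + delay_steps) % buflen;
    double* drow = &buf[(size_t)dslot * N];
    for (int i = 0; i < N; ++i) {
      if (!alive[i]) continue;
      if (refr[i] > 0.0) {
        double dV, de, dw;
        rhs(p, p.alpha, p.Vr, eps[i], 0.0, 0.0, dV, de, dw);
        eps[i] += dt * de; V[i] = p.Vr;
        refr[i] -= dt;
        continue;
      }
      double dV, de, dw;
      rhs(p, p.alpha, V[i], eps[i], 0.0, Isyn[i] + p.Ie, dV, de, dw);
      V[i] += dt * dV; eps[i] += dt * de;
      if (V[i] >= p.Vth && eps[i] >= p.epsc) {
        trains[i].push_back(t + dt);
        V[i] = p.Vr; eps[i] -= p.delta; refr[i] = refractory;
        for (int k = ptr[i]; k < ptr[i + 1]; ++k) drow[idx[k]] += wsyn[k];
      }
      if (eps[i] <= 0.0 && V[i] >= p.Ed) alive[i] = 0;
    }
    if (nrecN && (step + 1) % rec_every == 0 && ri < nrec) {
      rect[ri] = t + dt;
      for (int j = 0; j < nrecN; ++j) {
        recV(ri, j) = V[rec_idx[j]]; recE(ri, j) = eps[rec_idx[j]];
      }
      ++ri;
    }
  }
  List sp(N);
  for (int i = 0; i < N; ++i)
    sp[i] = NumericVector(trains[i].begin(), trains[i].end());
  int ndead = 0;
  for (int i = 0; i < N; ++i) if (!alive[i]) ++ndead;
  return List::create(_["spikes"] = sp, _["t"] = rect, _["V"] = recV,
                      _["eps"] = recE, _["n_dead"] = ndead);
}
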