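// Izhikevich network simulator with conductance-based synapses, Poisson
// background pulses, white-noise drive, optional STDP + homeostatic scaling,
// and exact state snapshot/restore (own RNG so checkpoints are bit-exact).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded by splitmix64, Box-Muller normals with cached spare.
// The full generator state lives in the snapshot so restore + continue is
// bit-identical to an uninterrupted run.
// ---------------------------------------------------------------------------
struct Rng {
  uint64_t s[4];
  bool has_spare;
  double spare;

  static uint64_t splitmix64(uint64_t &x) {
    x += 0x9E3779B97f4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t sd) {
    uint64_t x = sd;
    for (int i = 0; i < 4; i++) s[i] = splitmix64(x);
    has_spare = false;
    spare = 0.0;
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double normal() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
  int poisson(double lambda) {  // Knuth; lambda is tiny here (<< 1)
    double L = std::exp(-lambda), p = 1.0;
    int k = 0;
    do { k++; p *= unif(); } while (p > L);
    return k - 1;
  }
  // serialize as 8 doubles (uint32 halves) + spare flag + spare value
  NumericVector save() const {
    NumericVector out(10);
    for (int i = 0; i < 4; i++) {
      out[2 * i]     = (double)(uint32_t)(s[i] & 0xFFFFFFFFULL);
      out[2 * i + 1] = (double)(uint32_t)(s[i] >> 32);
    }
    out[8] = has_spare ? 1.0 : 0.0;
    out[9] = spare;
    return out;
  }
  void load(const NumericVector &v) {
    for (int i = 0; i < 4; i++) {
      uint64_t lo = (uint64_t)(uint32_t)v[2 * i];
      uint64_t hi = (uint64_t)(uint32_t)v[2 * i + 1];
      s[i] = lo | (hi << 32);
    }
    has_spare = v[8] != 0.0;
    spare = v[9];
  }
};

// Shared STDP trace update used by the network simulator and by the
// standalone two-neuron driver below (so tests exercise the same code path).
struct StdpRule {
  int rule;          // 1 = additive, 2 = weight-dependent (Morrison-style)
  double a_plus, a_minus, w_max, mu, alpha;

  inline void on_pre(double &w, double x_post) const {
    if (rule == 1) w -= a_minus * x_post;
    else           w -= alpha * a_minus * (w / w_max) * x_post;
    if (w < 0.0) w = 0.0; else if (w > w_max) w = w_max;
  }
  inline void on_post(double &w, double x_pre) const {
    if (rule == 1) w += a_plus * x_pre;
    else           w += a_plus * std::pow(w / w_max, mu) * x_pre;
    if (w < 0.0) w = 0.0; else if (w > w_max) w = w_max;
  }
};

// [[Rcpp::export]]
List cpp_simulate(List net, double duration_ms, double dt_v, double dt_slow,
                  double bg_rate_hz, double bg_amp, double bg_size,
                  IntegerVector stim_neurons, double stim_amp,
                  double stim_start, double stim_dur,
                  bool bg_kick, bool fluc_on, double fluc_scale,
                  Nullable<List> plasticity, Nullable<List> state_in,
                  double seed) {
  const int n  = as<int>(net["n"]);
  const int ne = as<int>(net["n_exc"]);
  IntegerVector ptr  = net["out_ptr"];    // length n + 1, 0-based CSR
  IntegerVector post = net["out_post"];   // 0-based
  NumericVector w_in = net["w"];
  NumericVector a = net["a"], b = net["b"], cres = net["c"], dres = net["d"];
  NumericVector imean = net["i_fluc_mean"], isd = net["i_fluc_sd"];
  const int E = post.size();
  // plain arrays for the hot loops
  std::vector<int> cptr(ptr.begin(), ptr.end()), cpost(post.begin(), post.end());

  const bool plastic = plasticity.isNotNull();
  List pl;
  StdpRule rule{1, 0.0, 0.0, 1.0, 0.4, 1.0};
  double tau_plus = 20.0, tau_minus = 20.0, tau_h = 2000.0, r_tar = 1.5;
  int rate_steps = 1;
  bool homeo = true;
  if (plastic) {
    pl = plasticity.get();
    rule.rule    = as<int>(pl["rule_code"]);
    rule.a_plus  = as<double>(pl["a_plus"]);
    rule.a_minus = as<double>(pl["a_minus"]);
    rule.w_max   = as<double>(pl["w_max"]);
    rule.mu      = as<double>(pl["mu"]);
    rule.alpha   = as<double>(pl["alpha"]);
    tau_plus  = as<double>(pl["tau_plus"]);
    tau_minus = as<double>(pl["tau_minus"]);
    tau_h     = as<double>(pl["tau_h"]);       // ms
    r_tar     = as<double>(pl["r_target"]);    // Hz
    homeo     = as<bool>(pl["homeostasis"]);
    rate_steps = (int)std::lround(as<double>(pl["rate_window"]) / dt_slow);
    if (rate_steps < 1) rate_steps = 1;
  }

  // weights: copied (plastic runs modify them)
  std::vector<double> w(w_in.begin(), w_in.end());

  // plastic edges: exc -> exc
  std::vector<int> pe_id, pe_pre, pe_post;
  std::vector<int> in_ptr(ne + 1, 0), in_eid, in_pre;
  if (plastic) {
    for (int i = 0; i < ne; i++)
      for (int k = cptr[i]; k < cptr[i + 1]; k++)
        if (cpost[k] < ne) {
          pe_id.push_back(k); pe_pre.push_back(i); pe_post.push_back(cpost[k]);
          in_ptr[cpost[k] + 1]++;
        }
    for (int j = 0; j < ne; j++) in_ptr[j + 1] += in_ptr[j];
    in_eid.resize(pe_id.size());
    in_pre.resize(pe_id.size());
    std::vector<int> fill(in_ptr.begin(), in_ptr.end() - 1);
    for (int i = 0; i < ne; i++)
      for (int k = cptr[i]; k < cptr[i + 1]; k++)
        if (cpost[k] < ne) { in_eid[fill[cpost[k]]] = k; in_pre[fill[cpost[k]]] = i; fill[cpost[k]]++; }
  }

  const int n_steps = (int)std::lround(duration_ms / dt_slow);
  const int n_sub = (int)std::lround(dt_slow / dt_v);
  const double dec_e = std::exp(-dt_slow / 2.0);   // exc conductance, tau = 2 ms
  const double dec_i = std::exp(-dt_slow / 10.0);  // inh conductance, tau = 10 ms
  const double dec_p = plastic ? std::exp(-dt_slow / tau_plus) : 1.0;
  const double dec_m = plastic ? std::exp(-dt_slow / tau_minus) : 1.0;

  // state vectors
  std::vector<double> v(n), u(n), g(ne, 0.0), se(n, 0.0), si(n, 0.0);
  std::vector<double> xpre, xpost, rate_buf;
  int rate_pos = 0;
  double rate_sum = 0.0;
  Rng rng;

  if (state_in.isNotNull()) {
    List st = state_in.get();
    NumericVector sv = st["v"], su = st["u"], sg = st["g"], sse = st["se"], ssi = st["si"];
    std::copy(sv.begin(), sv.end(), v.begin());
    std::copy(su.begin(), su.end(), u.begin());
    std::copy(sg.begin(), sg.end(), g.begin());
    std::copy(sse.begin(), sse.end(), se.begin());
    std::copy(ssi.begin(), ssi.end(), si.begin());
    rng.load(st["rng"]);
    if (plastic) {
      NumericVector sxp = st["x_pre"], sxm = st["x_post"], sw = st["w"], srb = st["rate_buf"];
      xpre.assign(sxp.begin(), sxp.end());
      xpost.assign(sxm.begin(), sxm.end());
      if (sw.size() == E) std::copy(sw.begin(), sw.end(), w.begin());
      rate_buf.assign(srb.begin(), srb.end());
      rate_pos = as<int>(st["rate_pos"]);
      for (double x : rate_buf) rate_sum += x;
      if ((int)rate_buf.size() != rate_steps)
        stop("snapshot rate buffer does not match the configured rate window");
    }
  } else {
    rng.seed((uint64_t)seed);
    // start every neuron at its resting fixed point for the frozen drive
    // (spike-free start); cells without a fixed point start at the reset value
    for (int i = 0; i < n; i++) {
      double im = fluc_on ? imean[i] : 0.0;
      double disc = (5.0 - b[i]) * (5.0 - b[i]) - 0.16 * (140.0 + im);
      v[i] = disc >= 0.0 ? (-(5.0 - b[i]) - std::sqrt(disc)) / 0.08 : cres[i];
      u[i] = b[i] * v[i];
    }
  }
  if (plastic && xpre.empty()) {
    xpre.assign(ne, 0.0);
    xpost.assign(ne, 0.0);
    rate_buf.assign(rate_steps, 0.0);
  }

  // plastic exc->exc synaptic sum per postsynaptic neuron, recomputed exactly
  // each step so homeostatic rescaling and STDP stay consistent
  std::vector<double> acc_pl(plastic ? ne : 0, 0.0);
  if (plastic)
    for (size_t k = 0; k < pe_id.size(); k++)
      acc_pl[pe_post[k]] += w[pe_id[k]] * g[pe_pre[k]];

  std::vector<char> stim_flag(n, 0);
  for (int i = 0; i < stim_neurons.size(); i++) stim_flag[stim_neurons[i]] = 1;
  const int stim_s0 = (int)std::lround(stim_start / dt_slow);
  const int stim_s1 = (int)std::lround((stim_start + stim_dur) / dt_slow);
  const bool has_stim = stim_neurons.size() > 0 && stim_amp != 0.0;

  if (bg_size < 1.0) stop("bg_size must be >= 1");
  const int bg_k = (int)std::lround(bg_size);
  // events arrive network-wide so that each neuron sees bg_rate_hz pulses/s
  const double lam_bg = bg_rate_hz * (double)ne * dt_slow * 1e-3 / bg_k;
  std::vector<double> ibg(ne, 0.0);
  std::vector<int> spikers; spikers.reserve(n);
  std::vector<int> out_step, out_id;
  const double dt_sec = dt_slow * 1e-3;

  for (int step = 0; step < n_steps; step++) {
    // background pulses for this step (current 15 for one slow step)
    int n_ev = 0;
    if (bg_rate_hz > 0.0) {
      n_ev = rng.poisson(lam_bg);
      for (int e = 0; e < n_ev; e++)
        for (int q = 0; q < bg_k; q++) {  // one correlated volley of bg_k cells
          int tgt = (int)(rng.unif() * ne);
          if (tgt >= ne) tgt = ne - 1;
          if (bg_kick) v[tgt] += bg_amp;  // event = depolarization of bg_amp
          else ibg[tgt] += bg_amp;        // event = current bg_amp for one step
        }
    }
    const bool stim_now = has_stim && step >= stim_s0 && step < stim_s1;

    // integrate all neurons with input fixed over the slow step
    spikers.clear();
    for (int i = 0; i < n; i++) {
      double I = 0.0;
      if (fluc_on) I += imean[i] + fluc_scale * isd[i] * rng.normal();
      if (i < ne) I += ibg[i];
      if (stim_now && stim_flag[i]) I += stim_amp;
      double s_exc = se[i] + (plastic && i < ne ? acc_pl[i] : 0.0);
      I += s_exc * (0.0 - v[i]) + si[i] * (-80.0 - v[i]);

      double vi = v[i], ui = u[i];
      for (int s = 0; s < n_sub; s++)
        vi += dt_v * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + I);
      ui += dt_slow * a[i] * (b[i] * vi - ui);
      if (!std::isfinite(vi))
        stop("simulation became unstable (non-finite membrane potential)");
      if (vi >= 30.0) {
        out_step.push_back(step); out_id.push_back(i);
        spikers.push_back(i);
        vi = cres[i]; ui += dres[i];
      }
      v[i] = vi; u[i] = ui;
    }
    if (n_ev > 0) for (int i = 0; i < ne; i++) ibg[i] = 0.0;

    // conductance decay
    for (int i = 0; i < n; i++) { se[i] *= dec_e; si[i] *= dec_i; }
    for (int i = 0; i < ne; i++) g[i] *= dec_e;
    if (plastic) for (int i = 0; i < ne; i++) { xpre[i] *= dec_p; xpost[i] *= dec_m; }

    // spike effects: conductance increments + STDP
    int n_exc_spikes = 0;
    for (int i : spikers) {
      if (i < ne) {
        n_exc_spikes++;
        g[i] += 1.0;
        for (int k = cptr[i]; k < cptr[i + 1]; k++) {
          if (plastic && cpost[k] < ne) continue;  // via acc_pl
          se[cpost[k]] += w[k];
        }
        if (plastic)  // depression: presynaptic spike reads the post trace
          for (int k = cptr[i]; k < cptr[i + 1]; k++)
            if (cpost[k] < ne) rule.on_pre(w[k], xpost[cpost[k]]);
      } else {
        for (int k = cptr[i]; k < cptr[i + 1]; k++) si[cpost[k]] += w[k];
      }
    }
    if (plastic) {
      for (int j : spikers)  // potentiation: postsynaptic spike reads pre traces
        if (j < ne)
          for (int k = in_ptr[j]; k < in_ptr[j + 1]; k++)
            rule.on_post(w[in_eid[k]], xpre[in_pre[k]]);
      for (int i : spikers)
        if (i < ne) { xpre[i] += 1.0; xpost[i] += 1.0; }

      // trailing-window excitatory population rate (Hz)
      rate_sum += n_exc_spikes - rate_buf[rate_pos];
      rate_buf[rate_pos] = n_exc_spikes;
      rate_pos = (rate_pos + 1) % rate_steps;
      double rbar = rate_sum / ((double)ne * rate_steps * dt_sec);

      const double f = homeo ? 1.0 + dt_slow * (r_tar - rbar) / tau_h : 1.0;
      std::fill(acc_pl.begin(), acc_pl.end(), 0.0);
      const int npe = (int)pe_id.size();
      const double wmax = rule.w_max;
      const int *ppid = pe_id.data(), *pppre = pe_pre.data(), *pppost = pe_post.data();
      double *pw = w.data();
      const double *pg = g.data();
      double *pacc = acc_pl.data();
      for (int k = 0; k < npe; k++) {
        double wk = pw[ppid[k]] * f;
        if (wk > wmax) wk = wmax;
        pw[ppid[k]] = wk;
        pacc[pppost[k]] += wk * pg[pppre[k]];
      }
    }
  }

  List state = List::create(
    _["v"] = NumericVector(v.begin(), v.end()),
    _["u"] = NumericVector(u.begin(), u.end()),
    _["g"] = NumericVector(g.begin(), g.end()),
    _["se"] = NumericVector(se.begin(), se.end()),
    _["si"] = NumericVector(si.begin(), si.end()),
    _["rng"] = rng.save());
  if (plastic) {
    state["x_pre"] = NumericVector(xpre.begin(), xpre.end());
    state["x_post"] = NumericVector(xpost.begin(), xpost.end());
    state["w"] = NumericVector(w.begin(), w.end());
    state["rate_buf"] = NumericVector(rate_buf.begin(), rate_buf.end());
    state["rate_pos"] = rate_pos;
  }
  List out = List::create(
    _["spike_step"] = IntegerVector(out_step.begin(), out_step.end()),
    _["spike_neuron"] = IntegerVector(out_id.begin(), out_id.end()),
    _["state"] = state);
  if (plastic) out["w"] = NumericVector(w.begin(), w.end());
  return out;
}

// ---------------------------------------------------------------------------
// Standalone trace-based STDP on one synapse with prescribed pre/post spike
// steps; exercises the same StdpRule and the same per-step ordering as the
// network simulator. Used to validate against the explicit all-pairs sum.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_stdp_train(IntegerVector pre_steps, IntegerVector post_steps,
                    double w0, double dt_slow, int rule_code,
                    double a_plus, double a_minus,
                    double tau_plus, double tau_minus,
                    double w_max, double mu, double alpha, int n_steps) {
  StdpRule rule{rule_code, a_plus, a_minus, w_max, mu, alpha};
  const double dec_p = std::exp(-dt_slow / tau_plus);
  const double dec_m = std::exp(-dt_slow / tau_minus);
  std::vector<char> pre(n_steps, 0), pst(n_steps, 0);
  for (int i = 0; i < pre_steps.size(); i++) pre[pre_steps[i]] = 1;
  for (int i = 0; i < post_steps.size(); i++) pst[post_steps[i]] = 1;
  double w = w0, xpre = 0.0, xpost = 0.0;
  for (int step = 0; step < n_steps; step++) {
    xpre *= dec_p; xpost *= dec_m;
    if (pre[step]) rule.on_pre(w, xpost);
    if (pst[step]) rule.on_post(w, xpre);
    if (pre[step]) xpre += 1.0;
    if (pst[step]) xpost += 1.0;
  }
  return List::create(_["w"] = w, _["x_pre"] = xpre, _["x_post"] = xpost);
}
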