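#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Discrete-time SKAN engine: one call advances a layer of neurons sharing the
// same input channels over n_steps time steps of unit dt.
//
// Update order within a step (register-transfer timing: the flag is
// combinational on the current input and registered state, the accumulator
// integrates the new flag, adaptation reads only registered values):
//   (a) kernel flag:        p(t)  from u(t), p(t-1), r(t-1)
//   (b) kernel accumulate:  r(t)  = max(r(t-1) + p(t)*dr(t-1), 0)
//                           dr(t) = clamp(dr(t-1) + p(t-1)*ddr*s(t-1), floor, max)
//   (c) membrane(t) = sum_i r_i(t)
//   (d) s_n(t) = membrane > theta(t-1), gated by (inh(t-1)==0 | s_n(t-1)==1)
//   (e) homeostatic threshold update (rise while spiking, fall on membrane
//       return to zero with inhibition clear, or on own falling edge while
//       inhibition is active)
//   (f) inh(t) = inh_max if any s_n(t) else max(inh(t-1) - inh_decay, 0)
//
// Events must be sorted by time (0-based step index), channels 1-based.
// With adapt=false, dr and theta are frozen (pure probe; kernels still run).

// [[Rcpp::export(".skan_engine_cpp")]]
List skan_engine_cpp(IntegerVector ev_time, IntegerVector ev_channel,
                     int n_steps, int n_channels,
                     IntegerMatrix p0, IntegerMatrix r0, IntegerMatrix dr0,
                     IntegerVector s0, IntegerVector theta0, int inh0,
                     int w, int ddr, int dr_max, int dr_floor,
                     int theta_rise, int theta_fall,
                     int inh_max, int inh_decay,
                     bool adapt, bool record_mem, bool record_r) {
  const int n_neurons = p0.ncol();
  if (p0.nrow() != n_channels)
    stop("state/channel dimension mismatch");

  IntegerMatrix p(clone(p0)), r(clone(r0)), dr(clone(dr0));
  std::vector<int> s_prev(s0.begin(), s0.end());
  std::vector<int> theta(theta0.begin(), theta0.end());
  std::vector<int> mem_prev(n_neurons);
  for (int n = 0; n < n_neurons; ++n) {
    long m = 0;
    for (int i = 0; i < n_channels; ++i) m += r(i, n);
    mem_prev[n] = (int)m;
  }
  int inh = inh0;

  IntegerMatrix s_out(n_neurons, n_steps);
  IntegerMatrix mem_out, theta_out;
  IntegerVector inh_out;
  IntegerVector r_out;
  if (record_mem) {
    mem_out = IntegerMatrix(n_neurons, n_steps);
    theta_out = IntegerMatrix(n_neurons, n_steps);
    inh_out = IntegerVector(n_steps);
  }
  if (record_r) {
    r_out = IntegerVector(Dimension(n_channels, n_neurons, n_steps));
  }

  std::vector<int> u(n_channels, 0);
  std::vector<int> touched;
  touched.reserve(8);
  R_xlen_t ev = 0, n_ev = ev_time.size();
  std::vector<int> s_now(n_neurons);

  for (int t = 0; t < n_steps; ++t) {
    // input spikes arriving this step
    touched.clear();
    while (ev < n_ev && ev_time[ev] == t) {
      int ch = ev_channel[ev] - 1;
      if (ch < 0 || ch >= n_channels) stop("event channel out of range");
      if (!u[ch]) { u[ch] = 1; touched.push_back(ch); }
      ++ev;
    }
    if (ev < n_ev && ev_time[ev] < t) stop("events must be sorted by time");

    int any_spike = 0;
    for (int n = 0; n < n_neurons; ++n) {
      const int sp = s_prev[n];
      long mem = 0;
      for (int i = 0; i < n_channels; ++i) {
        const int rp = r(i, n), pp = p(i, n), drp = dr(i, n);
        int pn;
        if ((u[i] == 1 && pp == 0) || (pp == 1 && rp < w)) pn = 1;
        else if ((pp == 1 && rp >= w) || (pp == -1 && rp > 0)) pn = -1;
        else pn = 0;
        int rn = rp + pn * drp;
        if (rn < 0) rn = 0;
        int drn = drp;
        if (adapt && sp) {
          drn = drp + pp * ddr;
          if (drn > dr_max) drn = dr_max;
          if (drn < dr_floor) drn = dr_floor;
        }
        r(i, n) = rn; p(i, n) = pn; dr(i, n) = drn;
        mem += rn;
        if (record_r) r_out[i + n_channels * (n + (R_xlen_t)n_neurons * t)] = rn;
      }
      const bool gate = (inh == 0) || (sp == 1);
      const int sn = (mem > theta[n] && gate) ? 1 : 0;
      if (adapt) {
        if (sn == 1) {
          theta[n] += theta_rise;
        } else if ((mem == 0 && mem_prev[n] > 0 && inh == 0) ||
                   (sp == 1 && inh > 0)) {
          theta[n] -= theta_fall;
          if (theta[n] < 0) theta[n] = 0;
        }
      }
      s_now[n] = sn;
      s_out(n, t) = sn;
      if (record_mem) { mem_out(n, t) = (int)mem; theta_out(n, t) = theta[n]; }
      mem_prev[n] = (int)mem;
      if (sn) any_spike = 1;
    }
    for (int n = 0; n < n_neurons; ++n) s_prev[n] = s_now[n];
    inh = any_spike ? inh_max : (inh - inh_decay > 0 ? inh - inh_decay : 0);
    if (record_mem) inh_out[t] = inh;
    for (size_t k = 0; k < touched.size(); ++k) u[touched[k]] = 0;
  }

  List out = List::create(
    _["s"] = s_out,
    _["p"] = p, _["r"] = r, _["dr"] = dr,
    _["s_last"] = IntegerVector(s_prev.begin(), s_prev.end()),
    _["theta"] = IntegerVector(theta.begin(), theta.end()),
    _["inh"] = inh);
  if (record_mem) {
    out["membrane"] = mem_out;
    out["theta_trace"] = theta_out;
    out["inh_trace"] = inh_out;
  }
  if (record_r) out["r_trace"] = r_out;
  return out;
}
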