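#include <Rcpp.h>
using namespace Rcpp;

// Full closed parameter vector layout (see full_param_vector() on the R side):
//  0 k2   1 k3   2 k4   3 k5   4 k6   5 k7   6 k8   7 k9
//  8 k10  9 k11 10 k12 11 k13 12 L2  13 L4  14 L6  15 L8
// 16 L11 17 V   18 a   19 b   20 c   21 d   22 GIP_B 23 GLP1_B
// State layout: 0 Intest_G, 1 GIP, 2 GLP1, 3 A_GutG, 4 G, 5 I, 6 CP, 7 X.
// A GLP-1-free subject is integrated with the GLP1 row identically zero
// (k4 = k5 = c = d = GLP1_B = GLP1(0) = 0); the R layer hides the column.

static inline void model_rhs(const double* p, const double* y, double vin,
                             double* dy) {
  const double IntestG = y[0], GIP = y[1], GLP1 = y[2], AG = y[3];
  const double G = y[4], I = y[5], CP = y[6], X = y[7];

  const double v2  = p[0] * IntestG / (p[12] + IntestG);
  const double v3  = p[1] * (p[22] - GIP);
  const double v4  = p[2] * IntestG / (p[13] + IntestG);
  const double v5  = p[3] * (p[23] - GLP1);
  const double v6  = p[4] * IntestG / (p[14] + IntestG);
  const double v7  = p[5] * AG;
  const double v8  = p[6] / (p[15] + X);
  const double v9  = p[7] * G * X;
  const double v10 = p[8] * (G + p[18] * GIP + p[19] * G * GIP +
                             p[20] * GLP1 + p[21] * G * GLP1);
  const double v11 = p[9] * I / (p[16] + I);
  const double v12 = p[10] * CP;
  const double v13 = p[11] * X;

  dy[0] = vin - v6;
  dy[1] = v2 + v3;
  dy[2] = v4 + v5;
  dy[3] = v6 - v7;
  dy[4] = v7 / p[17] + v8 - v9;
  dy[5] = v10 - v11;
  dy[6] = v10 - v12;
  dy[7] = v11 / p[9] - v13;
}

// Piecewise-constant ingestion flux. Events are disjoint and sorted by start;
// columns: start, end, rate [g/min]. `ev` carries the scan position across
// calls within one (forward-moving) integration.
static inline double ingestion_rate(const NumericMatrix& events, double t,
                                    int& ev) {
  const int nev = events.nrow();
  while (ev < nev && t >= events(ev, 1) - 1e-12) ++ev;
  if (ev < nev && t >= events(ev, 0) - 1e-12) return events(ev, 2);
  return 0.0;
}

// Core forward-Euler loop. Writes linearly interpolated states at out_t into
// out (row-major, n_out x 8). Optionally tracks the running max of one state
// (peak_idx >= 0) over every grid point. Returns the first non-finite time,
// or -1.0 on success.
static double euler_core(const double* p, const NumericVector& y0,
                         const NumericMatrix& events, double h, double t_end,
                         const double* out_t, int n_out, double* out,
                         bool floor_at_zero, int peak_idx, double* peak) {
  double y[8], yn[8], dy[8];
  for (int j = 0; j < 8; ++j) y[j] = y0[j];

  const long nsteps = (long)std::llround(t_end / h);
  int ev = 0, oi = 0;

  // outputs at (or numerically before) t = 0
  while (oi < n_out && out_t[oi] <= 1e-12) {
    for (int j = 0; j < 8; ++j) out[oi * 8 + j] = y[j];
    ++oi;
  }
  if (peak_idx >= 0) *peak = y[peak_idx];

  for (long i = 0; i < nsteps; ++i) {
    const double t = i * h;
    const double vin = ingestion_rate(events, t, ev);
    model_rhs(p, y, vin, dy);
    bool ok = true;
    for (int j = 0; j < 8; ++j) {
      yn[j] = y[j] + h * dy[j];
      if (floor_at_zero && yn[j] < 0.0) yn[j] = 0.0;
      if (!R_finite(yn[j])) ok = false;
    }
    if (!ok) return t + h;
    const double t1 = (i + 1) * h;
    while (oi < n_out && out_t[oi] <= t1 + 1e-12) {
      const double w = (out_t[oi] - t) / h;
      for (int j = 0; j < 8; ++j)
        out[oi * 8 + j] = y[j] * (1.0 - w) + yn[j] * w;
      ++oi;
    }
    for (int j = 0; j < 8; ++j) y[j] = yn[j];
    if (peak_idx >= 0 && y[peak_idx] > *peak) *peak = y[peak_idx];
  }
  // any requested times beyond the last grid point (within rounding)
  while (oi < n_out) {
    for (int j = 0; j < 8; ++j) out[oi * 8 + j] = y[j];
    ++oi;
  }
  return -1.0;
}

// [[Rcpp::export]]
NumericMatrix cpp_euler_traj(NumericVector p, NumericVector y0,
                             NumericMatrix events, double h, double t_end,
                             NumericVector out_times, bool floor_at_zero) {
  const int n_out = out_times.size();
  std::vector<double> buf((size_t)n_out * 8);
  double pk;
  const double bad = euler_core(REAL(p), y0, events, h, t_end,
                                REAL(out_times), n_out, buf.data(),
                                floor_at_zero, -1, &pk);
  if (bad >= 0.0)
    stop("non-finite state during Euler integration at t = %f min", bad);
  NumericMatrix out(n_out, 8);
  for (int i = 0; i < n_out; ++i)
    for (int j = 0; j < 8; ++j) out(i, j) = buf[(size_t)i * 8 + j];
  return out;
}

// [[Rcpp::export]]
double cpp_peak(NumericVector p, NumericVector y0, NumericMatrix events,
                double h, double t_end, int state_idx, bool floor_at_zero) {
  double pk;
  const double bad = euler_core(REAL(p), y0, events, h, t_end, nullptr, 0,
                                nullptr, floor_at_zero, state_idx, &pk);
  if (bad >= 0.0)
    stop("non-finite state during Euler integration at t = %f min", bad);
  return pk;
}

// Peak of one state for a batch of ingestion patterns (rows of U, grams per
// slot; each nonzero slot becomes one event of `event_duration` min).
// [[Rcpp::export]]
NumericVector cpp_peak_patterns(NumericVector p, NumericVector y0,
                                IntegerMatrix U, NumericVector slot_times,
                                double event_duration, double h, double t_end,
                                int state_idx, bool floor_at_zero) {
  const int m = U.nrow(), k = U.ncol();
  NumericVector out(m);
  for (int r = 0; r < m; ++r) {
    int nev = 0;
    for (int s = 0; s < k; ++s)
      if (U(r, s) > 0) ++nev;
    NumericMatrix events(nev, 3);
    int e = 0;
    for (int s = 0; s < k; ++s) {
      if (U(r, s) > 0) {
        events(e, 0) = slot_times[s];
        events(e, 1) = slot_times[s] + event_duration;
        events(e, 2) = U(r, s) / event_duration;
        ++e;
      }
    }
    double pk;
    const double bad = euler_core(REAL(p), y0, events, h, t_end, nullptr, 0,
                                  nullptr, floor_at_zero, state_idx, &pk);
    out[r] = (bad >= 0.0) ? R_PosInf : pk;
  }
  return out;
}

// Min-max-normalized RSS for a batch of candidate parameter sets.
// P: m x 24 closed parameter rows; Y0: m x 8 initial states.
// conds: list of conditions, each a list(events = 3-col matrix,
//   times = output times, obs = 4-col matrix [state_idx0, time_idx0,
//   value, inv_range2]).
// A candidate whose integration goes non-finite scores +Inf.
// [[Rcpp::export]]
NumericVector cpp_rss_batch(NumericMatrix P, NumericMatrix Y0, List conds,
                            double h, bool floor_at_zero) {
  const int m = P.nrow(), nc = conds.size();

  std::vector<NumericMatrix> evs(nc), obs(nc);
  std::vector<NumericVector> tms(nc);
  std::vector<double> tend(nc);
  for (int c = 0; c < nc; ++c) {
    List cd = conds[c];
    evs[c] = as<NumericMatrix>(cd["events"]);
    tms[c] = as<NumericVector>(cd["times"]);
    obs[c] = as<NumericMatrix>(cd["obs"]);
    double te = 0.0;
    for (int i = 0; i < tms[c].size(); ++i)
      if (tms[c][i] > te) te = tms[c][i];
    const NumericMatrix& E = evs[c];
    for (int i = 0; i < E.nrow(); ++i)
      if (E(i, 1) > te) te = E(i, 1);
    tend[c] = te;
  }

  NumericVector out(m);
  std::vector<double> prow(24), y0(8);
  for (int r = 0; r < m; ++r) {
    for (int j = 0; j < 24; ++j) prow[j] = P(r, j);
    NumericVector y0v(8);
    for (int j = 0; j < 8; ++j) y0v[j] = Y0(r, j);
    double rss = 0.0;
    bool ok = true;
    for (int c = 0; c < nc && ok; ++c) {
      const int nt = tms[c].size();
      std::vector<double> sim((size_t)nt * 8);
      double pk;
      const double bad = euler_core(prow.data(), y0v, evs[c], h, tend[c],
                                    REAL(tms[c]), nt, sim.data(),
                                    floor_at_zero, -1, &pk);
      if (bad >= 0.0) { ok = false; break; }
      const NumericMatrix& O = obs[c];
      for (int i = 0; i < O.nrow(); ++i) {
        const int sj = (int)O(i, 0), ti = (int)O(i, 1);
        const double d = sim[(size_t)ti * 8 + sj] - O(i, 2);
        rss += d * d * O(i, 3);
      }
    }
    out[r] = ok ? rss : R_PosInf;
  }
  return out;
}
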