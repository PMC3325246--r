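// Core synchronous threshold-network iteration.
//
// Discrete case: states live on {-1,+1}^N or {0,1}^N, the update is
// x(t+1) = sigma(W x(t)) with sigma the sign/step function, and the
// attractor (fixed point or limit cycle) is detected exactly by hashing
// every visited state and reporting transient/period at the first revisit.
//
// Continuous case: sigma is a logistic sigmoid with steepness a; a fixed
// point is declared when the max-norm step change stays below eps for a
// window of consecutive steps, and cycles are detected by recurrence (within
// eps) of checkpoint states stored at powers of two (Brent-style), which
// bounds memory while still reporting a period.

#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <cmath>

using namespace Rcpp;

// zero-input conventions for the discrete step
enum ZeroConv { ZERO_MINUS = 0, ZERO_PLUS = 1, ZERO_KEEP = 2, ZERO_QUENCHED = 3 };

// outcome codes shared with the R side
enum Outcome { OUT_FIXED = 0, OUT_CYCLE = 1, OUT_UNRESOLVED = 2 };

static inline std::string encode_state(const std::vector<int>& x, int on) {
  std::string key(x.size(), '0');
  for (size_t i = 0; i < x.size(); ++i) key[i] = (x[i] == on) ? '1' : '0';
  return key;
}

// one synchronous discrete update; on/off are the map's two values
static void step_discrete(const NumericMatrix& W, const std::vector<int>& x,
                          std::vector<int>& out, int on, int off,
                          int zero_conv, const IntegerVector& tie_on) {
  const int n = W.nrow();
  for (int i = 0; i < n; ++i) {
    double h = 0.0;
    for (int j = 0; j < n; ++j) h += W(i, j) * x[j];
    if (h > 0) out[i] = on;
    else if (h < 0) out[i] = off;
    else {
      switch (zero_conv) {
      case ZERO_PLUS: out[i] = on; break;
      case ZERO_MINUS: out[i] = off; break;
      case ZERO_KEEP: out[i] = x[i]; break;
      default: out[i] = (tie_on[i] > 0) ? on : off;
      }
    }
  }
}

// [[Rcpp::export]]
IntegerVector cpp_step_discrete(NumericMatrix W, IntegerVector x,
                                int on, int off, int zero_conv,
                                IntegerVector tie_on) {
  const int n = W.nrow();
  std::vector<int> xi(x.begin(), x.end()), xo(n);
  step_discrete(W, xi, xo, on, off, zero_conv, tie_on);
  return IntegerVector(xo.begin(), xo.end());
}

// Iterate to the attractor, hashing visited states. Exact whenever
// t_max >= transient + period; otherwise outcome = unresolved.
// [[Rcpp::export]]
List cpp_iterate_discrete(NumericMatrix W, IntegerVector x0,
                          int on, int off, int zero_conv,
                          IntegerVector tie_on, int t_max,
                          bool keep_attractor) {
  const int n = W.nrow();
  std::vector<int> x(x0.begin(), x0.end()), xn(n);
  std::unordered_map<std::string, int> seen;
  std::vector<std::string> trace;
  seen.reserve(std::min(t_max + 1, 1 << 20));

  int transient = -1, period = -1, outcome = OUT_UNRESOLVED, steps = 0;
  std::string key = encode_state(x, on);
  seen.emplace(key, 0);
  trace.push_back(key);

  for (int t = 1; t <= t_max; ++t) {
    step_discrete(W, x, xn, on, off, zero_conv, tie_on);
    x.swap(xn);
    steps = t;
    key = encode_state(x, on);
    auto it = seen.find(key);
    if (it != seen.end()) {
      transient = it->second;
      period = t - it->second;
      outcome = (period == 1) ? OUT_FIXED : OUT_CYCLE;
      break;
    }
    seen.emplace(key, t);
    trace.push_back(key);
  }

  List res = List::create(
    _["outcome"] = outcome, _["period"] = period,
    _["transient"] = transient, _["steps_run"] = steps);

  if (keep_attractor && outcome != OUT_UNRESOLVED) {
    IntegerMatrix att(period, n);
    for (int p = 0; p < period; ++p) {
      const std::string& s = trace[transient + p];
      for (int i = 0; i < n; ++i) att(p, i) = (s[i] == '1') ? on : off;
    }
    res["attractor"] = att;
  }
  return res;
}

static inline double sigma_cont(double h, double a, bool pm1) {
  // pm1 uses tanh(a h / 2) == 2 / (1 + exp(-a h)) - 1: same function, but
  // free of the cancellation that rounds tiny inputs to exactly zero
  if (pm1) return std::tanh(0.5 * a * h);
  return 1.0 / (1.0 + std::exp(-a * h));
}

// [[Rcpp::export]]
NumericVector cpp_step_continuous(NumericMatrix W, NumericVector x,
                                  double a, bool pm1) {
  const int n = W.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double h = 0.0;
    for (int j = 0; j < n; ++j) h += W(i, j) * x[j];
    out[i] = sigma_cont(h, a, pm1);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_iterate_continuous(NumericMatrix W, NumericVector x0,
                            double a, bool pm1, int t_max,
                            double eps, int window) {
  const int n = W.nrow();
  std::vector<double> x(x0.begin(), x0.end()), xn(n);
  std::vector<double> cp(x);      // checkpoint state (Brent-style)
  int cp_time = 0, next_cp = 1;   // next power-of-two checkpoint time
  int quiet = 0;                  // consecutive steps with small change

  int outcome = OUT_UNRESOLVED, period = -1, transient = -1, steps = 0;

  for (int t = 1; t <= t_max; ++t) {
    double delta = 0.0;
    for (int i = 0; i < n; ++i) {
      double h = 0.0;
      for (int j = 0; j < n; ++j) h += W(i, j) * x[j];
      xn[i] = sigma_cont(h, a, pm1);
      double d = std::fabs(xn[i] - x[i]);
      if (d > delta) delta = d;
    }
    x.swap(xn);
    steps = t;

    quiet = (delta < eps) ? quiet + 1 : 0;
    if (quiet >= window) {
      outcome = OUT_FIXED; period = 1;
      transient = t - window; if (transient < 0) transient = 0;
      break;
    }

    double dcp = 0.0;
    for (int i = 0; i < n; ++i) {
      double d = std::fabs(x[i] - cp[i]);
      if (d > dcp) dcp = d;
    }
    // recurrence of a checkpoint state; quiescent steps (delta < eps) are
    // left to the windowed fixed-point test so a convergent tail is not
    // misread as a short cycle
    if (dcp < eps && delta >= eps && t - cp_time >= 2) {
      outcome = OUT_CYCLE; period = t - cp_time; transient = cp_time;
      break;
    }
    if (t == next_cp) { cp = x; cp_time = t; next_cp *= 2; }
  }

  return List::create(
    _["outcome"] = outcome, _["period"] = period,
    _["transient"] = transient, _["steps_run"] = steps,
    _["state"] = NumericVector(x.begin(), x.end()));
}
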