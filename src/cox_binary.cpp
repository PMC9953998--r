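// Binary-covariate Cox partial likelihood: Newton fit, Jeffreys (Firth)
// penalization, exhaustive cut-point scan and permutation null engine.
//
// The whole machinery is scalar in beta, so every derivative of the partial
// log-likelihood is available in closed form.  With Efron tie handling each
// event block of size d contributes d terms log(A_j e^b + B_j) with
//   A_j = r1 - (j/d) d1,  B_j = r0 - (j/d) d0,   j = 0..d-1,
// where (r1, r0) are the at-risk counts and (d1, d0) the event counts of the
// high/low groups.  Writing u = A e^b / (A e^b + B):
//   l'    = s1 - sum u
//   l''   = -sum u(1-u)
//   l'''  = -sum u(1-u)(1-2u)
//   l'''' = -sum u(1-u)(1-6u+6u^2)
// which gives the Firth score l' + l'''/(2 l'') and the penalized observed
// information exactly, no numerical differentiation anywhere.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct TieBlock {
  int first_at_risk;  // index (sorted order) of first subject with time >= t
  int d;              // events at this time
  std::vector<int> event_idx;  // sorted-order indices of the events
};

// Risk-set structure of one dataset, independent of the group indicator.
struct CoxData {
  int n;
  std::vector<double> time;   // ascending
  std::vector<int> event;     // aligned
  std::vector<TieBlock> blocks;
  int n_events;
};

CoxData prepare(const NumericVector& time, const IntegerVector& event,
                std::vector<int>& order_out) {
  const int n = time.size();
  order_out.resize(n);
  for (int i = 0; i < n; ++i) order_out[i] = i;
  std::stable_sort(order_out.begin(), order_out.end(),
                   [&](int a, int b) { return time[a] < time[b]; });
  CoxData d;
  d.n = n;
  d.time.resize(n);
  d.event.resize(n);
  d.n_events = 0;
  for (int i = 0; i < n; ++i) {
    d.time[i] = time[order_out[i]];
    d.event[i] = event[order_out[i]];
    d.n_events += d.event[i];
  }
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && d.time[j] == d.time[i]) ++j;
    TieBlock b;
    b.first_at_risk = i;
    b.d = 0;
    for (int k2 = i; k2 < j; ++k2)
      if (d.event[k2]) { b.event_idx.push_back(k2); ++b.d; }
    if (b.d > 0) d.blocks.push_back(b);
    i = j;
  }
  return d;
}

// Group summaries for a given 0/1 indicator x (sorted order).
struct GroupSums {
  std::vector<double> r1, d1, r, dd;  // per block
  double s1;        // sum of x over events
  int ev1, ev0;     // events per group
  int n1;           // group-1 size
};

void group_sums(const CoxData& cd, const std::vector<int>& x, GroupSums& g) {
  const int n = cd.n;
  const int nb = (int)cd.blocks.size();
  g.r1.assign(nb, 0.0); g.d1.assign(nb, 0.0);
  g.r.assign(nb, 0.0);  g.dd.assign(nb, 0.0);
  g.s1 = 0.0; g.ev1 = 0; g.ev0 = 0; g.n1 = 0;
  std::vector<double> suf(n + 1, 0.0);
  for (int i = n - 1; i >= 0; --i) suf[i] = suf[i + 1] + x[i];
  g.n1 = (int)suf[0];
  for (int b = 0; b < nb; ++b) {
    const TieBlock& tb = cd.blocks[b];
    g.r[b] = n - tb.first_at_risk;
    g.r1[b] = suf[tb.first_at_risk];
    g.dd[b] = tb.d;
    double d1 = 0.0;
    for (int idx : tb.event_idx) d1 += x[idx];
    g.d1[b] = d1;
    g.s1 += d1;
  }
  g.ev1 = (int)(g.s1 + 0.5);
  g.ev0 = cd.n_events - g.ev1;
}

struct Derivs {
  double l, l1, l2, l3, l4;
};

// All derivatives at beta; efron=false gives Breslow.
void derivs(const GroupSums& g, double beta, bool efron, Derivs& out,
            bool want_l = true) {
  const double eb = std::exp(beta);
  double l = g.s1 * beta, l1 = g.s1, l2 = 0.0, l3 = 0.0, l4 = 0.0;
  const int nb = (int)g.r.size();
  for (int b = 0; b < nb; ++b) {
    const double d = g.dd[b];
    for (int j = 0; j < (int)d; ++j) {
      const double f = efron ? (double)j / d : 0.0;
      const double A = g.r1[b] - f * g.d1[b];
      const double B = (g.r[b] - g.r1[b]) - f * (d - g.d1[b]);
      const double Ae = A * eb;
      const double den = Ae + B;
      const double u = Ae / den;
      if (want_l) l -= std::log(den);
      l1 -= u;
      const double v = u * (1.0 - u);
      l2 -= v;
      l3 -= v * (1.0 - 2.0 * u);
      l4 -= v * (1.0 - 6.0 * u + 6.0 * u * u);
    }
  }
  out.l = l; out.l1 = l1; out.l2 = l2; out.l3 = l3; out.l4 = l4;
}

struct FitResult {
  double beta, var, loglik, loglik0, lrt, chi2;
  bool used_firth, converged;
  int ev1, ev0, iter;
  bool valid;
};

const double BETA_BOUND = 15.0;
const double SCORE_TOL = 1e-8;
const int MAX_ITER = 50;

// Penalized score g = l' + l'''/(2 l'') and penalized information.
inline double firth_score(const Derivs& d) {
  return d.l1 + 0.5 * d.l3 / d.l2;
}
inline double firth_info(const Derivs& d) {
  // -d/dbeta of firth score
  return -d.l2 - 0.5 * (d.l4 * d.l2 - d.l3 * d.l3) / (d.l2 * d.l2);
}
inline double firth_loglik(const Derivs& d) {
  return d.l + 0.5 * std::log(-d.l2);
}

// Root-find the (penalized) score by Newton iteration safeguarded with a
// bracket.  The plain score is strictly decreasing (the partial likelihood
// is strictly concave once both groups are represented in a risk set), so
// a sign change over [-BETA_BOUND, BETA_BOUND] certifies a finite MLE and
// its absence certifies monotone likelihood.  Newton proposals falling
// outside the current bracket are replaced by bisection, which bounds the
// worst case without ever evaluating the log-likelihood in the loop.
struct ScoreFun {
  const GroupSums& g;
  bool efron, penalized;
  Derivs d;
  double operator()(double beta) {
    derivs(g, beta, efron, d, false);
    return penalized ? firth_score(d) : d.l1;
  }
  double dscore() const {  // derivative of the score at the last beta
    return penalized ? -firth_info(d) : d.l2;
  }
};

bool solve_score(ScoreFun& f, double& beta_out, int& iter_out) {
  double lo = -BETA_BOUND, hi = BETA_BOUND;
  double slo = f(lo);
  if (!std::isfinite(slo) || slo <= 0.0)
    return false;   // root below -BETA_BOUND (or none)
  double shi = f(hi);
  if (!std::isfinite(shi) || shi >= 0.0)
    return false;   // root above +BETA_BOUND
  double beta = 0.0;
  double sc = f(beta);
  for (int it = 1; it <= MAX_ITER * 4; ++it) {
    if (std::fabs(sc) < SCORE_TOL || hi - lo < 1e-12) {
      beta_out = beta; iter_out = it;
      return true;
    }
    if (sc > 0.0) lo = beta; else hi = beta;
    const double ds = f.dscore();
    double bnew = (ds < 0.0) ? beta - sc / ds : beta;
    if (!(bnew > lo && bnew < hi)) bnew = 0.5 * (lo + hi);
    beta = bnew;
    sc = f(beta);
  }
  beta_out = beta; iter_out = MAX_ITER * 4;  // bracket guarantees closeness
  return true;
}

bool newton_mle(const GroupSums& g, bool efron, FitResult& fr) {
  ScoreFun f{g, efron, false, Derivs()};
  double beta;
  int iter;
  if (!solve_score(f, beta, iter)) return false;
  Derivs d;
  derivs(g, beta, efron, d);
  fr.beta = beta;
  fr.var = -1.0 / d.l2;
  fr.loglik = d.l;
  fr.converged = true;
  fr.iter = iter;
  return true;
}

bool newton_firth(const GroupSums& g, bool efron, FitResult& fr) {
  ScoreFun f{g, efron, true, Derivs()};
  double beta;
  int iter;
  if (!solve_score(f, beta, iter)) return false;
  Derivs d;
  derivs(g, beta, efron, d);
  fr.beta = beta;
  fr.var = 1.0 / firth_info(d);
  fr.loglik = firth_loglik(d);
  fr.converged = true;
  fr.iter = iter;
  return true;
}

// Fit with the automatic Firth fallback (firth: 0 = auto, 1 = force,
// 2 = never).  Returns valid=false only when no finite fit exists.
FitResult fit_binary(const CoxData& cd, const GroupSums& g, bool efron,
                     int firth) {
  FitResult fr;
  fr.valid = false; fr.used_firth = false; fr.converged = false;
  fr.ev1 = g.ev1; fr.ev0 = g.ev0; fr.iter = 0;
  fr.beta = NA_REAL; fr.var = NA_REAL; fr.loglik = NA_REAL;
  fr.loglik0 = NA_REAL; fr.lrt = NA_REAL; fr.chi2 = NA_REAL;
  if (cd.n_events == 0 || g.n1 == 0 || g.n1 == cd.n) return fr;

  Derivs d0;
  derivs(g, 0.0, efron, d0);
  // zero observed information: the indicator never varies within any
  // event's risk set (e.g. a minority group censored before every event);
  // no hazard ratio is estimable, penalized or not
  if (!(d0.l2 < -1e-12)) return fr;

  bool want_firth = (firth == 1) || (firth == 0 && (g.ev1 == 0 || g.ev0 == 0));
  if (!want_firth) {
    if (newton_mle(g, efron, fr)) {
      fr.valid = true;
      fr.loglik0 = d0.l;
      fr.lrt = 2.0 * (fr.loglik - fr.loglik0);
      fr.chi2 = fr.beta * fr.beta / fr.var;
      return fr;
    }
    if (firth == 2) return fr;  // caller asked for no fallback
  }
  if (firth == 2 && !want_firth) return fr;
  if (newton_firth(g, efron, fr)) {
    fr.valid = true;
    fr.used_firth = true;
    fr.loglik0 = firth_loglik(d0);
    fr.lrt = 2.0 * (fr.loglik - fr.loglik0);
    if (fr.lrt < 0.0) fr.lrt = 0.0;
    fr.chi2 = fr.beta * fr.beta / fr.var;
    return fr;
  }
  return fr;
}

// Candidate cut-points: distinct marker values whose "> c" split leaves both
// groups with >= min_group_size subjects.
std::vector<double> candidates(const std::vector<double>& marker_sorted_vals,
                               int n, int mgs) {
  std::vector<double> out;
  const int m = (int)marker_sorted_vals.size();
  // marker_sorted_vals is the full sorted vector (with duplicates)
  int i = 0;
  while (i < m) {
    int j = i;
    while (j < m && marker_sorted_vals[j] == marker_sorted_vals[i]) ++j;
    const double c = marker_sorted_vals[i];
    const int n_below = j;          // values <= c
    const int n_above = n - j;      // values > c
    if (n_below >= mgs && n_above >= mgs) out.push_back(c);
    i = j;
  }
  return out;
}

struct ScanOut {
  std::vector<double> cutoffs, chi2, beta, var, lrt;
  std::vector<int> used_firth, n1;
  int best;  // index into cutoffs, -1 if none
};

void scan(const CoxData& cd, const std::vector<double>& marker_sorted,
          int mgs, bool efron, ScanOut& out) {
  std::vector<double> mv(marker_sorted);
  std::sort(mv.begin(), mv.end());
  out.cutoffs = candidates(mv, cd.n, mgs);
  const int m = (int)out.cutoffs.size();
  out.chi2.assign(m, NA_REAL); out.beta.assign(m, NA_REAL);
  out.var.assign(m, NA_REAL);  out.lrt.assign(m, NA_REAL);
  out.used_firth.assign(m, 0); out.n1.assign(m, 0);
  out.best = -1;
  double best_chi2 = -1.0;
  std::vector<int> x(cd.n);
  GroupSums g;
  for (int c = 0; c < m; ++c) {
    const double cut = out.cutoffs[c];
    for (int i = 0; i < cd.n; ++i) x[i] = marker_sorted[i] > cut ? 1 : 0;
    group_sums(cd, x, g);
    FitResult fr = fit_binary(cd, g, efron, 0);
    if (!fr.valid) continue;
    out.chi2[c] = fr.chi2; out.beta[c] = fr.beta; out.var[c] = fr.var;
    out.lrt[c] = fr.lrt; out.used_firth[c] = fr.used_firth ? 1 : 0;
    out.n1[c] = g.n1;
    if (fr.chi2 > best_chi2 + 1e-12) {  // ties keep the smallest cut-off
      best_chi2 = fr.chi2;
      out.best = c;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List cox_fit_binary_cpp(NumericVector time, IntegerVector event,
                        IntegerVector x, bool efron, int firth) {
  std::vector<int> ord;
  CoxData cd = prepare(time, event, ord);
  std::vector<int> xs(cd.n);
  for (int i = 0; i < cd.n; ++i) xs[i] = x[ord[i]];
  GroupSums g;
  group_sums(cd, xs, g);
  FitResult fr = fit_binary(cd, g, efron, firth);
  return List::create(
      _["ln_hr"] = fr.beta, _["variance"] = fr.var,
      _["loglik"] = fr.loglik, _["loglik0"] = fr.loglik0,
      _["lrt"] = fr.lrt, _["chi2"] = fr.chi2,
      _["used_firth"] = fr.used_firth, _["converged"] = fr.converged,
      _["valid"] = fr.valid, _["n_events_high"] = fr.ev1,
      _["n_events_low"] = fr.ev0, _["iterations"] = fr.iter);
}

// [[Rcpp::export]]
List scan_cutoffs_cpp(NumericVector time, IntegerVector event,
                      NumericVector marker, int min_group_size, bool efron) {
  std::vector<int> ord;
  CoxData cd = prepare(time, event, ord);
  std::vector<double> ms(cd.n);
  for (int i = 0; i < cd.n; ++i) ms[i] = marker[ord[i]];
  ScanOut so;
  scan(cd, ms, min_group_size, efron, so);
  return List::create(
      _["cutoffs"] = wrap(so.cutoffs), _["chi2"] = wrap(so.chi2),
      _["ln_hr"] = wrap(so.beta), _["variance"] = wrap(so.var),
      _["lrt"] = wrap(so.lrt), _["used_firth"] = wrap(so.used_firth),
      _["n_high"] = wrap(so.n1), _["best_index"] = so.best + 1);
}

// Permutation null for the maximally selected Wald chi-square: each
// replicate couples a uniform random permutation of the marker against the
// fixed (time, event) pairs and re-runs the full scan.  Uses R's RNG.
// [[Rcpp::export]]
NumericVector perm_max_chi2_cpp(NumericVector time, IntegerVector event,
                                NumericVector marker, int k,
                                int min_group_size, bool efron) {
  std::vector<int> ord;
  CoxData cd = prepare(time, event, ord);
  const int n = cd.n;
  std::vector<double> ms(n);
  for (int i = 0; i < n; ++i) ms[i] = marker[ord[i]];
  NumericVector out(k);
  std::vector<double> mp(n);
  ScanOut so;
  for (int rep = 0; rep < k; ++rep) {
    mp = ms;
    for (int i = n - 1; i > 0; --i) {  // Fisher-Yates with R's RNG
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(mp[i], mp[j]);
    }
    scan(cd, mp, min_group_size, efron, so);
    out[rep] = (so.best >= 0) ? so.chi2[so.best] : 0.0;
  }
  return out;
}
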