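// Likelihood kernel for the two-compartment population model.
//
// Per subject: closed-form concentration prediction (zero-order infusion /
// first-order absorption, steady-state accumulation), the joint negative
// log density of observations and random effects, an inner Newton search
// for the empirical-Bayes eta mode, and the Laplace (FOCE-style, with
// interaction) contribution to the -2 log marginal likelihood.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

struct Dose {
  double time, amt, tinf, ii;
  int route; // 0 = iv infusion, 1 = extravascular (oral/nasogastric)
  int ss;
};

struct Subject {
  std::vector<double> t, y;
  std::vector<Dose> doses;
  std::vector<std::vector<double> > X; // n_obs rows, p covariate columns
};

struct Params {
  double cl_tv, vc, vp, q, ka, f;
  std::vector<double> beta;
  double omega[3]; // SDs for eta_cl, eta_vc, eta_vp (0 = fixed at 0)
  double prop, add;
};

static const double LOG2PI = 1.8378770664093454836;

static double conc_one(double tobs, const std::vector<Dose>& doses,
                       double cl, double vc, double vp, double q,
                       double ka, double f) {
  double k10 = cl / vc, k12 = q / vc, k21 = q / vp;
  double s = k10 + k12 + k21, p = k10 * k21;
  double disc = s * s - 4.0 * p;
  disc = disc > 0 ? std::sqrt(disc) : 0.0;
  double al = (s + disc) / 2.0;
  double be = p / al;
  double out = 0.0;
  // a steady-state record stands for the whole established regimen:
  // it resets the system, superseding all earlier dose events
  double last_ss = -1e300;
  for (size_t d = 0; d < doses.size(); ++d)
    if (doses[d].ss == 1 && doses[d].time <= tobs && doses[d].time > last_ss)
      last_ss = doses[d].time;
  for (size_t d = 0; d < doses.size(); ++d) {
    const Dose& ds = doses[d];
    double tau = tobs - ds.time;
    if (tau < 0 || ds.time < last_ss) continue;
    bool ss = ds.ss == 1;
    if (ss) tau -= ds.ii * std::floor(tau / ds.ii); // tau mod ii
    if (ds.route == 0) {
      double r0 = ds.amt / ds.tinf;
      double co[2] = { (al - k21) / (al - be), (k21 - be) / (al - be) };
      double lam[2] = { al, be };
      for (int i = 0; i < 2; ++i) {
        double l = lam[i];
        double cterm = r0 * co[i] / (vc * l);
        double einf = 1.0 - std::exp(-l * ds.tinf);
        if (ss) {
          double eii = std::exp(-l * ds.ii);
          double acc = eii / (1.0 - eii);
          if (tau <= ds.tinf)
            out += cterm * ((1.0 - std::exp(-l * tau)) +
                            einf * std::exp(-l * (tau - ds.tinf)) * acc);
          else
            out += cterm * einf * std::exp(-l * (tau - ds.tinf)) / (1.0 - eii);
        } else {
          if (tau <= ds.tinf)
            out += cterm * (1.0 - std::exp(-l * tau));
          else
            out += cterm * einf * std::exp(-l * (tau - ds.tinf));
        }
      }
    } else {
      double kaa = ka;
      if (std::fabs(kaa - al) < 1e-9 * al) kaa *= 1.0 + 1e-7;
      if (std::fabs(kaa - be) < 1e-9 * be) kaa *= 1.0 + 1e-7;
      double co[3] = { (k21 - al) / ((kaa - al) * (be - al)),
                       (k21 - be) / ((kaa - be) * (al - be)),
                       (k21 - kaa) / ((al - kaa) * (be - kaa)) };
      double lam[3] = { al, be, kaa };
      double scale = f * ds.amt * kaa / vc;
      for (int i = 0; i < 3; ++i) {
        double acc = ss ? 1.0 / (1.0 - std::exp(-lam[i] * ds.ii)) : 1.0;
        out += scale * co[i] * std::exp(-lam[i] * tau) * acc;
      }
    }
  }
  return out > 0 ? out : 0.0;
}

// predictions for all observations of one subject at a given eta
static void predict_subject(const Subject& s, const Params& p,
                            const double eta[3], std::vector<double>& f) {
  double vc = p.vc * std::exp(eta[1]);
  double vp = p.vp * std::exp(eta[2]);
  size_t n = s.t.size();
  f.resize(n);
  for (size_t j = 0; j < n; ++j) {
    double lcl = std::log(p.cl_tv) + eta[0];
    for (size_t k = 0; k < p.beta.size(); ++k)
      lcl += p.beta[k] * s.X[j][k];
    f[j] = conc_one(s.t[j], s.doses, std::exp(lcl), vc, vp, p.q, p.ka, p.f);
  }
}

// joint negative log density of (y, eta); interaction: residual variance
// evaluated at the conditional prediction
static double subj_nll(const Subject& s, const Params& p, const double eta[3]) {
  std::vector<double> f;
  predict_subject(s, p, eta, f);
  double nll = 0.0;
  for (size_t j = 0; j < f.size(); ++j) {
    double g = f[j] * p.prop * f[j] * p.prop + p.add * p.add;
    if (!(g > 0) || !R_finite(f[j])) return R_PosInf;
    double r = s.y[j] - f[j];
    nll += 0.5 * (std::log(g) + LOG2PI + r * r / g);
  }
  for (int d = 0; d < 3; ++d) {
    if (p.omega[d] > 0) {
      double w2 = p.omega[d] * p.omega[d];
      nll += 0.5 * (std::log(w2) + LOG2PI + eta[d] * eta[d] / w2);
    }
  }
  return nll;
}

// numeric gradient and Hessian over active eta dimensions
static void num_derivs(const Subject& s, const Params& p, const double eta[3],
                       const std::vector<int>& act, double h,
                       std::vector<double>& g,
                       std::vector<std::vector<double> >& H) {
  int d = (int)act.size();
  g.assign(d, 0.0);
  H.assign(d, std::vector<double>(d, 0.0));
  double f0 = subj_nll(s, p, eta);
  double e[3];
  for (int a = 0; a < d; ++a) {
    std::copy(eta, eta + 3, e);
    e[act[a]] = eta[act[a]] + h;
    double fp = subj_nll(s, p, e);
    e[act[a]] = eta[act[a]] - h;
    double fm = subj_nll(s, p, e);
    g[a] = (fp - fm) / (2.0 * h);
    H[a][a] = (fp - 2.0 * f0 + fm) / (h * h);
  }
  for (int a = 0; a < d; ++a)
    for (int b = a + 1; b < d; ++b) {
      std::copy(eta, eta + 3, e);
      e[act[a]] += h; e[act[b]] += h;
      double fpp = subj_nll(s, p, e);
      std::copy(eta, eta + 3, e);
      e[act[a]] += h; e[act[b]] -= h;
      double fpm = subj_nll(s, p, e);
      std::copy(eta, eta + 3, e);
      e[act[a]] -= h; e[act[b]] += h;
      double fmp = subj_nll(s, p, e);
      std::copy(eta, eta + 3, e);
      e[act[a]] -= h; e[act[b]] -= h;
      double fmm = subj_nll(s, p, e);
      H[a][b] = H[b][a] = (fpp - fpm - fmp + fmm) / (4.0 * h * h);
    }
}

// Cholesky of a small matrix with ridge fallback; returns log-determinant,
// or solves L L' x = -g when solve = true.
static bool chol_small(std::vector<std::vector<double> > A, int d,
                       std::vector<std::vector<double> >& L) {
  L.assign(d, std::vector<double>(d, 0.0));
  for (int i = 0; i < d; ++i) {
    for (int j = 0; j <= i; ++j) {
      double sum = A[i][j];
      for (int k = 0; k < j; ++k) sum -= L[i][k] * L[j][k];
      if (i == j) {
        if (sum <= 0) return false;
        L[i][i] = std::sqrt(sum);
      } else {
        L[i][j] = sum / L[j][j];
      }
    }
  }
  return true;
}

static void chol_solve(const std::vector<std::vector<double> >& L, int d,
                       const std::vector<double>& b, std::vector<double>& x) {
  std::vector<double> ytmp(d);
  for (int i = 0; i < d; ++i) {
    double sum = b[i];
    for (int k = 0; k < i; ++k) sum -= L[i][k] * ytmp[k];
    ytmp[i] = sum / L[i][i];
  }
  x.assign(d, 0.0);
  for (int i = d - 1; i >= 0; --i) {
    double sum = ytmp[i];
    for (int k = i + 1; k < d; ++k) sum -= L[k][i] * x[k];
    x[i] = sum / L[i][i];
  }
}

// inner Newton search for the EB mode; returns nll at the mode
static double eb_mode(const Subject& s, const Params& p, double eta[3],
                      const std::vector<int>& act) {
  int d = (int)act.size();
  double cur = subj_nll(s, p, eta);
  if (d == 0) return cur;
  std::vector<double> g, step;
  std::vector<std::vector<double> > H, L;
  const double h = 1e-4;
  for (int it = 0; it < 60; ++it) {
    num_derivs(s, p, eta, act, h, g, H);
    double gmax = 0;
    for (int a = 0; a < d; ++a) gmax = std::max(gmax, std::fabs(g[a]));
    if (gmax < 1e-7) break;
    // ridge until positive definite
    double ridge = 0.0;
    std::vector<std::vector<double> > Hr = H;
    while (!chol_small(Hr, d, L)) {
      ridge = ridge == 0.0 ? 1e-4 : ridge * 10.0;
      Hr = H;
      for (int a = 0; a < d; ++a) Hr[a][a] += ridge;
      if (ridge > 1e8) break;
    }
    std::vector<double> nb(d);
    for (int a = 0; a < d; ++a) nb[a] = -g[a];
    chol_solve(L, d, nb, step);
    // backtracking line search
    double alpha = 1.0;
    double e[3];
    bool moved = false;
    for (int ls = 0; ls < 25; ++ls) {
      std::copy(eta, eta + 3, e);
      for (int a = 0; a < d; ++a) e[act[a]] += alpha * step[a];
      double nl = subj_nll(s, p, e);
      if (nl < cur - 1e-12) {
        std::copy(e, e + 3, eta);
        cur = nl;
        moved = true;
        break;
      }
      alpha *= 0.5;
    }
    if (!moved) break;
  }
  return cur;
}

static Params unpack_params(const List& pars) {
  Params p;
  p.cl_tv = as<double>(pars["cl_tv"]);
  p.vc = as<double>(pars["vc"]);
  p.vp = as<double>(pars["vp"]);
  p.q = as<double>(pars["q"]);
  p.ka = as<double>(pars["ka"]);
  p.f = as<double>(pars["f"]);
  NumericVector b = pars["beta"];
  p.beta.assign(b.begin(), b.end());
  NumericVector om = pars["omega"];
  for (int i = 0; i < 3; ++i) p.omega[i] = om[i];
  p.prop = as<double>(pars["prop"]);
  p.add = as<double>(pars["add"]);
  return p;
}

static std::vector<Subject> unpack_subjects(const List& subjects) {
  int n = subjects.size();
  std::vector<Subject> out(n);
  for (int i = 0; i < n; ++i) {
    List si = subjects[i];
    NumericVector t = si["t"], y = si["y"];
    out[i].t.assign(t.begin(), t.end());
    out[i].y.assign(y.begin(), y.end());
    NumericMatrix D = si["doses"]; // cols: time amt route tinf ss ii
    for (int r = 0; r < D.nrow(); ++r) {
      Dose ds;
      ds.time = D(r, 0); ds.amt = D(r, 1); ds.route = (int)D(r, 2);
      ds.tinf = D(r, 3); ds.ss = (int)D(r, 4); ds.ii = D(r, 5);
      out[i].doses.push_back(ds);
    }
    NumericMatrix X = si["X"];
    out[i].X.assign(X.nrow(), std::vector<double>(X.ncol()));
    for (int r = 0; r < X.nrow(); ++r)
      for (int c = 0; c < X.ncol(); ++c)
        out[i].X[r][c] = X(r, c);
  }
  return out;
}

// [[Rcpp::export(name = ".ofv_kernel")]]
List ofv_kernel(List subjects, List pars, NumericMatrix eta_start) {
  std::vector<Subject> subs = unpack_subjects(subjects);
  Params p = unpack_params(pars);
  int n = (int)subs.size();
  std::vector<int> act;
  for (int d = 0; d < 3; ++d) if (p.omega[d] > 0) act.push_back(d);
  int da = (int)act.size();

  NumericMatrix etas(n, 3);
  NumericVector ofv_i(n);
  double total = 0.0;
  bool ok = true;
  for (int i = 0; i < n; ++i) {
    double eta[3] = {0, 0, 0};
    if (eta_start.nrow() == n)
      for (int d = 0; d < 3; ++d) eta[d] = eta_start(i, d);
    for (int d = 0; d < 3; ++d) if (p.omega[d] <= 0) eta[d] = 0;
    if (subs[i].t.empty()) {
      // no observations: prior mode, no data contribution
      for (int d = 0; d < 3; ++d) etas(i, d) = 0.0;
      ofv_i[i] = 0.0;
      continue;
    }
    double nll = eb_mode(subs[i], p, eta, act);
    double contrib;
    if (da == 0) {
      contrib = 2.0 * nll; // exact fixed-effects -2LL
    } else {
      std::vector<double> g;
      std::vector<std::vector<double> > H, L;
      num_derivs(subs[i], p, eta, act, 1e-4, g, H);
      double ridge = 0.0;
      std::vector<std::vector<double> > Hr = H;
      while (!chol_small(Hr, da, L)) {
        ridge = ridge == 0.0 ? 1e-8 : ridge * 10.0;
        Hr = H;
        for (int a = 0; a < da; ++a) Hr[a][a] += ridge;
        if (ridge > 1e8) { ok = false; break; }
      }
      double logdet = 0.0;
      for (int a = 0; a < da; ++a) logdet += 2.0 * std::log(L[a][a]);
      contrib = 2.0 * nll - da * LOG2PI + logdet;
    }
    if (!R_finite(contrib)) ok = false;
    ofv_i[i] = contrib;
    total += contrib;
    for (int d = 0; d < 3; ++d) etas(i, d) = eta[d];
  }
  return List::create(_["ofv"] = total, _["ofv_i"] = ofv_i,
                      _["etas"] = etas, _["ok"] = ok);
}

// [[Rcpp::export(name = ".predict_kernel")]]
List predict_kernel(List subjects, List pars, NumericMatrix etas) {
  std::vector<Subject> subs = unpack_subjects(subjects);
  Params p = unpack_params(pars);
  int n = (int)subs.size();
  List out(n);
  for (int i = 0; i < n; ++i) {
    double eta[3] = {0, 0, 0};
    if (etas.nrow() == n)
      for (int d = 0; d < 3; ++d) eta[d] = etas(i, d);
    std::vector<double> f;
    predict_subject(subs[i], p, eta, f);
    out[i] = NumericVector(f.begin(), f.end());
  }
  return out;
}

// [[Rcpp::export(name = ".nll_kernel")]]
double nll_kernel(List subject, List pars, NumericVector eta) {
  List wrap = List::create(subject);
  std::vector<Subject> subs = unpack_subjects(wrap);
  Params p = unpack_params(pars);
  double e[3] = { eta[0], eta[1], eta[2] };
  return subj_nll(subs[0], p, e);
}
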