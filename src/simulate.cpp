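// Inner loop of the Langevin splitting integrators with on-the-fly
// accumulation of the Girsanov log-weight increments.  Mirrors the pure-R
// reference engine in R/integrators.R step for step and draws its noise from
// R's RNG stream so that set.seed() reproduces both engines identically.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>

using namespace Rcpp;

namespace {

struct Term {
  int kind;  // 1 harmonic, 2 double_well, 3 mueller_brown, 4 linear_x, 5 poly_x
  double scale;
  std::vector<double> par;
};

std::vector<Term> parse_terms(const List& terms) {
  std::vector<Term> out;
  for (R_xlen_t i = 0; i < terms.size(); ++i) {
    List t = terms[i];
    Term tm;
    std::string k = as<std::string>(t["kind"]);
    if (k == "harmonic") tm.kind = 1;
    else if (k == "double_well") tm.kind = 2;
    else if (k == "mueller_brown") tm.kind = 3;
    else if (k == "linear_x") tm.kind = 4;
    else if (k == "poly_x") tm.kind = 5;
    else stop("unknown potential term kind: " + k);
    tm.scale = as<double>(t["scale"]);
    tm.par = as<std::vector<double> >(t["par"]);
    out.push_back(tm);
  }
  return out;
}

// Adds scale * gradient into g (if g != null), returns scale * energy.
double eval_term(const Term& t, const double* q, int nd, double* g) {
  switch (t.kind) {
  case 1: {  // harmonic: par = stiffness per dof
    double e = 0.0;
    for (int l = 0; l < nd; ++l) {
      e += 0.5 * t.par[l] * q[l] * q[l];
      if (g) g[l] += t.scale * t.par[l] * q[l];
    }
    return t.scale * e;
  }
  case 2: {  // double well: par = (height, q_min), acts on dof 0
    const double h = t.par[0], q0 = t.par[1];
    const double q04 = q0 * q0 * q0 * q0;
    const double u = q[0] * q[0] - q0 * q0;
    if (g) g[0] += t.scale * 4.0 * h * q[0] * u / q04;
    return t.scale * h * u * u / q04;
  }
  case 3: {  // Mueller-Brown: par = A[4], a[4], b[4], c[4], x0[4], y0[4]
    const double* A = &t.par[0];
    const double* a = &t.par[4];
    const double* b = &t.par[8];
    const double* c = &t.par[12];
    const double* x0 = &t.par[16];
    const double* y0 = &t.par[20];
    double e = 0.0, gx = 0.0, gy = 0.0;
    for (int n = 0; n < 4; ++n) {
      const double dx = q[0] - x0[n], dy = q[1] - y0[n];
      const double en = A[n] * std::exp(a[n] * dx * dx + b[n] * dx * dy +
                                        c[n] * dy * dy);
      e += en;
      gx += en * (2.0 * a[n] * dx + b[n] * dy);
      gy += en * (b[n] * dx + 2.0 * c[n] * dy);
    }
    if (g) { g[0] += t.scale * gx; g[1] += t.scale * gy; }
    return t.scale * e;
  }
  case 4: {  // linear along x: par = (k, ndim)
    if (g) g[0] += t.scale * t.par[0];
    return t.scale * t.par[0] * q[0];
  }
  case 5: {  // polynomial along x: par = (k, a_1..a_m), Horner
    const double k = t.par[0];
    const int m = static_cast<int>(t.par.size()) - 1;
    const double x = q[0];
    double s = 0.0, ds = 0.0;
    for (int i = m; i >= 1; --i) s = t.par[i] + x * s;
    for (int i = m; i >= 1; --i) ds = i * t.par[i] + x * ds;
    if (g) g[0] += t.scale * k * ds;
    return t.scale * k * x * s;
  }
  }
  return 0.0;
}

struct Potential {
  std::vector<Term> terms;
  double energy_grad(const double* q, int nd, double* g) const {
    if (g) for (int l = 0; l < nd; ++l) g[l] = 0.0;
    double e = 0.0;
    for (size_t i = 0; i < terms.size(); ++i)
      e += eval_term(terms[i], q, nd, g);
    return e;
  }
};

enum SchemeId { S_NONE = 0, S_ABO, S_ABOBA, S_AOBOA, S_BOAOB, S_OBABO };

SchemeId scheme_id(const std::string& canonical) {
  if (canonical == "ABO") return S_ABO;
  if (canonical == "ABOBA") return S_ABOBA;
  if (canonical == "AOBOA") return S_AOBOA;
  if (canonical == "BOAOB") return S_BOAOB;
  if (canonical == "OBABO") return S_OBABO;
  return S_NONE;
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".simulate_core")]]
List simulate_core(NumericVector q0, NumericVector p0,
                   CharacterVector letters, LogicalVector half,
                   std::string canonical,
                   NumericVector masses, double dt, double xi, double rt,
                   int n_steps, int n_out,
                   List v_terms_r, List u_terms_r, bool has_u,
                   bool record_noise, double blow_bound) {
  const int nd = q0.size();
  const int n_ops = letters.size();
  const int n_frames = n_steps / n_out + 1;

  Potential V; V.terms = parse_terms(v_terms_r);
  Potential U; U.terms = parse_terms(u_terms_r);

  const double d_full = std::exp(-xi * dt);
  const double d_half = std::exp(-xi * dt * 0.5);
  std::vector<double> f_full(nd), f_half(nd), a_full(nd), a_half(nd);
  for (int l = 0; l < nd; ++l) {
    f_full[l] = std::sqrt(rt * masses[l] * (1.0 - d_full * d_full));
    f_half[l] = std::sqrt(rt * masses[l] * (1.0 - d_half * d_half));
    a_full[l] = dt / masses[l];
    a_half[l] = dt / (2.0 * masses[l]);
  }

  std::vector<int> op(n_ops);
  int n_noise = 0;
  for (int i = 0; i < n_ops; ++i) {
    std::string s = as<std::string>(letters[i]);
    op[i] = (s == "A") ? 0 : (s == "B") ? 1 : 2;
    if (op[i] == 2) ++n_noise;
  }
  const SchemeId sid = scheme_id(canonical);
  if (has_u && sid == S_NONE)
    stop("path reweighting is undefined for this splitting scheme");

  std::vector<double> q(q0.begin(), q0.end());
  std::vector<double> p(p0.begin(), p0.end());
  std::vector<double> q_pre(nd), q_mid(nd), fcur(nd), grad(nd), gU(nd),
      gU_pre(nd);
  std::vector<double> eta(static_cast<size_t>(std::max(n_noise, 1)) * nd);

  NumericMatrix Q(n_frames, nd), P(n_frames, nd);
  NumericVector dS(n_frames), Uq(n_frames), time_ps(n_frames);
  NumericMatrix E1, E2;
  if (record_noise) {
    E1 = NumericMatrix(n_steps, nd);
    if (n_noise > 1) E2 = NumericMatrix(n_steps, nd);
  }

  for (int l = 0; l < nd; ++l) { Q(0, l) = q[l]; P(0, l) = p[l]; }
  dS[0] = 0.0;
  Uq[0] = has_u ? U.energy_grad(&q[0], nd, 0) : 0.0;
  time_ps[0] = 0.0;

  double buffer = 0.0;
  RNGScope rng_scope;

  for (int k = 0; k < n_steps; ++k) {
    if (k % 100000 == 0) Rcpp::checkUserInterrupt();
    for (int l = 0; l < nd; ++l) q_pre[l] = q[l];
    const bool need_pre = has_u && (sid == S_BOAOB || sid == S_OBABO);
    if (need_pre) U.energy_grad(&q[0], nd, &gU_pre[0]);

    bool have_force = false;
    bool have_mid = false;
    int i_noise = 0;
    for (int i = 0; i < n_ops; ++i) {
      const bool h = half[i];
      switch (op[i]) {
      case 0: {  // A: position drift
        for (int l = 0; l < nd; ++l)
          q[l] += (h ? a_half[l] : a_full[l]) * p[l];
        have_force = false;
        if (!have_mid) {
          for (int l = 0; l < nd; ++l) q_mid[l] = q[l];
          have_mid = true;
        }
        break;
      }
      case 1: {  // B: force kick with the full simulation-potential force
        if (!have_force) {
          V.energy_grad(&q[0], nd, &grad[0]);
          for (int l = 0; l < nd; ++l) fcur[l] = -grad[l];
          have_force = true;
        }
        const double w = h ? dt * 0.5 : dt;
        for (int l = 0; l < nd; ++l) p[l] += w * fcur[l];
        break;
      }
      case 2: {  // O: Ornstein-Uhlenbeck friction + noise
        const double dd = h ? d_half : d_full;
        double* e = &eta[static_cast<size_t>(i_noise) * nd];
        for (int l = 0; l < nd; ++l) {
          e[l] = norm_rand();
          p[l] = dd * p[l] + (h ? f_half[l] : f_full[l]) * e[l];
        }
        ++i_noise;
        break;
      }
      }
    }

    if (record_noise) {
      for (int l = 0; l < nd; ++l) E1(k, l) = eta[l];
      if (n_noise > 1)
        for (int l = 0; l < nd; ++l) E2(k, l) = eta[nd + l];
    }

    if (has_u) {
      double s = 0.0;
      switch (sid) {
      case S_ABO: {  // perturbation force after position update
        U.energy_grad(&q[0], nd, &gU[0]);
        for (int l = 0; l < nd; ++l) {
          const double de = d_full * dt * gU[l] / f_full[l];
          s += eta[l] * de + 0.5 * de * de;
        }
        break;
      }
      case S_ABOBA: {  // at the intermediate (midpoint) position
        U.energy_grad(&q_mid[0], nd, &gU[0]);
        for (int l = 0; l < nd; ++l) {
          const double de = (1.0 + d_full) * dt * gU[l] / (2.0 * f_full[l]);
          s += eta[l] * de + 0.5 * de * de;
        }
        break;
      }
      case S_AOBOA: {  // combined channel eta_comb = d' eta1 + eta2
        U.energy_grad(&q_mid[0], nd, &gU[0]);
        const double var = 1.0 + d_half * d_half;
        for (int l = 0; l < nd; ++l) {
          const double de = d_half * dt * gU[l] / f_half[l];
          const double comb = d_half * eta[l] + eta[nd + l];
          s += (comb * de + 0.5 * de * de) / var;
        }
        break;
      }
      case S_BOAOB: {  // channel 1 before, channel 2 after position update
        U.energy_grad(&q[0], nd, &gU[0]);
        for (int l = 0; l < nd; ++l) {
          const double de1 = d_half * dt * gU_pre[l] / (2.0 * f_half[l]);
          const double de2 = dt * gU[l] / (2.0 * f_half[l]);
          s += eta[l] * de1 + 0.5 * de1 * de1;
          s += eta[nd + l] * de2 + 0.5 * de2 * de2;
        }
        break;
      }
      case S_OBABO: {
        U.energy_grad(&q[0], nd, &gU[0]);
        for (int l = 0; l < nd; ++l) {
          const double de1 = dt * gU_pre[l] / (2.0 * f_half[l]);
          const double de2 = d_half * dt * gU[l] / (2.0 * f_half[l]);
          s += eta[l] * de1 + 0.5 * de1 * de1;
          s += eta[nd + l] * de2 + 0.5 * de2 * de2;
        }
        break;
      }
      default: break;
      }
      buffer += s;
    }

    for (int l = 0; l < nd; ++l) {
      if (!std::isfinite(q[l]) || !std::isfinite(p[l]) ||
          std::fabs(q[l]) > blow_bound)
        stop("simulation blow-up at step %d (|q| or energy not finite)",
             k + 1);
    }

    if ((k + 1) % n_out == 0) {
      const int fr = (k + 1) / n_out;
      for (int l = 0; l < nd; ++l) { Q(fr, l) = q[l]; P(fr, l) = p[l]; }
      dS[fr] = buffer;
      buffer = 0.0;
      Uq[fr] = has_u ? U.energy_grad(&q[0], nd, 0) : 0.0;
      time_ps[fr] = (k + 1) * dt;
    }
  }

  List out = List::create(_["q"] = Q, _["p"] = P, _["dS"] = dS,
                          _["U_q"] = Uq, _["time_ps"] = time_ps);
  if (record_noise) {
    out["eta1"] = E1;
    if (n_noise > 1) out["eta2"] = E2;
  }
  return out;
}
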