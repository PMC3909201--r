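// Coarse-grained Go-model core: energies/forces and Langevin propagation.
// Reduced units throughout (k_B = 1, epsilon = energy unit, Angstrom).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Topo {
  int n;
  std::vector<double> r0, theta0, phi0;      // bonded reference geometry
  std::vector<int> ci, cj;                   // native contacts (0-based)
  std::vector<double> cr0, cw;               // contact r0 and MJ weight
  std::vector<int> fi, fj;                   // frustration pairs
  std::vector<int> ri, rj;                   // repulsion pairs
};

Topo unpack_topo(const List& t) {
  Topo o;
  o.n = as<int>(t["n"]);
  o.r0 = as<std::vector<double>>(t["r0"]);
  o.theta0 = as<std::vector<double>>(t["theta0"]);
  o.phi0 = as<std::vector<double>>(t["phi0"]);
  IntegerVector ci = t["ci"], cj = t["cj"], fi = t["fi"], fj = t["fj"],
                ri = t["ri"], rj = t["rj"];
  for (int k = 0; k < ci.size(); ++k) { o.ci.push_back(ci[k] - 1); o.cj.push_back(cj[k] - 1); }
  for (int k = 0; k < fi.size(); ++k) { o.fi.push_back(fi[k] - 1); o.fj.push_back(fj[k] - 1); }
  for (int k = 0; k < ri.size(); ++k) { o.ri.push_back(ri[k] - 1); o.rj.push_back(rj[k] - 1); }
  o.cr0 = as<std::vector<double>>(t["cr0"]);
  o.cw = as<std::vector<double>>(t["cw"]);
  return o;
}

struct Params {
  double eps, k_bond, k_angle, k_dih1, k_dih3, sigma_rep, eps_f, c_f;
  bool contact_12_10;
};

Params unpack_params(const List& p) {
  Params o;
  o.eps = as<double>(p["epsilon"]);
  o.k_bond = as<double>(p["k_bond"]);
  o.k_angle = as<double>(p["k_angle"]);
  o.k_dih1 = as<double>(p["k_dih1"]);
  o.k_dih3 = as<double>(p["k_dih3"]);
  o.sigma_rep = as<double>(p["sigma_rep"]);
  o.eps_f = as<double>(p["eps_f"]);
  o.c_f = as<double>(p["c_f"]);
  o.contact_12_10 = as<std::string>(p["contact_form"]) == "12-10";
  return o;
}

inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// terms bitmask: 1 bond, 2 angle, 4 dihedral, 8 contact, 16 repulsion, 32 frustration
void energy_forces(const std::vector<double>& x, const Topo& t,
                   const Params& p, int terms,
                   double* e_out, std::vector<double>& f) {
  const int n = t.n;
  std::fill(f.begin(), f.end(), 0.0);
  for (int k = 0; k < 6; ++k) e_out[k] = 0.0;

  // bonds: K (r - r0)^2
  if (terms & 1) {
    for (int i = 0; i < n - 1; ++i) {
      double d[3] = {x[3*(i+1)] - x[3*i], x[3*(i+1)+1] - x[3*i+1],
                     x[3*(i+1)+2] - x[3*i+2]};
      double r = std::sqrt(dot3(d, d));
      if (r <= 0) stop("numeric error: zero bond length");
      double dr = r - t.r0[i];
      e_out[0] += p.k_bond * dr * dr;
      double coef = 2.0 * p.k_bond * dr / r;  // dV/dr / r
      for (int c = 0; c < 3; ++c) {
        f[3*i+c]     += coef * d[c];
        f[3*(i+1)+c] -= coef * d[c];
      }
    }
  }

  // angles: K (theta - theta0)^2
  if (terms & 2) {
    for (int i = 0; i < n - 2; ++i) {
      const double *p1 = &x[3*i], *p2 = &x[3*(i+1)], *p3 = &x[3*(i+2)];
      double u[3] = {p1[0]-p2[0], p1[1]-p2[1], p1[2]-p2[2]};
      double v[3] = {p3[0]-p2[0], p3[1]-p2[1], p3[2]-p2[2]};
      double lu = std::sqrt(dot3(u, u)), lv = std::sqrt(dot3(v, v));
      double cth = dot3(u, v) / (lu * lv);
      cth = std::max(-1.0, std::min(1.0, cth));
      double th = std::acos(cth);
      double sth = std::sqrt(std::max(1e-12, 1.0 - cth * cth));
      double dth = th - t.theta0[i];
      e_out[1] += p.k_angle * dth * dth;
      double dEdth = 2.0 * p.k_angle * dth;
      // dtheta/dx1 = (cth*uhat - vhat) / (lu*sth); analogous for x3
      for (int c = 0; c < 3; ++c) {
        double uh = u[c] / lu, vh = v[c] / lv;
        double g1 = (cth * uh - vh) / (lu * sth);
        double g3 = (cth * vh - uh) / (lv * sth);
        f[3*i+c]     -= dEdth * g1;
        f[3*(i+2)+c] -= dEdth * g3;
        f[3*(i+1)+c] += dEdth * (g1 + g3);
      }
    }
  }

  // dihedrals: K1[1-cos(phi-phi0)] + K3[1-cos 3(phi-phi0)]
  if (terms & 4) {
    for (int i = 0; i < n - 3; ++i) {
      const double *x1 = &x[3*i], *x2 = &x[3*(i+1)],
                   *x3 = &x[3*(i+2)], *x4 = &x[3*(i+3)];
      double b1[3] = {x2[0]-x1[0], x2[1]-x1[1], x2[2]-x1[2]};
      double b2[3] = {x3[0]-x2[0], x3[1]-x2[1], x3[2]-x2[2]};
      double b3[3] = {x4[0]-x3[0], x4[1]-x3[1], x4[2]-x3[2]};
      double n1[3], n2[3], m1[3];
      cross3(b1, b2, n1);
      cross3(b2, b3, n2);
      double lb2 = std::sqrt(dot3(b2, b2));
      cross3(n1, b2, m1);
      double phi = std::atan2(dot3(m1, n2) / lb2, dot3(n1, n2));
      double dphi = phi - t.phi0[i];
      e_out[2] += p.k_dih1 * (1.0 - std::cos(dphi)) +
                  p.k_dih3 * (1.0 - std::cos(3.0 * dphi));
      double dEdphi = p.k_dih1 * std::sin(dphi) +
                      3.0 * p.k_dih3 * std::sin(3.0 * dphi);
      double n1sq = dot3(n1, n1), n2sq = dot3(n2, n2);
      if (n1sq < 1e-12 || n2sq < 1e-12) continue;  // collinear: force undefined, torque ~ 0
      double g1[3], g4[3];
      for (int c = 0; c < 3; ++c) {
        g1[c] =  lb2 / n1sq * n1[c];
        g4[c] = -lb2 / n2sq * n2[c];
      }
      double a12 = dot3(b1, b2) / (lb2 * lb2);
      double a32 = dot3(b3, b2) / (lb2 * lb2);
      for (int c = 0; c < 3; ++c) {
        double g2 = -(1.0 + a12) * g1[c] + a32 * g4[c];
        double g3 = a12 * g1[c] - (1.0 + a32) * g4[c];
        f[3*i+c]     -= dEdphi * g1[c];
        f[3*(i+1)+c] -= dEdphi * g2;
        f[3*(i+2)+c] -= dEdphi * g3;
        f[3*(i+3)+c] -= dEdphi * g4[c];
      }
    }
  }

  // native contacts: Lennard-Jones well, depth w*eps, minimum at r0
  if (terms & 8) {
    for (size_t k = 0; k < t.ci.size(); ++k) {
      int i = t.ci[k], j = t.cj[k];
      double d[3] = {x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2]};
      double r2 = dot3(d, d);
      if (r2 <= 0) stop("numeric error: coincident contact beads");
      double r = std::sqrt(r2);
      double s2 = (t.cr0[k] * t.cr0[k]) / r2;
      double s6 = s2 * s2 * s2;
      double w = t.cw[k] * p.eps;
      double e, dVdr;
      if (p.contact_12_10) {
        double s10 = s6 * s2 * s2, s12 = s6 * s6;
        e = w * (5.0 * s12 - 6.0 * s10);
        dVdr = -60.0 * w * (s12 - s10) / r;
      } else {
        double s12 = s6 * s6;
        e = w * (s12 - 2.0 * s6);
        dVdr = -12.0 * w * (s12 - s6) / r;
      }
      e_out[3] += e;
      double coef = -dVdr / r;  // force on i along +d
      for (int c = 0; c < 3; ++c) { f[3*i+c] += coef * d[c]; f[3*j+c] -= coef * d[c]; }
    }
  }

  // repulsion: eps (sigma/r)^12 over non-bonded non-native (non-frustration) pairs
  if (terms & 16) {
    double s0 = p.sigma_rep;
    for (size_t k = 0; k < t.ri.size(); ++k) {
      int i = t.ri[k], j = t.rj[k];
      double d[3] = {x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2]};
      double r2 = dot3(d, d);
      if (r2 <= 0) stop("numeric error: coincident beads");
      double s2 = (s0 * s0) / r2;
      double s12 = s2 * s2 * s2; s12 *= s12;
      e_out[4] += p.eps * s12;
      double coef = 12.0 * p.eps * s12 / r2;  // -dV/dr / r
      for (int c = 0; c < 3; ++c) { f[3*i+c] += coef * d[c]; f[3*j+c] -= coef * d[c]; }
    }
  }

  // frustration: eps_f [ (c_f/r)^12 - 2 (c_f/r)^6 ], minimum -eps_f at c_f
  if (terms & 32) {
    for (size_t k = 0; k < t.fi.size(); ++k) {
      int i = t.fi[k], j = t.fj[k];
      double d[3] = {x[3*i] - x[3*j], x[3*i+1] - x[3*j+1], x[3*i+2] - x[3*j+2]};
      double r2 = dot3(d, d);
      if (r2 <= 0) stop("numeric error: coincident beads");
      double s2 = (p.c_f * p.c_f) / r2;
      double s6 = s2 * s2 * s2, s12 = s6 * s6;
      e_out[5] += p.eps_f * (s12 - 2.0 * s6);
      double coef = 12.0 * p.eps_f * (s12 - s6) / r2;
      for (int c = 0; c < 3; ++c) { f[3*i+c] += coef * d[c]; f[3*j+c] -= coef * d[c]; }
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List cg_energy_forces_cpp(NumericMatrix x, List topo, List params,
                          int terms = 63) {
  Topo t = unpack_topo(topo);
  Params p = unpack_params(params);
  if (x.nrow() != t.n || x.ncol() != 3) stop("x must be n x 3");
  std::vector<double> xv(3 * t.n), f(3 * t.n);
  for (int i = 0; i < t.n; ++i)
    for (int c = 0; c < 3; ++c) {
      if (!std::isfinite(x(i, c))) stop("numeric error: non-finite coordinates");
      xv[3*i+c] = x(i, c);
    }
  double e[6];
  energy_forces(xv, t, p, terms, e, f);
  NumericMatrix fo(t.n, 3);
  for (int i = 0; i < t.n; ++i)
    for (int c = 0; c < 3; ++c) fo(i, c) = f[3*i+c];
  NumericVector ev = NumericVector::create(
      _["bond"] = e[0], _["angle"] = e[1], _["dihedral"] = e[2],
      _["native_contact"] = e[3], _["repulsion"] = e[4],
      _["frustration"] = e[5]);
  return List::create(_["energy"] = ev, _["forces"] = fo);
}

// BAOAB Langevin propagation with thinned snapshot recording.
// Returns final phase-space state plus per-snapshot step, Q, kept flags
// and coordinates.  Uses R's RNG (seed via set.seed before the call).
// [[Rcpp::export]]
List cg_run_cpp(NumericMatrix x0, NumericMatrix v0, List topo, List params,
                double dt, double gamma, double temperature, double mass,
                double n_steps, int stride, double step_offset,
                double kept_lambda, int terms = 63) {
  Topo t = unpack_topo(topo);
  Params p = unpack_params(params);
  const int n = t.n, m = (int)t.ci.size();
  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) { x[3*i+c] = x0(i, c); v[3*i+c] = v0(i, c); }
  double e[6];
  energy_forces(x, t, p, terms, e, f);

  const double half = 0.5 * dt;
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(temperature * (1.0 - c1 * c1) / mass);
  const long long N = (long long)(n_steps + 0.5);
  const int S = (int)(N / stride);
  IntegerVector snap_step_lo(S), qv(S);
  NumericVector snap_t(S), coords((R_xlen_t)S * n * 3);
  LogicalMatrix kept(S, m);
  std::vector<double> xold(3 * n);

  int s_idx = 0;
  for (long long step = 0; step < N; ++step) {
    std::copy(x.begin(), x.end(), xold.begin());
    for (int k = 0; k < 3 * n; ++k) {
      v[k] += half * f[k] / mass;
      x[k] += half * v[k];
    }
    for (int k = 0; k < 3 * n; ++k)
      v[k] = c1 * v[k] + c2 * norm_rand();
    for (int k = 0; k < 3 * n; ++k) x[k] += half * v[k];
    energy_forces(x, t, p, terms, e, f);
    for (int k = 0; k < 3 * n; ++k) v[k] += half * f[k] / mass;

    for (int i = 0; i < n; ++i) {
      double dx = x[3*i] - xold[3*i], dy = x[3*i+1] - xold[3*i+1],
             dz = x[3*i+2] - xold[3*i+2];
      if (dx * dx + dy * dy + dz * dz > 1.0)
        stop("instability error: bead displacement > 1 A in one step; use a smaller dt");
    }

    if ((step + 1) % stride == 0) {
      int q = 0;
      for (int k = 0; k < m; ++k) {
        int i = t.ci[k], j = t.cj[k];
        double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1],
               dz = x[3*i+2] - x[3*j+2];
        bool ok = std::sqrt(dx * dx + dy * dy + dz * dz) <=
                  kept_lambda * t.cr0[k];
        kept(s_idx, k) = ok;
        if (ok) ++q;
      }
      qv[s_idx] = q;
      snap_step_lo[s_idx] = (int)((step_offset + step + 1) / stride);
      snap_t[s_idx] = temperature;
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < 3; ++c)
          coords[(R_xlen_t)s_idx + (R_xlen_t)S * (i + (R_xlen_t)n * c)] =
              x[3*i+c];
      ++s_idx;
    }
    if (step % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix xf(n, 3), vf(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) { xf(i, c) = x[3*i+c]; vf(i, c) = v[3*i+c]; }
  coords.attr("dim") = IntegerVector::create(S, n, 3);
  return List::create(_["x"] = xf, _["v"] = vf,
                      _["snap_index"] = snap_step_lo, _["temperature"] = snap_t,
                      _["q"] = qv, _["kept"] = kept, _["coords"] = coords);
}

// 1-D double-well Langevin sampler.  Piecewise quartic, C1 at the barrier
// top x = 0: left well V = h (x^2-1)^2 (minimum 0 at x = -1); right
// ("native") well V = (h+d) ((x/w)^2-1)^2 - d (minimum -d at x = w).
// Counts per-step occupancy of the right well (x > 0).
static inline double dw_force(double x, double h, double d, double w) {
  if (x <= 0.0) return -4.0 * h * x * (x * x - 1.0);
  double xw = x / w;
  return -4.0 * (h + d) * xw * (xw * xw - 1.0) / w;
}

// [[Rcpp::export]]
List dw_run_cpp(double x0, double v0, double h, double d, double w,
                double dt, double gamma, double temperature, double mass,
                double n_steps) {
  const double half = 0.5 * dt;
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(temperature * (1.0 - c1 * c1) / mass);
  double x = x0, v = v0;
  double fx = dw_force(x, h, d, w);
  const long long N = (long long)(n_steps + 0.5);
  long long n_right = 0;
  for (long long step = 0; step < N; ++step) {
    v += half * fx / mass;
    x += half * v;
    v = c1 * v + c2 * norm_rand();
    x += half * v;
    fx = dw_force(x, h, d, w);
    v += half * fx / mass;
    if (x > 0) ++n_right;
    if (step % 1000000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["x"] = x, _["v"] = v,
                      _["n_right"] = (double)n_right, _["n_total"] = (double)N);
}
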