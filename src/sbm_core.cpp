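// Coarse-grained dual-basin SBM: energy, analytic forces, Langevin (BAOAB)
// leapfrog propagation. Reduced units throughout: energy in eps (1 kJ/mol),
// length nm, mass 1, k_B = 0.008314 per reduced kelvin.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double KB_REDUCED = 0.008314;

struct Vec3 {
  double x, y, z;
};
static inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
}
static inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

struct Topo {
  // bonded (0-based indices)
  std::vector<int> b_i, b_j;
  std::vector<double> b_r0;
  double k_r;
  std::vector<int> a_i, a_j, a_k;
  std::vector<double> a_t0;
  double k_theta;
  std::vector<int> d_i, d_j, d_k, d_l;
  std::vector<double> d_p0;
  double k_phi1, k_phi3;
  // dual-Gaussian common contacts
  std::vector<int> g_i, g_j;
  std::vector<double> g_r1, g_r2;
  double eps_dg, sigma_nc, gauss_width;
  // state-specific 10-12 contacts (per-contact strength)
  std::vector<int> so_i, so_j;
  std::vector<double> so_sig, so_eps;
  std::vector<int> sc_i, sc_j;
  std::vector<double> sc_sig, sc_eps;
  // excluded volume pair list
  std::vector<int> e_i, e_j;
  double eps_ev, ev_cutoff;
};

static std::vector<int> col_int(const NumericMatrix &m, int c) {
  std::vector<int> v(m.nrow());
  for (int r = 0; r < m.nrow(); ++r) v[r] = (int)m(r, c) - 1;  // to 0-based
  return v;
}
static std::vector<double> col_num(const NumericMatrix &m, int c) {
  std::vector<double> v(m.nrow());
  for (int r = 0; r < m.nrow(); ++r) v[r] = m(r, c);
  return v;
}

static Topo unpack(const List &topo) {
  Topo t;
  NumericMatrix b = topo["bonds"], a = topo["angles"], d = topo["dihedrals"];
  NumericMatrix g = topo["dg"], so = topo["spec_open"], sc = topo["spec_closed"];
  NumericMatrix e = topo["ev_pairs"];
  t.b_i = col_int(b, 0); t.b_j = col_int(b, 1); t.b_r0 = col_num(b, 2);
  t.a_i = col_int(a, 0); t.a_j = col_int(a, 1); t.a_k = col_int(a, 2);
  t.a_t0 = col_num(a, 3);
  t.d_i = col_int(d, 0); t.d_j = col_int(d, 1); t.d_k = col_int(d, 2);
  t.d_l = col_int(d, 3); t.d_p0 = col_num(d, 4);
  t.g_i = col_int(g, 0); t.g_j = col_int(g, 1);
  t.g_r1 = col_num(g, 2); t.g_r2 = col_num(g, 3);
  t.so_i = col_int(so, 0); t.so_j = col_int(so, 1);
  t.so_sig = col_num(so, 2); t.so_eps = col_num(so, 3);
  t.sc_i = col_int(sc, 0); t.sc_j = col_int(sc, 1);
  t.sc_sig = col_num(sc, 2); t.sc_eps = col_num(sc, 3);
  t.e_i = col_int(e, 0); t.e_j = col_int(e, 1);
  t.k_r = as<double>(topo["k_r"]);
  t.k_theta = as<double>(topo["k_theta"]);
  t.k_phi1 = as<double>(topo["k_phi1"]);
  t.k_phi3 = as<double>(topo["k_phi3"]);
  t.eps_dg = as<double>(topo["eps_dg"]);
  t.sigma_nc = as<double>(topo["sigma_nc"]);
  t.gauss_width = as<double>(topo["gauss_width"]);
  t.eps_ev = as<double>(topo["eps_ev"]);
  t.ev_cutoff = as<double>(topo["ev_cutoff"]);
  return t;
}

// energy components + (optionally) forces, accumulated into f
static void eval_sbm(const std::vector<Vec3> &x, const Topo &t,
                     double comp[7], std::vector<Vec3> *f) {
  for (int c = 0; c < 7; ++c) comp[c] = 0.0;
  if (f) for (size_t i = 0; i < f->size(); ++i) (*f)[i] = {0, 0, 0};

  // bonds: K_r (r - r0)^2
  for (size_t m = 0; m < t.b_i.size(); ++m) {
    Vec3 dv = sub(x[t.b_i[m]], x[t.b_j[m]]);
    double r = norm(dv);
    double dr = r - t.b_r0[m];
    comp[0] += t.k_r * dr * dr;
    if (f) {
      double c = -2.0 * t.k_r * dr / r;  // force magnitude / r on i
      (*f)[t.b_i[m]].x += c * dv.x; (*f)[t.b_i[m]].y += c * dv.y;
      (*f)[t.b_i[m]].z += c * dv.z;
      (*f)[t.b_j[m]].x -= c * dv.x; (*f)[t.b_j[m]].y -= c * dv.y;
      (*f)[t.b_j[m]].z -= c * dv.z;
    }
  }

  // angles: K_theta (theta - theta0)^2
  for (size_t m = 0; m < t.a_i.size(); ++m) {
    const Vec3 &ri = x[t.a_i[m]], &rj = x[t.a_j[m]], &rk = x[t.a_k[m]];
    Vec3 u = sub(ri, rj), v = sub(rk, rj);
    double nu = norm(u), nv = norm(v);
    double c = dot(u, v) / (nu * nv);
    if (c > 1.0) c = 1.0;
    if (c < -1.0) c = -1.0;
    double th = std::acos(c);
    double dth = th - t.a_t0[m];
    comp[1] += t.k_theta * dth * dth;
    if (f) {
      double s = std::sqrt(1.0 - c * c);
      if (s < 1e-8) s = 1e-8;
      double pref = 2.0 * t.k_theta * dth / s;  // = -dV/dtheta * (-1/s)
      // dtheta/dri = (c*u/nu - v/nv) / (s*nu) -> force = -dV/dth * dth/dri
      Vec3 gi = {(c * u.x / nu - v.x / nv) / nu,
                 (c * u.y / nu - v.y / nv) / nu,
                 (c * u.z / nu - v.z / nv) / nu};
      Vec3 gk = {(c * v.x / nv - u.x / nu) / nv,
                 (c * v.y / nv - u.y / nu) / nv,
                 (c * v.z / nv - u.z / nu) / nv};
      // force_i = -dV/dth * dth/dri with dth/dri = -gi/s -> force_i = pref*gi...
      // dc/dri = (v/nv - c*u/nu)/nu ; dth/dri = -dc/dri / s
      // force_i = -2K dth * dth/dri = -2K dth * (c*u/nu - v/nv)/(nu*s) = -pref*gi
      (*f)[t.a_i[m]].x -= pref * gi.x; (*f)[t.a_i[m]].y -= pref * gi.y;
      (*f)[t.a_i[m]].z -= pref * gi.z;
      (*f)[t.a_k[m]].x -= pref * gk.x; (*f)[t.a_k[m]].y -= pref * gk.y;
      (*f)[t.a_k[m]].z -= pref * gk.z;
      (*f)[t.a_j[m]].x += pref * (gi.x + gk.x);
      (*f)[t.a_j[m]].y += pref * (gi.y + gk.y);
      (*f)[t.a_j[m]].z += pref * (gi.z + gk.z);
    }
  }

  // dihedrals: sum_{n=1,3} K_n (1 - cos n(phi - phi0))
  for (size_t m = 0; m < t.d_i.size(); ++m) {
    const Vec3 &ri = x[t.d_i[m]], &rj = x[t.d_j[m]];
    const Vec3 &rk = x[t.d_k[m]], &rl = x[t.d_l[m]];
    Vec3 b1 = sub(rj, ri), b2 = sub(rk, rj), b3 = sub(rl, rk);
    Vec3 n1 = cross(b1, b2), n2 = cross(b2, b3);
    double nb2 = norm(b2);
    double phi = std::atan2(dot(cross(n1, n2), b2) / nb2, dot(n1, n2));
    double dphi = phi - t.d_p0[m];
    comp[2] += t.k_phi1 * (1.0 - std::cos(dphi)) +
               t.k_phi3 * (1.0 - std::cos(3.0 * dphi));
    if (f) {
      double dV = t.k_phi1 * std::sin(dphi) +
                  3.0 * t.k_phi3 * std::sin(3.0 * dphi);
      double n1sq = dot(n1, n1), n2sq = dot(n2, n2);
      if (n1sq < 1e-16) n1sq = 1e-16;
      if (n2sq < 1e-16) n2sq = 1e-16;
      Vec3 dpi = {-nb2 / n1sq * n1.x, -nb2 / n1sq * n1.y, -nb2 / n1sq * n1.z};
      Vec3 dpl = {nb2 / n2sq * n2.x, nb2 / n2sq * n2.y, nb2 / n2sq * n2.z};
      double tt = dot(b1, b2) / (nb2 * nb2);
      double ss = dot(b3, b2) / (nb2 * nb2);
      Vec3 dpj = {-(1.0 + tt) * dpi.x + ss * dpl.x,
                  -(1.0 + tt) * dpi.y + ss * dpl.y,
                  -(1.0 + tt) * dpi.z + ss * dpl.z};
      Vec3 dpk = {tt * dpi.x - (1.0 + ss) * dpl.x,
                  tt * dpi.y - (1.0 + ss) * dpl.y,
                  tt * dpi.z - (1.0 + ss) * dpl.z};
      (*f)[t.d_i[m]].x -= dV * dpi.x; (*f)[t.d_i[m]].y -= dV * dpi.y;
      (*f)[t.d_i[m]].z -= dV * dpi.z;
      (*f)[t.d_j[m]].x -= dV * dpj.x; (*f)[t.d_j[m]].y -= dV * dpj.y;
      (*f)[t.d_j[m]].z -= dV * dpj.z;
      (*f)[t.d_k[m]].x -= dV * dpk.x; (*f)[t.d_k[m]].y -= dV * dpk.y;
      (*f)[t.d_k[m]].z -= dV * dpk.z;
      (*f)[t.d_l[m]].x -= dV * dpl.x; (*f)[t.d_l[m]].y -= dV * dpl.y;
      (*f)[t.d_l[m]].z -= dV * dpl.z;
    }
  }

  // dual-Gaussian common contacts:
  // U = eps_dg * ( [1+(s/r)^12] [1+G1] [1+G2] - 1 ),  G_n = -exp(-(r-rn)^2/(2 w^2))
  double w2 = t.gauss_width * t.gauss_width;
  double snc2 = t.sigma_nc * t.sigma_nc;
  for (size_t m = 0; m < t.g_i.size(); ++m) {
    Vec3 dv = sub(x[t.g_i[m]], x[t.g_j[m]]);
    double r = norm(dv);
    double u = snc2 / (r * r), u2 = u * u;
    double core = u2 * u2 * u2;  // (sigma_nc/r)^12
    double g1 = -std::exp(-(r - t.g_r1[m]) * (r - t.g_r1[m]) / (2.0 * w2));
    double g2 = -std::exp(-(r - t.g_r2[m]) * (r - t.g_r2[m]) / (2.0 * w2));
    comp[3] += t.eps_dg * ((1.0 + core) * (1.0 + g1) * (1.0 + g2) - 1.0);
    if (f) {
      double dcore = -12.0 * core / r;
      double dg1 = -g1 * (r - t.g_r1[m]) / w2;
      double dg2 = -g2 * (r - t.g_r2[m]) / w2;
      double dU = t.eps_dg * (dcore * (1.0 + g1) * (1.0 + g2) +
                              (1.0 + core) * dg1 * (1.0 + g2) +
                              (1.0 + core) * (1.0 + g1) * dg2);
      double c = -dU / r;
      (*f)[t.g_i[m]].x += c * dv.x; (*f)[t.g_i[m]].y += c * dv.y;
      (*f)[t.g_i[m]].z += c * dv.z;
      (*f)[t.g_j[m]].x -= c * dv.x; (*f)[t.g_j[m]].y -= c * dv.y;
      (*f)[t.g_j[m]].z -= c * dv.z;
    }
  }

  // state-specific 10-12 contacts: eps * (5 (s/r)^12 - 6 (s/r)^10)
  for (int which = 0; which < 2; ++which) {
    const std::vector<int> &si = which == 0 ? t.so_i : t.sc_i;
    const std::vector<int> &sj = which == 0 ? t.so_j : t.sc_j;
    const std::vector<double> &sg = which == 0 ? t.so_sig : t.sc_sig;
    const std::vector<double> &se = which == 0 ? t.so_eps : t.sc_eps;
    for (size_t m = 0; m < si.size(); ++m) {
      Vec3 dv = sub(x[si[m]], x[sj[m]]);
      double r2 = dot(dv, dv);
      double u = sg[m] * sg[m] / r2, u2 = u * u;
      double sr10 = u2 * u2 * u;        // (sigma/r)^10
      double sr12 = u2 * u2 * u2;       // (sigma/r)^12
      comp[4 + which] += se[m] * (5.0 * sr12 - 6.0 * sr10);
      if (f) {
        double c = se[m] * 60.0 * (sr12 - sr10) / r2;
        (*f)[si[m]].x += c * dv.x; (*f)[si[m]].y += c * dv.y;
        (*f)[si[m]].z += c * dv.z;
        (*f)[sj[m]].x -= c * dv.x; (*f)[sj[m]].y -= c * dv.y;
        (*f)[sj[m]].z -= c * dv.z;
      }
    }
  }

  // excluded volume: eps_ev (sigma_nc/r)^12 on the non-contact pair list,
  // distance cutoff (term < 1e-9 eps at the default 2.5 nm cutoff)
  double cut2 = t.ev_cutoff * t.ev_cutoff;
  for (size_t m = 0; m < t.e_i.size(); ++m) {
    Vec3 dv = sub(x[t.e_i[m]], x[t.e_j[m]]);
    double r2 = dot(dv, dv);
    if (r2 > cut2) continue;
    double u = snc2 / r2, u2 = u * u;
    double sr12 = u2 * u2 * u2;
    comp[6] += t.eps_ev * sr12;
    if (f) {
      double c = 12.0 * t.eps_ev * sr12 / r2;
      (*f)[t.e_i[m]].x += c * dv.x; (*f)[t.e_i[m]].y += c * dv.y;
      (*f)[t.e_i[m]].z += c * dv.z;
      (*f)[t.e_j[m]].x -= c * dv.x; (*f)[t.e_j[m]].y -= c * dv.y;
      (*f)[t.e_j[m]].z -= c * dv.z;
    }
  }
}

static std::vector<Vec3> as_vec3(const NumericMatrix &coords) {
  std::vector<Vec3> x(coords.nrow());
  for (int i = 0; i < coords.nrow(); ++i)
    x[i] = {coords(i, 0), coords(i, 1), coords(i, 2)};
  return x;
}

// [[Rcpp::export]]
NumericVector sbm_energy_cpp(NumericMatrix coords, List topo) {
  std::vector<Vec3> x = as_vec3(coords);
  for (size_t i = 0; i < x.size(); ++i) {
    if (!std::isfinite(x[i].x) || !std::isfinite(x[i].y) ||
        !std::isfinite(x[i].z))
      stop("non-finite coordinate at bead %d", (int)i + 1);
  }
  Topo t = unpack(topo);
  double comp[7];
  eval_sbm(x, t, comp, nullptr);
  double total = 0;
  for (int c = 0; c < 7; ++c) total += comp[c];
  NumericVector out = NumericVector::create(
      _["bond"] = comp[0], _["angle"] = comp[1], _["dihedral"] = comp[2],
      _["dual_gaussian"] = comp[3], _["specific_open"] = comp[4],
      _["specific_closed"] = comp[5], _["excluded"] = comp[6],
      _["total"] = total);
  return out;
}

// [[Rcpp::export]]
NumericMatrix sbm_forces_cpp(NumericMatrix coords, List topo) {
  std::vector<Vec3> x = as_vec3(coords);
  Topo t = unpack(topo);
  double comp[7];
  std::vector<Vec3> f(x.size());
  eval_sbm(x, t, comp, &f);
  NumericMatrix out(x.size(), 3);
  for (size_t i = 0; i < x.size(); ++i) {
    out(i, 0) = f[i].x; out(i, 1) = f[i].y; out(i, 2) = f[i].z;
  }
  return out;
}

// Langevin leapfrog (BAOAB splitting). gamma = 0 and no noise reduces to
// velocity Verlet, conserving energy; gamma > 0 samples NVT at temperature T
// (reduced kelvin, k_B = 0.008314). Uses R's RNG so set.seed() governs the
// noise stream and Maxwell-Boltzmann velocity initialisation.
// [[Rcpp::export]]
List run_dynamics_cpp(NumericMatrix coords0, List topo, double dt,
                      double temperature, double gamma, double mass,
                      double n_steps_d, int save_every,
                      Nullable<NumericMatrix> vel0 = R_NilValue) {
  long long n_steps = (long long)n_steps_d;
  std::vector<Vec3> x = as_vec3(coords0);
  int n = (int)x.size();
  Topo t = unpack(topo);
  double kT = KB_REDUCED * temperature;

  std::vector<Vec3> v(n), f(n);
  if (vel0.isNotNull()) {
    NumericMatrix vm(vel0);
    for (int i = 0; i < n; ++i) v[i] = {vm(i, 0), vm(i, 1), vm(i, 2)};
  } else {
    double sd = std::sqrt(kT / mass);
    for (int i = 0; i < n; ++i)
      v[i] = {sd * norm_rand(), sd * norm_rand(), sd * norm_rand()};
    // remove centre-of-mass velocity
    Vec3 cm = {0, 0, 0};
    for (int i = 0; i < n; ++i) {
      cm.x += v[i].x; cm.y += v[i].y; cm.z += v[i].z;
    }
    for (int i = 0; i < n; ++i) {
      v[i].x -= cm.x / n; v[i].y -= cm.y / n; v[i].z -= cm.z / n;
    }
  }

  double a = std::exp(-gamma * dt);
  double b = (gamma > 0) ? std::sqrt(kT / mass * (1.0 - a * a)) : 0.0;

  long long n_frames = n_steps / save_every + 1;
  NumericMatrix xyz_out((int)n_frames, 3 * n);
  NumericMatrix elog((int)n_frames, 10);
  NumericVector steps_out((int)n_frames);

  double comp[7];
  eval_sbm(x, t, comp, &f);

  auto record = [&](long long frame, long long step) {
    for (int i = 0; i < n; ++i) {
      xyz_out((int)frame, 3 * i) = x[i].x;
      xyz_out((int)frame, 3 * i + 1) = x[i].y;
      xyz_out((int)frame, 3 * i + 2) = x[i].z;
    }
    double pot = 0;
    for (int c = 0; c < 7; ++c) {
      elog((int)frame, c) = comp[c];
      pot += comp[c];
    }
    double ke = 0;
    for (int i = 0; i < n; ++i) ke += 0.5 * mass * dot(v[i], v[i]);
    elog((int)frame, 7) = pot;
    elog((int)frame, 8) = ke;
    elog((int)frame, 9) = 2.0 * ke / (3.0 * n * KB_REDUCED);
    steps_out[(int)frame] = (double)step;
    if (!std::isfinite(pot) || std::fabs(pot) > 1e6)
      stop("energy divergence at step %g (potential = %g)", (double)step, pot);
  };
  record(0, 0);

  long long frame = 1;
  double half_dt = 0.5 * dt;
  for (long long step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i) {  // B
      v[i].x += half_dt * f[i].x / mass;
      v[i].y += half_dt * f[i].y / mass;
      v[i].z += half_dt * f[i].z / mass;
    }
    for (int i = 0; i < n; ++i) {  // A
      x[i].x += half_dt * v[i].x;
      x[i].y += half_dt * v[i].y;
      x[i].z += half_dt * v[i].z;
    }
    if (gamma > 0) {               // O
      for (int i = 0; i < n; ++i) {
        v[i].x = a * v[i].x + b * norm_rand();
        v[i].y = a * v[i].y + b * norm_rand();
        v[i].z = a * v[i].z + b * norm_rand();
      }
    }
    for (int i = 0; i < n; ++i) {  // A
      x[i].x += half_dt * v[i].x;
      x[i].y += half_dt * v[i].y;
      x[i].z += half_dt * v[i].z;
    }
    eval_sbm(x, t, comp, &f);      // force refresh
    for (int i = 0; i < n; ++i) {  // B
      v[i].x += half_dt * f[i].x / mass;
      v[i].y += half_dt * f[i].y / mass;
      v[i].z += half_dt * f[i].z / mass;
    }
    if (step % save_every == 0) {
      record(frame, step);
      ++frame;
      if (frame % 64 == 0) Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix vel_out(n, 3);
  for (int i = 0; i < n; ++i) {
    vel_out(i, 0) = v[i].x; vel_out(i, 1) = v[i].y; vel_out(i, 2) = v[i].z;
  }
  colnames(elog) = CharacterVector::create(
      "bond", "angle", "dihedral", "dual_gaussian", "specific_open",
      "specific_closed", "excluded", "potential", "kinetic", "temperature");
  return List::create(_["xyz"] = xyz_out, _["steps"] = steps_out,
                      _["energy"] = elog, _["velocities"] = vel_out);
}
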