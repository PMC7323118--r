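// Coarse-grained bead-chain kernels: Metropolis Monte Carlo for closed rings
// and for an open chain confined by a charged impenetrable core, plus a FIRE
// energy minimizer.  One bead per bending site; energies in kT (300 K),
// lengths in Angstrom.  All randomness comes from R's RNG so set.seed() on
// the R side makes every trajectory reproducible.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Bending profile: quartic (kind 0) and harmonic (kind 1) are analytic and
// extend over all angles by their formula; tabulated (kind 2) is a dense
// equispaced lookup table with linear interpolation, clamped at the ends.
struct Profile {
  int kind;
  double c2, c3, c4, Lp;
  std::vector<double> tx, ty;
  double x0, dx;

  double energy(double th) const {
    if (kind == 0) return th * th * (c2 + th * (c3 + th * c4));
    if (kind == 1) return 0.5 * Lp * th * th;
    const int n = (int)tx.size();
    if (th <= tx[0]) return ty[0];
    if (th >= tx[n - 1]) return ty[n - 1];
    double u = (th - x0) / dx;
    int i = (int)u;
    if (i > n - 2) i = n - 2;
    double f = u - i;
    return ty[i] * (1.0 - f) + ty[i + 1] * f;
  }
  double slope(double th) const {
    if (kind == 0) return th * (2.0 * c2 + th * (3.0 * c3 + 4.0 * c4 * th));
    if (kind == 1) return Lp * th;
    const int n = (int)tx.size();
    if (th <= tx[0] || th >= tx[n - 1]) return 0.0;
    double u = (th - x0) / dx;
    int i = (int)u;
    if (i > n - 2) i = n - 2;
    return (ty[i + 1] - ty[i]) / dx;
  }
};

static Profile make_profile(const List& pr) {
  Profile p;
  p.kind = as<int>(pr["kind"]);
  p.c2 = p.c3 = p.c4 = p.Lp = 0.0;
  NumericVector par = pr["params"];
  if (p.kind == 0) { p.c2 = par[0]; p.c3 = par[1]; p.c4 = par[2]; }
  else if (p.kind == 1) { p.Lp = par[0]; }
  else {
    NumericVector tx = pr["tab_x"], ty = pr["tab_y"];
    p.tx.assign(tx.begin(), tx.end());
    p.ty.assign(ty.begin(), ty.end());
    p.x0 = p.tx.front();
    p.dx = (p.tx.back() - p.tx.front()) / (p.tx.size() - 1);
  }
  return p;
}

// ---------------------------------------------------------------------------
// Geometry helpers on a flat coordinate vector x[3*i + d].
static inline double bond_len(const std::vector<double>& x, int i, int j) {
  double dx = x[3 * j] - x[3 * i], dy = x[3 * j + 1] - x[3 * i + 1],
         dz = x[3 * j + 2] - x[3 * i + 2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// Angle between segments (a->b) and (b->c); 0 = straight.
static inline double bend_angle(const std::vector<double>& x, int a, int b, int c) {
  double ux = x[3 * b] - x[3 * a], uy = x[3 * b + 1] - x[3 * a + 1],
         uz = x[3 * b + 2] - x[3 * a + 2];
  double vx = x[3 * c] - x[3 * b], vy = x[3 * c + 1] - x[3 * b + 1],
         vz = x[3 * c + 2] - x[3 * b + 2];
  double dot = ux * vx + uy * vy + uz * vz;
  double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
  double cr = std::sqrt(cx * cx + cy * cy + cz * cz);
  return std::atan2(cr, dot);
}

// [[Rcpp::export(name = ".bend_angles_cpp")]]
NumericVector bend_angles_cpp(NumericMatrix coords, bool ring) {
  int n = coords.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);
  if (ring) {
    NumericVector th(n);
    for (int i = 0; i < n; ++i) {
      int a = (i - 1 + n) % n, c = (i + 1) % n;
      if (bond_len(x, a, i) < 1e-12 || bond_len(x, i, c) < 1e-12)
        stop("degenerate geometry: zero-length bond at bead %d", i + 1);
      th[i] = bend_angle(x, a, i, c);
    }
    return th;
  }
  NumericVector th(n - 2);
  for (int i = 1; i < n - 1; ++i) {
    if (bond_len(x, i - 1, i) < 1e-12 || bond_len(x, i, i + 1) < 1e-12)
      stop("degenerate geometry: zero-length bond at bead %d", i + 1);
    th[i - 1] = bend_angle(x, i - 1, i, i + 1);
  }
  return th;
}

// ---------------------------------------------------------------------------
// Ring energetics: stiff harmonic bonds + per-site angle potential.
struct RingSystem {
  int n;
  double b0, kb;       // bond rest length (A), bond constant (kT/A^2)
  Profile prof;

  double angle_energy(const std::vector<double>& x) const {
    double e = 0.0;
    for (int i = 0; i < n; ++i)
      e += prof.energy(bend_angle(x, (i - 1 + n) % n, i, (i + 1) % n));
    return e;
  }
  double total_energy(const std::vector<double>& x) const {
    double e = angle_energy(x);
    for (int i = 0; i < n; ++i) {
      double d = bond_len(x, i, (i + 1) % n) - b0;
      e += 0.5 * kb * d * d;
    }
    return e;
  }
  // Energy terms touched by a move of bead i: two bonds, three angles.
  double local_energy(const std::vector<double>& x, int i) const {
    double e = 0.0;
    int im = (i - 1 + n) % n, ip = (i + 1) % n;
    double d1 = bond_len(x, im, i) - b0, d2 = bond_len(x, i, ip) - b0;
    e += 0.5 * kb * (d1 * d1 + d2 * d2);
    for (int j : {im, i, ip})
      e += prof.energy(bend_angle(x, (j - 1 + n) % n, j, (j + 1) % n));
    return e;
  }
};

// [[Rcpp::export(name = ".mc_ring_cpp")]]
List mc_ring_cpp(NumericMatrix coords, List profile, double beta,
                 int sweeps, double burn_frac, int thin,
                 double step0, double bond_k, double bond_b,
                 bool record_coords, int check_every) {
  RingSystem sys;
  sys.n = coords.nrow();
  sys.b0 = bond_b;
  sys.kb = bond_k;
  sys.prof = make_profile(profile);
  const int n = sys.n;

  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);

  int burn = (int)std::floor(burn_frac * sweeps);
  double step = step0;
  double e_run = sys.total_energy(x);
  double drift_max = 0.0;
  long acc = 0, att = 0;
  int tune_int = 50;
  long acc_t = 0, att_t = 0;

  int n_frames = (sweeps - burn + thin - 1) / thin;
  if (n_frames < 0) n_frames = 0;
  NumericMatrix angles(n_frames, n);
  NumericVector bendE(n_frames), totE(n_frames);
  NumericVector traj;
  if (record_coords) traj = NumericVector(n_frames * n * 3);
  int fr = 0;

  for (int s = 0; s < sweeps; ++s) {
    for (int m = 0; m < n; ++m) {
      int i = (int)(unif_rand() * n);
      if (i == n) i = n - 1;
      double old[3] = {x[3 * i], x[3 * i + 1], x[3 * i + 2]};
      double e_old = sys.local_energy(x, i);
      for (int d = 0; d < 3; ++d) x[3 * i + d] += step * norm_rand();
      double e_new = sys.local_energy(x, i);
      double dE = e_new - e_old;
      ++att; ++att_t;
      if (dE <= 0.0 || unif_rand() < std::exp(-beta * dE)) {
        e_run += dE; ++acc; ++acc_t;
      } else {
        for (int d = 0; d < 3; ++d) x[3 * i + d] = old[d];
      }
    }
    if (s < burn && (s + 1) % tune_int == 0) {
      double r = (double)acc_t / att_t;
      double f = r / 0.40;
      if (f < 0.5) f = 0.5;
      if (f > 2.0) f = 2.0;
      step *= f;
      acc_t = att_t = 0;
    }
    if ((s + 1) % check_every == 0) {
      double e_full = sys.total_energy(x);
      double d = std::fabs(e_full - e_run);
      if (d > drift_max) drift_max = d;
      e_run = e_full;
    }
    if (s >= burn && (s - burn) % thin == 0 && fr < n_frames) {
      double be = 0.0;
      for (int i = 0; i < n; ++i) {
        double th = bend_angle(x, (i - 1 + n) % n, i, (i + 1) % n);
        angles(fr, i) = th;
        be += sys.prof.energy(th);
      }
      bendE[fr] = be;
      totE[fr] = sys.total_energy(x);
      if (record_coords)
        for (int i = 0; i < n; ++i)
          for (int d = 0; d < 3; ++d)
            traj[(R_xlen_t)fr * n * 3 + 3 * i + d] = x[3 * i + d];
      ++fr;
    }
  }

  NumericMatrix fin(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) fin(i, d) = x[3 * i + d];

  return List::create(
    _["angles"] = angles, _["bend_energy"] = bendE, _["total_energy"] = totE,
    _["coords_flat"] = traj, _["n_frames"] = fr,
    _["final_coords"] = fin,
    _["acceptance"] = (double)acc / (double)att,
    _["step"] = step, _["energy_drift_max"] = drift_max);
}

// ---------------------------------------------------------------------------
// Gradient of the ring energy (bonds + angles) w.r.t. all coordinates.
static void ring_gradient(const RingSystem& sys, const std::vector<double>& x,
                          std::vector<double>& g) {
  const int n = sys.n;
  std::fill(g.begin(), g.end(), 0.0);
  for (int i = 0; i < n; ++i) {           // bonds i -> i+1
    int j = (i + 1) % n;
    double dx = x[3 * j] - x[3 * i], dy = x[3 * j + 1] - x[3 * i + 1],
           dz = x[3 * j + 2] - x[3 * i + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) continue;
    double f = sys.kb * (r - sys.b0) / r;
    g[3 * i] -= f * dx; g[3 * i + 1] -= f * dy; g[3 * i + 2] -= f * dz;
    g[3 * j] += f * dx; g[3 * j + 1] += f * dy; g[3 * j + 2] += f * dz;
  }
  for (int j = 0; j < n; ++j) {           // angle at site j
    int a = (j - 1 + n) % n, c = (j + 1) % n;
    double ux = x[3 * j] - x[3 * a], uy = x[3 * j + 1] - x[3 * a + 1],
           uz = x[3 * j + 2] - x[3 * a + 2];
    double vx = x[3 * c] - x[3 * j], vy = x[3 * c + 1] - x[3 * j + 1],
           vz = x[3 * c + 2] - x[3 * j + 2];
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (nu < 1e-12 || nv < 1e-12) continue;
    double dot = ux * vx + uy * vy + uz * vz;
    double ct = dot / (nu * nv);
    if (ct > 1.0) ct = 1.0; if (ct < -1.0) ct = -1.0;
    double th = std::acos(ct);
    double st = std::sqrt(1.0 - ct * ct);
    if (st < 1e-9) st = 1e-9;
    double dEdth = sys.prof.slope(th);
    // dE/dx = dEdth * dth/dx = -(dEdth/st) * dcos/dx
    double pref = -dEdth / st;
    double dcu[3] = {vx / (nu * nv) - ct * ux / (nu * nu),
                     vy / (nu * nv) - ct * uy / (nu * nu),
                     vz / (nu * nv) - ct * uz / (nu * nu)};
    double dcv[3] = {ux / (nu * nv) - ct * vx / (nv * nv),
                     uy / (nu * nv) - ct * vy / (nv * nv),
                     uz / (nu * nv) - ct * vz / (nv * nv)};
    for (int d = 0; d < 3; ++d) {
      g[3 * a + d] += -pref * dcu[d];                 // d u / d x_a = -I
      g[3 * j + d] += pref * (dcu[d] - dcv[d]);
      g[3 * c + d] += pref * dcv[d];
    }
  }
}

// FIRE minimizer on the ring energy; exits when the max-norm gradient falls
// below tol (kT/A).
// [[Rcpp::export(name = ".minimize_ring_cpp")]]
List minimize_ring_cpp(NumericMatrix coords, List profile,
                       double bond_k, double bond_b,
                       double tol, int max_iter) {
  RingSystem sys;
  sys.n = coords.nrow();
  sys.b0 = bond_b;
  sys.kb = bond_k;
  sys.prof = make_profile(profile);
  const int n = sys.n, m = 3 * n;

  std::vector<double> x(m), v(m, 0.0), g(m);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);

  double dt = 0.005, dt_max = 0.05, alpha = 0.1;
  const double f_inc = 1.1, f_dec = 0.5, alpha0 = 0.1, f_alpha = 0.99;
  int n_pos = 0, iter = 0;
  bool converged = false;

  ring_gradient(sys, x, g);
  for (iter = 0; iter < max_iter; ++iter) {
    double gmax = 0.0;
    for (int k = 0; k < m; ++k) gmax = std::max(gmax, std::fabs(g[k]));
    if (gmax < tol) { converged = true; break; }

    double P = 0.0, vn = 0.0, fn = 0.0;
    for (int k = 0; k < m; ++k) {
      P += -g[k] * v[k];
      vn += v[k] * v[k];
      fn += g[k] * g[k];
    }
    vn = std::sqrt(vn); fn = std::sqrt(fn);
    if (P > 0.0) {
      for (int k = 0; k < m; ++k)
        v[k] = (1.0 - alpha) * v[k] + alpha * (-g[k]) * (fn > 0 ? vn / fn : 0.0);
      if (++n_pos > 5) { dt = std::min(dt * f_inc, dt_max); alpha *= f_alpha; }
    } else {
      std::fill(v.begin(), v.end(), 0.0);
      dt *= f_dec;
      alpha = alpha0;
      n_pos = 0;
    }
    for (int k = 0; k < m; ++k) {
      v[k] += dt * (-g[k]);
      x[k] += dt * v[k];
    }
    ring_gradient(sys, x, g);
  }
  if (!converged)
    warning("FIRE minimization did not reach gradient tolerance in %d iterations",
            max_iter);

  NumericMatrix fin(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) fin(i, d) = x[3 * i + d];
  return List::create(
    _["coords"] = fin,
    _["energy"] = sys.total_energy(x),
    _["angle_energy"] = sys.angle_energy(x),
    _["converged"] = converged, _["iterations"] = iter);
}

// ---------------------------------------------------------------------------
// Confined open chain: stiff bonds, angle potential at interior sites,
// Coulomb attraction of each bead (charge qs) to a core charge Q at the
// origin, steep inverse-power exclusion from the core surface and from two
// confining walls at z = +-gap/2 (the repulsion diverges at contact and
// penetrating moves are rejected outright).  Optional bead-bead Coulomb +
// soft-core repulsion, and an outward flat-bottom restraint on a tail
// segment (used for unwrapping energetics).
struct ConfinedSystem {
  int n;
  double b0, kb;
  Profile prof;
  double qs, Q, lB, R, gap;  // gap <= 0: walls off
  int core;                  // 0 sphere, 1 cylinder (axis z)
  bool nonbonded;
  double sigma;              // soft-core diameter for bead-bead repulsion
  int n_detach;              // trailing beads pushed outside R + detach_off
  double detach_off, k_detach;

  double core_dist(const double* p) const {
    if (core == 0)
      return std::sqrt(p[0] * p[0] + p[1] * p[1] + p[2] * p[2]);
    return std::sqrt(p[0] * p[0] + p[1] * p[1]);
  }
  bool feasible(const std::vector<double>& x, int i) const {
    const double* p = &x[3 * i];
    if (core_dist(p) <= R) return false;
    if (gap > 0 && std::fabs(p[2]) >= 0.5 * gap) return false;
    return true;
  }
  double bead_field_energy(const std::vector<double>& x, int i) const {
    const double* p = &x[3 * i];
    double r = core_dist(p);
    double e = qs * Q * lB / std::max(r, 1e-6);
    double d = r - R;
    double w = 1.0;
    e += std::pow(w / d, 12);                       // core exclusion
    if (gap > 0) {
      double dz = 0.5 * gap - std::fabs(p[2]);
      e += std::pow(w / dz, 12);                    // walls
    }
    if (i >= n - n_detach) {                        // unwrapping restraint
      double rr = R + detach_off;
      if (r < rr) e += 0.5 * k_detach * (rr - r) * (rr - r);
    }
    return e;
  }
  double pair_energy(const std::vector<double>& x, int i, int j) const {
    double r = bond_len(x, i, j);
    double e = qs * qs * lB / std::max(r, 1e-6);
    if (r < sigma) {
      double u = sigma / std::max(r, 1e-3);
      double u6 = u * u * u; u6 *= u6;
      e += u6 * u6 - 1.0;
    }
    return e;
  }
  double angle_at(const std::vector<double>& x, int j) const {
    return prof.energy(bend_angle(x, j - 1, j, j + 1));
  }
  double total_energy(const std::vector<double>& x) const {
    double e = 0.0;
    for (int i = 0; i + 1 < n; ++i) {
      double d = bond_len(x, i, i + 1) - b0;
      e += 0.5 * kb * d * d;
    }
    for (int j = 1; j + 1 < n; ++j) e += angle_at(x, j);
    for (int i = 0; i < n; ++i) e += bead_field_energy(x, i);
    if (nonbonded)
      for (int i = 0; i < n; ++i)
        for (int j = i + 2; j < n; ++j) e += pair_energy(x, i, j);
    return e;
  }
  double local_energy(const std::vector<double>& x, int i) const {
    double e = bead_field_energy(x, i);
    if (i > 0) { double d = bond_len(x, i - 1, i) - b0; e += 0.5 * kb * d * d; }
    if (i + 1 < n) { double d = bond_len(x, i, i + 1) - b0; e += 0.5 * kb * d * d; }
    for (int j = i - 1; j <= i + 1; ++j)
      if (j >= 1 && j + 1 < n) e += angle_at(x, j);
    if (nonbonded)
      for (int j = 0; j < n; ++j)
        if (j < i - 1 || j > i + 1) e += pair_energy(x, i, j);
    return e;
  }
};

// [[Rcpp::export(name = ".mc_confined_cpp")]]
List mc_confined_cpp(NumericMatrix coords, List profile, double beta,
                     int sweeps, double burn_frac, int thin, double step0,
                     double bond_k, double bond_b,
                     double qs, double Q, double lB, double R, double gap,
                     int core, bool nonbonded, double sigma,
                     int n_detach, double detach_off, double k_detach,
                     bool record_coords) {
  ConfinedSystem sys;
  sys.n = coords.nrow();
  sys.b0 = bond_b; sys.kb = bond_k;
  sys.prof = make_profile(profile);
  sys.qs = qs; sys.Q = Q; sys.lB = lB; sys.R = R; sys.gap = gap;
  sys.core = core; sys.nonbonded = nonbonded; sys.sigma = sigma;
  sys.n_detach = n_detach; sys.detach_off = detach_off; sys.k_detach = k_detach;
  const int n = sys.n;

  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);
  for (int i = 0; i < n; ++i)
    if (!sys.feasible(x, i))
      stop("infeasible starting geometry: bead %d penetrates the core or walls",
           i + 1);

  int burn = (int)std::floor(burn_frac * sweeps);
  double step = step0;
  long acc = 0, att = 0, acc_t = 0, att_t = 0;
  int tune_int = 50;

  int n_frames = (sweeps - burn + thin - 1) / thin;
  if (n_frames < 0) n_frames = 0;
  NumericMatrix angles(n_frames, n - 2), radii(n_frames, n);
  NumericVector bendE(n_frames), totE(n_frames), zabs(n_frames);
  NumericVector traj;
  if (record_coords) traj = NumericVector((R_xlen_t)n_frames * n * 3);
  int fr = 0;

  for (int s = 0; s < sweeps; ++s) {
    for (int m = 0; m < n; ++m) {
      int i = (int)(unif_rand() * n);
      if (i == n) i = n - 1;
      double old[3] = {x[3 * i], x[3 * i + 1], x[3 * i + 2]};
      double e_old = sys.local_energy(x, i);
      for (int d = 0; d < 3; ++d) x[3 * i + d] += step * norm_rand();
      ++att; ++att_t;
      bool ok = sys.feasible(x, i);
      double dE = ok ? sys.local_energy(x, i) - e_old : 0.0;
      if (ok && (dE <= 0.0 || unif_rand() < std::exp(-beta * dE))) {
        ++acc; ++acc_t;
      } else {
        for (int d = 0; d < 3; ++d) x[3 * i + d] = old[d];
      }
    }
    if (s < burn && (s + 1) % tune_int == 0) {
      double r = (double)acc_t / att_t;
      double f = r / 0.40;
      if (f < 0.5) f = 0.5;
      if (f > 2.0) f = 2.0;
      step *= f;
      acc_t = att_t = 0;
    }
    if (s >= burn && (s - burn) % thin == 0 && fr < n_frames) {
      double be = 0.0, za = 0.0;
      for (int j = 1; j + 1 < n; ++j) {
        double th = bend_angle(x, j - 1, j, j + 1);
        angles(fr, j - 1) = th;
        be += sys.prof.energy(th);
      }
      for (int i = 0; i < n; ++i) {
        radii(fr, i) = sys.core_dist(&x[3 * i]);
        za += std::fabs(x[3 * i + 2]);
      }
      bendE[fr] = be;
      totE[fr] = sys.total_energy(x);
      zabs[fr] = za / n;
      if (record_coords)
        for (int i = 0; i < n; ++i)
          for (int d = 0; d < 3; ++d)
            traj[(R_xlen_t)fr * n * 3 + 3 * i + d] = x[3 * i + d];
      ++fr;
    }
  }

  NumericMatrix fin(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) fin(i, d) = x[3 * i + d];
  return List::create(
    _["angles"] = angles, _["radii"] = radii,
    _["bend_energy"] = bendE, _["total_energy"] = totE,
    _["mean_abs_z"] = zabs, _["coords_flat"] = traj, _["n_frames"] = fr,
    _["final_coords"] = fin,
    _["acceptance"] = (double)acc / (double)att, _["step"] = step);
}
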