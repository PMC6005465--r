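// Compiled core: pairwise forces (cell list) and the GJF Langevin integrator.
//
// Conventions shared with the R wrappers:
//  - particle arrays are flat doubles, xyz interleaved; monomers first
//    (indices 0..n-1), condensins after (n..n+m-1)
//  - spring / anchor index matrices arrive 0-based
//  - energies in kT units, lengths in sigma units

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Pot {
  double sigma, eps, eps_cut, eps_spr, dB;
  double Floop, Fcond, Delta;
  bool cap_force;                     // false: flat clamp; true: constant-force continuation
  double wall_R, wall_k, wall_fmax;   // wall_R <= 0 disables the confining shell
  double rc2, rcap, Fcap;             // derived
};

Pot make_pot(const List& p) {
  Pot q;
  q.sigma     = as<double>(p["sigma"]);
  q.eps       = as<double>(p["eps"]);
  q.eps_cut   = as<double>(p["eps_cut"]);
  q.eps_spr   = as<double>(p["eps_spr"]);
  q.dB        = as<double>(p["d_B"]);
  q.Floop     = as<double>(p["F_loop"]);
  q.Fcond     = as<double>(p["F_cond"]);
  q.Delta     = as<double>(p["Delta"]);
  q.cap_force = as<int>(p["cap_force"]) != 0;
  q.wall_R    = as<double>(p["wall_R"]);
  q.wall_k    = as<double>(p["wall_k"]);
  q.wall_fmax = as<double>(p["wall_fmax"]);
  if (q.eps > 0.0) {
    const double cut = std::pow(2.0, 1.0 / 6.0) * q.sigma;
    q.rc2 = cut * cut;
    const double xc = 0.5 * (1.0 + std::sqrt(q.eps_cut / q.eps)); // (sigma/rcap)^6
    q.rcap = q.sigma * std::pow(xc, -1.0 / 6.0);
    q.Fcap = 24.0 * q.eps * (2.0 * xc * xc - xc) / q.rcap;
  } else {
    q.rc2 = -1.0; q.rcap = 0.0; q.Fcap = 0.0;                     // excluded volume off
  }
  return q;
}

// WCA pair with energy cap; accumulates forces on i and j, returns pair energy.
inline double wca_pair(const Pot& q, const double* xi, const double* xj,
                       double* fi, double* fj) {
  double dx = xi[0] - xj[0], dy = xi[1] - xj[1], dz = xi[2] - xj[2];
  double r2 = dx * dx + dy * dy + dz * dz;
  if (r2 >= q.rc2) return 0.0;
  double r = std::sqrt(r2);
  if (r < q.rcap) {
    if (!q.cap_force || r < 1e-12) return q.eps_cut;  // flat clamp / coincident tie-break
    double fr = q.Fcap / r;
    fi[0] += fr * dx; fi[1] += fr * dy; fi[2] += fr * dz;
    fj[0] -= fr * dx; fj[1] -= fr * dy; fj[2] -= fr * dz;
    return q.eps_cut + q.Fcap * (q.rcap - r);
  }
  double s2 = q.sigma * q.sigma / r2;
  double s6 = s2 * s2 * s2, s12 = s6 * s6;
  double fr = 24.0 * q.eps * (2.0 * s12 - s6) / r2;
  fi[0] += fr * dx; fi[1] += fr * dy; fi[2] += fr * dz;
  fj[0] -= fr * dx; fj[1] -= fr * dy; fj[2] -= fr * dz;
  return 4.0 * q.eps * (s12 - s6 + 0.25);
}

// Cell list built by counting sort; only occupied cells are visited in the
// pair loop, and the total cell count is capped (cells grow beyond the
// interaction cutoff for very spread-out transients, which are dilute).
struct CellGrid {
  int nn[3];
  double lo[3], cl[3];
  std::vector<int> start, order, cidx, occupied, cursor;

  void build(const std::vector<double>& x, int n, double cut) {
    const int MAXC = 40;
    const size_t MAXTOT = 32768;
    for (int d = 0; d < 3; ++d) lo[d] = x[d];
    double hi[3] = { x[0], x[1], x[2] };
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        double v = x[3 * i + d];
        if (v < lo[d]) lo[d] = v;
        if (v > hi[d]) hi[d] = v;
      }
    for (int d = 0; d < 3; ++d) {
      double ext = hi[d] - lo[d];
      int k = (int)std::floor(ext / cut) + 1;
      if (k < 1) k = 1;
      if (k > MAXC) k = MAXC;
      nn[d] = k;
    }
    while ((size_t)nn[0] * nn[1] * nn[2] > MAXTOT) {
      int dmax = 0;
      if (nn[1] > nn[dmax]) dmax = 1;
      if (nn[2] > nn[dmax]) dmax = 2;
      nn[dmax] = nn[dmax] * 3 / 4;
    }
    for (int d = 0; d < 3; ++d) {
      double ext = hi[d] - lo[d];
      cl[d] = ext / nn[d] + 1e-9;
      if (cl[d] < cut) cl[d] = cut;
    }
    size_t ncell = (size_t)nn[0] * nn[1] * nn[2];
    start.assign(ncell + 1, 0);
    cidx.resize(n);
    order.resize(n);
    for (int i = 0; i < n; ++i) {
      cidx[i] = cell_of(&x[3 * i]);
      ++start[cidx[i] + 1];
    }
    occupied.clear();
    for (size_t c = 0; c < ncell; ++c) {
      if (start[c + 1] > 0) occupied.push_back((int)c);
      start[c + 1] += start[c];
    }
    cursor.assign(start.begin(), start.end() - 1);
    for (int i = 0; i < n; ++i) order[cursor[cidx[i]]++] = i;
  }

  inline int clampi(int v, int hi_) const { return v < 0 ? 0 : (v >= hi_ ? hi_ - 1 : v); }
  inline int cell_of(const double* p) const {
    int cx = clampi((int)((p[0] - lo[0]) / cl[0]), nn[0]);
    int cy = clampi((int)((p[1] - lo[1]) / cl[1]), nn[1]);
    int cz = clampi((int)((p[2] - lo[2]) / cl[2]), nn[2]);
    return (cz * nn[1] + cy) * nn[0] + cx;
  }
};

// half-space neighbor offsets for the cell pair loop (13 of 26)
const int OFF[13][3] = {
  {1,0,0}, {-1,1,0}, {0,1,0}, {1,1,0},
  {-1,-1,1}, {0,-1,1}, {1,-1,1}, {-1,0,1}, {0,0,1}, {1,0,1},
  {-1,1,1}, {0,1,1}, {1,1,1}
};

double compute_forces(const Pot& q, const std::vector<double>& x, int n, int m,
                      const IntegerMatrix& springs, const IntegerMatrix& anchors,
                      std::vector<double>& f, CellGrid& grid) {
  std::fill(f.begin(), f.end(), 0.0);
  double U = 0.0;

  // excluded volume among monomers (all pairs within cutoff, bonded or not)
  if (q.rc2 > 0.0 && n > 1) {
    double cut = std::sqrt(q.rc2);
    grid.build(x, n, cut);
    const int nx = grid.nn[0], ny = grid.nn[1], nz = grid.nn[2];
    for (int c : grid.occupied) {
      int cx = c % nx, cy = (c / nx) % ny, cz = c / (nx * ny);
      int i0 = grid.start[c], i1 = grid.start[c + 1];
      for (int ii = i0; ii < i1; ++ii) {
        int i = grid.order[ii];
        for (int jj = ii + 1; jj < i1; ++jj) {
          int j = grid.order[jj];
          U += wca_pair(q, &x[3 * i], &x[3 * j], &f[3 * i], &f[3 * j]);
        }
      }
      for (int k = 0; k < 13; ++k) {
        int ox = cx + OFF[k][0], oy = cy + OFF[k][1], oz = cz + OFF[k][2];
        if (ox < 0 || oy < 0 || oz < 0 || ox >= nx || oy >= ny || oz >= nz)
          continue;
        int c2 = (oz * ny + oy) * nx + ox;
        int j0 = grid.start[c2], j1 = grid.start[c2 + 1];
        if (j0 == j1) continue;
        for (int ii = i0; ii < i1; ++ii) {
          int i = grid.order[ii];
          for (int jj = j0; jj < j1; ++jj) {
            int j = grid.order[jj];
            U += wca_pair(q, &x[3 * i], &x[3 * j], &f[3 * i], &f[3 * j]);
          }
        }
      }
    }
  }

  // chain springs (phantom: no excluded volume of their own)
  for (int s = 0; s < springs.nrow(); ++s) {
    int i = springs(s, 0), j = springs(s, 1);
    double dx = x[3 * i] - x[3 * j], dy = x[3 * i + 1] - x[3 * j + 1],
           dz = x[3 * i + 2] - x[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double e = r - q.dB;
    U += 0.5 * q.eps_spr * e * e;
    if (r > 1e-12) {
      double fr = -q.eps_spr * e / r;
      f[3 * i] += fr * dx; f[3 * i + 1] += fr * dy; f[3 * i + 2] += fr * dz;
      f[3 * j] -= fr * dx; f[3 * j + 1] -= fr * dy; f[3 * j + 2] -= fr * dz;
    }
  }

  // loop-holding: condensin k tethered to its two base-point monomers
  if (q.Floop > 0.0) {
    for (int k = 0; k < m; ++k) {
      int ck = n + k;
      for (int s = 0; s < 2; ++s) {
        int a = anchors(k, s);
        double dx = x[3 * ck] - x[3 * a], dy = x[3 * ck + 1] - x[3 * a + 1],
               dz = x[3 * ck + 2] - x[3 * a + 2];
        U += 0.5 * q.Floop * (dx * dx + dy * dy + dz * dz);
        f[3 * ck] -= q.Floop * dx; f[3 * ck + 1] -= q.Floop * dy; f[3 * ck + 2] -= q.Floop * dz;
        f[3 * a] += q.Floop * dx; f[3 * a + 1] += q.Floop * dy; f[3 * a + 2] += q.Floop * dz;
      }
    }
  }

  // finite-range inter-condensin attraction, all pairs (cis and trans alike)
  if (q.Fcond > 0.0 && q.Delta > 0.0 && m > 1) {
    double D2 = q.Delta * q.Delta;
    for (int k = 0; k < m; ++k) {
      int ik = n + k;
      for (int l = k + 1; l < m; ++l) {
        int il = n + l;
        double dx = x[3 * ik] - x[3 * il], dy = x[3 * ik + 1] - x[3 * il + 1],
               dz = x[3 * ik + 2] - x[3 * il + 2];
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= D2) continue;
        double r = std::sqrt(r2);
        double g = q.Delta - r;
        U -= q.Fcond * g * g;
        if (r > 1e-12) {
          double fr = -2.0 * q.Fcond * g / r;   // attractive
          f[3 * ik] += fr * dx; f[3 * ik + 1] += fr * dy; f[3 * ik + 2] += fr * dz;
          f[3 * il] -= fr * dx; f[3 * il + 1] -= fr * dy; f[3 * il + 2] -= fr * dz;
        }
      }
    }
  }

  // spherical confining wall (compaction stage only); force clamped at wall_fmax
  if (q.wall_R > 0.0) {
    int ntot = n + m;
    for (int i = 0; i < ntot; ++i) {
      double px = x[3 * i], py = x[3 * i + 1], pz = x[3 * i + 2];
      double d = std::sqrt(px * px + py * py + pz * pz);
      if (d <= q.wall_R || d < 1e-12) continue;
      double exc = d - q.wall_R;
      double fmag = q.wall_k * exc;
      if (fmag > q.wall_fmax) {
        double exc0 = q.wall_fmax / q.wall_k;
        U += 0.5 * q.wall_k * exc0 * exc0 + q.wall_fmax * (exc - exc0);
        fmag = q.wall_fmax;
      } else {
        U += 0.5 * q.wall_k * exc * exc;
      }
      double fr = -fmag / d;
      f[3 * i] += fr * px; f[3 * i + 1] += fr * py; f[3 * i + 2] += fr * pz;
    }
  }

  return U;
}

void fill_vec(std::vector<double>& x, const NumericMatrix& M, int off) {
  for (int i = 0; i < M.nrow(); ++i)
    for (int d = 0; d < 3; ++d) x[3 * (off + i) + d] = M(i, d);
}

NumericMatrix take_mat(const std::vector<double>& x, int off, int n) {
  NumericMatrix M(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) M(i, d) = x[3 * (off + i) + d];
  return M;
}

bool all_finite(const std::vector<double>& x) {
  double s = 0.0;
  for (double v : x) s += v;
  return std::isfinite(s);
}

} // namespace

// [[Rcpp::export]]
List cpp_forces(NumericMatrix mono_pos, NumericMatrix cond_pos,
                IntegerMatrix springs, IntegerMatrix anchors, List pot) {
  Pot q = make_pot(pot);
  int n = mono_pos.nrow(), m = cond_pos.nrow();
  std::vector<double> x(3 * (n + m)), f(3 * (n + m));
  fill_vec(x, mono_pos, 0);
  fill_vec(x, cond_pos, n);
  CellGrid grid;
  double U = compute_forces(q, x, n, m, springs, anchors, f, grid);
  return List::create(_["f_mono"] = take_mat(f, 0, n),
                      _["f_cond"] = take_mat(f, n, m),
                      _["energy"] = U);
}

// [[Rcpp::export]]
double cpp_energy(NumericMatrix mono_pos, NumericMatrix cond_pos,
                  IntegerMatrix springs, IntegerMatrix anchors, List pot) {
  Pot q = make_pot(pot);
  int n = mono_pos.nrow(), m = cond_pos.nrow();
  std::vector<double> x(3 * (n + m)), f(3 * (n + m));
  fill_vec(x, mono_pos, 0);
  fill_vec(x, cond_pos, n);
  CellGrid grid;
  return compute_forces(q, x, n, m, springs, anchors, f, grid);
}

// GJF Langevin velocity-Verlet. gamma = 0 reduces to plain velocity Verlet
// (no noise drawn). Returns final state, final potential energy, and the
// run-averaged kinetic energy computed from half-step (2GJ) velocities.
// [[Rcpp::export]]
List cpp_run(NumericMatrix mono_pos, NumericMatrix mono_vel,
             NumericMatrix cond_pos, NumericMatrix cond_vel,
             IntegerMatrix springs, IntegerMatrix anchors, List pot,
             int n_steps, double dt, double gamma, double kT, double mass,
             int step0) {
  Pot q = make_pot(pot);
  int n = mono_pos.nrow(), m = cond_pos.nrow();
  int ntot = n + m, ndof = 3 * ntot;
  std::vector<double> x(ndof), v(ndof), f(ndof), xn(ndof), beta(ndof);
  fill_vec(x, mono_pos, 0); fill_vec(xn, mono_pos, 0);
  fill_vec(v, mono_vel, 0);
  fill_vec(x, cond_pos, n); fill_vec(xn, cond_pos, n);
  fill_vec(v, cond_vel, n);

  const double denom = 1.0 + gamma * dt / (2.0 * mass);
  const double a = (1.0 - gamma * dt / (2.0 * mass)) / denom;
  const double b = 1.0 / denom;
  const double sb = std::sqrt(b);
  const double sig = (gamma > 0.0) ? std::sqrt(2.0 * gamma * kT * dt) : 0.0;

  CellGrid grid;
  double U = compute_forces(q, x, n, m, springs, anchors, f, grid);
  double ke_half_sum = 0.0;

  for (int step = 0; step < n_steps; ++step) {
    if (gamma > 0.0)
      for (int i = 0; i < ndof; ++i) beta[i] = sig * norm_rand();
    else
      std::fill(beta.begin(), beta.end(), 0.0);

    double ke = 0.0;
    for (int i = 0; i < ndof; ++i) {
      double dxi = b * dt * v[i] + b * dt * dt / (2.0 * mass) * f[i] +
                   b * dt / (2.0 * mass) * beta[i];
      xn[i] = x[i] + dxi;
      double u = dxi / (sb * dt);
      ke += 0.5 * mass * u * u;
    }
    ke_half_sum += ke;

    std::vector<double>& fold = f;
    static thread_local std::vector<double> fn;
    fn.resize(ndof);
    double Un = compute_forces(q, xn, n, m, springs, anchors, fn, grid);

    for (int i = 0; i < ndof; ++i) {
      v[i] = a * v[i] + dt / (2.0 * mass) * (a * fold[i] + fn[i]) + b / mass * beta[i];
      x[i] = xn[i];
      f[i] = fn[i];
    }
    U = Un;

    if ((step & 127) == 0) {
      if (!all_finite(x))
        stop("integration blew up: non-finite coordinates near step %d", step0 + step + 1);
      Rcpp::checkUserInterrupt();
    }
  }
  if (!all_finite(x))
    stop("integration blew up: non-finite coordinates near step %d", step0 + n_steps);

  return List::create(
    _["mono_pos"] = take_mat(x, 0, n), _["mono_vel"] = take_mat(v, 0, n),
    _["cond_pos"] = take_mat(x, n, m), _["cond_vel"] = take_mat(v, n, m),
    _["epot"] = U,
    _["ke_half_mean"] = (n_steps > 0 ? ke_half_sum / n_steps : NA_REAL));
}
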