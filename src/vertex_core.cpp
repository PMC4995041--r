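// Compiled core of the vertex model: work function, analytic gradient,
// L-BFGS relaxation with Armijo backtracking, and the overdamped Euler
// integrator used by the ablation assay.
//
// Network encoding shared by all entry points (all indices 0-based here;
// R wrappers convert from 1-based):
//   V         n x 2 vertex positions
//   cell_ptr  length nc+1, offsets into cell_vert (CSR layout of loops)
//   cell_vert concatenated counterclockwise vertex loops
//   pref_area length nc, preferred area of each cell (A0 * multiplier)
//   bonds     m x 2 vertex index pairs
//   tension   length m, line tension Lambda per bond (0 for ablated bonds)
//   K         area elastic modulus
//   gamma     perimeter elasticity Gamma

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Net {
  int n, nc, m;
  const int *cptr, *cvert;
  const double *pref;
  const int *b0, *b1;
  const double *ten;
  double K, gamma;
};

// Shoelace area of cell c (positive for CCW loops)
inline double cell_area(const Net &net, const double *x, const double *y, int c) {
  double a = 0.0;
  int s = net.cptr[c], e = net.cptr[c + 1];
  for (int k = s; k < e; ++k) {
    int i = net.cvert[k];
    int j = net.cvert[(k + 1 < e) ? k + 1 : s];
    a += x[i] * y[j] - x[j] * y[i];
  }
  return 0.5 * a;
}

inline double cell_perimeter(const Net &net, const double *x, const double *y, int c) {
  double p = 0.0;
  int s = net.cptr[c], e = net.cptr[c + 1];
  for (int k = s; k < e; ++k) {
    int i = net.cvert[k];
    int j = net.cvert[(k + 1 < e) ? k + 1 : s];
    p += std::sqrt((x[j]-x[i])*(x[j]-x[i]) + (y[j]-y[i])*(y[j]-y[i]));
  }
  return p;
}

// Work function. If any cell area <= 0 and barrier is true, returns +Inf
// (used by the line search to reject steps that invert a polygon).
double energy(const Net &net, const double *x, const double *y,
              bool barrier, double *terms /* 3 or nullptr */) {
  double e_area = 0.0, e_ten = 0.0, e_per = 0.0;
  for (int c = 0; c < net.nc; ++c) {
    double A = cell_area(net, x, y, c);
    if (barrier && A <= 0.0) return R_PosInf;
    double dA = A - net.pref[c];
    e_area += 0.5 * net.K * dA * dA;
    double L = cell_perimeter(net, x, y, c);
    e_per += 0.5 * net.gamma * L * L;
  }
  for (int b = 0; b < net.m; ++b) {
    double dx = x[net.b1[b]] - x[net.b0[b]];
    double dy = y[net.b1[b]] - y[net.b0[b]];
    e_ten += net.ten[b] * std::sqrt(dx * dx + dy * dy);
  }
  if (terms) { terms[0] = e_area; terms[1] = e_ten; terms[2] = e_per; }
  return e_area + e_ten + e_per;
}

// Gradient of the work function wrt vertex coordinates.
void gradient(const Net &net, const double *x, const double *y,
              double *gx, double *gy) {
  for (int i = 0; i < net.n; ++i) { gx[i] = 0.0; gy[i] = 0.0; }
  for (int c = 0; c < net.nc; ++c) {
    double A = cell_area(net, x, y, c);
    double ka = net.K * (A - net.pref[c]);
    double L = cell_perimeter(net, x, y, c);
    double gl = net.gamma * L;
    int s = net.cptr[c], e = net.cptr[c + 1], len = e - s;
    for (int k = 0; k < len; ++k) {
      int i = net.cvert[s + k];
      int ip = net.cvert[s + ((k + 1) % len)];   // next (CCW)
      int im = net.cvert[s + ((k + len - 1) % len)]; // previous
      // area term: dA/dx_i = (y_next - y_prev)/2, dA/dy_i = (x_prev - x_next)/2
      gx[i] += ka * 0.5 * (y[ip] - y[im]);
      gy[i] += ka * 0.5 * (x[im] - x[ip]);
      // perimeter term: sum of unit vectors away from both neighbours
      double dxp = x[i] - x[ip], dyp = y[i] - y[ip];
      double lp = std::sqrt(dxp * dxp + dyp * dyp);
      if (lp > 0) { gx[i] += gl * dxp / lp; gy[i] += gl * dyp / lp; }
      double dxm = x[i] - x[im], dym = y[i] - y[im];
      double lm = std::sqrt(dxm * dxm + dym * dym);
      if (lm > 0) { gx[i] += gl * dxm / lm; gy[i] += gl * dym / lm; }
    }
  }
  for (int b = 0; b < net.m; ++b) {
    int i = net.b0[b], j = net.b1[b];
    double dx = x[i] - x[j], dy = y[i] - y[j];
    double l = std::sqrt(dx * dx + dy * dy);
    if (l > 0) {
      double t = net.ten[b];
      gx[i] += t * dx / l; gy[i] += t * dy / l;
      gx[j] -= t * dx / l; gy[j] -= t * dy / l;
    }
  }
}

inline double max_vertex_force(const Net &net, const double *gx, const double *gy) {
  double mx = 0.0;
  for (int i = 0; i < net.n; ++i) {
    double f = std::sqrt(gx[i] * gx[i] + gy[i] * gy[i]);
    if (f > mx) mx = f;
  }
  return mx;
}

Net make_net(const NumericMatrix &V, const IntegerVector &cell_ptr,
             const IntegerVector &cell_vert, const NumericVector &pref_area,
             const IntegerVector &bond_a, const IntegerVector &bond_b,
             const NumericVector &tension, double K, double gamma) {
  Net net;
  net.n = V.nrow();
  net.nc = cell_ptr.size() - 1;
  net.m = bond_a.size();
  net.cptr = cell_ptr.begin();
  net.cvert = cell_vert.begin();
  net.pref = pref_area.begin();
  net.b0 = bond_a.begin();
  net.b1 = bond_b.begin();
  net.ten = tension.begin();
  net.K = K;
  net.gamma = gamma;
  return net;
}

} // namespace

// [[Rcpp::export]]
List tissue_energy_cpp(NumericMatrix V, IntegerVector cell_ptr, IntegerVector cell_vert,
                       NumericVector pref_area, IntegerVector bond_a, IntegerVector bond_b,
                       NumericVector tension, double K, double gamma) {
  Net net = make_net(V, cell_ptr, cell_vert, pref_area, bond_a, bond_b, tension, K, gamma);
  std::vector<double> x(net.n), y(net.n);
  for (int i = 0; i < net.n; ++i) { x[i] = V(i, 0); y[i] = V(i, 1); }
  double terms[3];
  double e = energy(net, x.data(), y.data(), false, terms);
  return List::create(_["total"] = e, _["area"] = terms[0],
                      _["tension"] = terms[1], _["perimeter"] = terms[2]);
}

// [[Rcpp::export]]
NumericMatrix tissue_gradient_cpp(NumericMatrix V, IntegerVector cell_ptr, IntegerVector cell_vert,
                                  NumericVector pref_area, IntegerVector bond_a, IntegerVector bond_b,
                                  NumericVector tension, double K, double gamma) {
  Net net = make_net(V, cell_ptr, cell_vert, pref_area, bond_a, bond_b, tension, K, gamma);
  std::vector<double> x(net.n), y(net.n), gx(net.n), gy(net.n);
  for (int i = 0; i < net.n; ++i) { x[i] = V(i, 0); y[i] = V(i, 1); }
  gradient(net, x.data(), y.data(), gx.data(), gy.data());
  NumericMatrix G(net.n, 2);
  for (int i = 0; i < net.n; ++i) { G(i, 0) = gx[i]; G(i, 1) = gy[i]; }
  return G;
}

// [[Rcpp::export]]
NumericVector cell_areas_cpp(NumericMatrix V, IntegerVector cell_ptr, IntegerVector cell_vert) {
  Net net;
  net.n = V.nrow(); net.nc = cell_ptr.size() - 1;
  net.cptr = cell_ptr.begin(); net.cvert = cell_vert.begin();
  std::vector<double> x(net.n), y(net.n);
  for (int i = 0; i < net.n; ++i) { x[i] = V(i, 0); y[i] = V(i, 1); }
  NumericVector out(net.nc);
  for (int c = 0; c < net.nc; ++c) out[c] = cell_area(net, x.data(), y.data(), c);
  return out;
}

// L-BFGS with Armijo backtracking; monotone in energy. Stops when the
// largest per-vertex force norm drops below grad_tol.
// [[Rcpp::export]]
List relax_lbfgs_cpp(NumericMatrix V, IntegerVector cell_ptr, IntegerVector cell_vert,
                     NumericVector pref_area, IntegerVector bond_a, IntegerVector bond_b,
                     NumericVector tension, double K, double gamma,
                     double grad_tol, int max_iter) {
  Net net = make_net(V, cell_ptr, cell_vert, pref_area, bond_a, bond_b, tension, K, gamma);
  const int n = net.n, dim = 2 * n, hist = 8;
  std::vector<double> x(dim);           // packed (x..., y...)
  for (int i = 0; i < n; ++i) { x[i] = V(i, 0); x[n + i] = V(i, 1); }
  std::vector<double> g(dim), gnew(dim), d(dim), xtry(dim);
  std::vector<std::vector<double> > S(hist, std::vector<double>(dim)),
      Y(hist, std::vector<double>(dim));
  std::vector<double> rho(hist), alpha_buf(hist);
  int nstored = 0, head = 0;

  gradient(net, x.data(), x.data() + n, g.data(), g.data() + n);
  double f = energy(net, x.data(), x.data() + n, true, nullptr);
  if (!R_FINITE(f))
    stop("relax: initial configuration has a degenerate (non-positive area) cell");

  double maxf = max_vertex_force(net, g.data(), g.data() + n);
  int iter = 0;
  bool converged = maxf < grad_tol;
  bool stalled = false;

  while (!converged && iter < max_iter) {
    // two-loop recursion
    for (int i = 0; i < dim; ++i) d[i] = -g[i];
    double gamma_h = 1.0;
    for (int k = 0; k < nstored; ++k) {
      int idx = (head - 1 - k + hist * 4) % hist;
      double a = 0.0;
      for (int i = 0; i < dim; ++i) a += S[idx][i] * d[i];
      a *= rho[idx];
      alpha_buf[idx] = a;
      for (int i = 0; i < dim; ++i) d[i] -= a * Y[idx][i];
    }
    if (nstored > 0) {
      int last = (head - 1 + hist) % hist;
      double yy = 0.0, sy = 0.0;
      for (int i = 0; i < dim; ++i) { yy += Y[last][i] * Y[last][i]; sy += S[last][i] * Y[last][i]; }
      if (yy > 0 && sy > 0) gamma_h = sy / yy;
    }
    for (int i = 0; i < dim; ++i) d[i] *= gamma_h;
    for (int k = nstored - 1; k >= 0; --k) {
      int idx = (head - 1 - k + hist * 4) % hist;
      double b = 0.0;
      for (int i = 0; i < dim; ++i) b += Y[idx][i] * d[i];
      b *= rho[idx];
      for (int i = 0; i < dim; ++i) d[i] += (alpha_buf[idx] - b) * S[idx][i];
    }
    double gd = 0.0;
    for (int i = 0; i < dim; ++i) gd += g[i] * d[i];
    if (gd >= 0) { // not a descent direction: reset to steepest descent
      double gn = 0.0;
      for (int i = 0; i < dim; ++i) gn += g[i] * g[i];
      double scale = (gn > 0) ? 1.0 / std::sqrt(gn) : 1.0;
      for (int i = 0; i < dim; ++i) d[i] = -g[i] * scale;
      gd = -std::sqrt(gn);
      nstored = 0; head = 0;
    }

    // Armijo backtracking (also rejects polygon inversion via the barrier)
    double step = 1.0, fnew = R_PosInf;
    const double c1 = 1e-4;
    int ls = 0;
    for (; ls < 60; ++ls) {
      for (int i = 0; i < dim; ++i) xtry[i] = x[i] + step * d[i];
      fnew = energy(net, xtry.data(), xtry.data() + n, true, nullptr);
      if (R_FINITE(fnew) && fnew <= f + c1 * step * gd) break;
      step *= 0.5;
    }
    if (ls == 60) { stalled = true; break; } // line search failed

    gradient(net, xtry.data(), xtry.data() + n, gnew.data(), gnew.data() + n);
    // store curvature pair
    double sy = 0.0;
    for (int i = 0; i < dim; ++i) {
      S[head][i] = xtry[i] - x[i];
      Y[head][i] = gnew[i] - g[i];
      sy += S[head][i] * Y[head][i];
    }
    if (sy > 1e-14) {
      rho[head] = 1.0 / sy;
      head = (head + 1) % hist;
      if (nstored < hist) ++nstored;
    }
    x.swap(xtry);
    g.swap(gnew);
    f = fnew;
    maxf = max_vertex_force(net, g.data(), g.data() + n);
    converged = maxf < grad_tol;
    ++iter;
  }

  NumericMatrix Vout(n, 2);
  for (int i = 0; i < n; ++i) { Vout(i, 0) = x[i]; Vout(i, 1) = x[n + i]; }
  return List::create(_["V"] = Vout, _["converged"] = converged,
                      _["stalled"] = stalled,
                      _["iterations"] = iter, _["max_force"] = maxf,
                      _["energy"] = f);
}

// Overdamped dynamics dx/dt = -grad(E)/friction, forward Euler. Records the
// distance between vertices vi and vj at t = 0, dt, 2dt, ... If the energy
// increases beyond a small tolerance the step size is halved and the
// integration restarted (up to max_halvings), after which it fails.
// [[Rcpp::export]]
List overdamped_trace_cpp(NumericMatrix V, IntegerVector cell_ptr, IntegerVector cell_vert,
                          NumericVector pref_area, IntegerVector bond_a, IntegerVector bond_b,
                          NumericVector tension, double K, double gamma,
                          int vi, int vj, double dt, double t_max, double friction,
                          int max_halvings) {
  Net net = make_net(V, cell_ptr, cell_vert, pref_area, bond_a, bond_b, tension, K, gamma);
  const int n = net.n;

  double dt_use = dt;
  for (int attempt = 0; attempt <= max_halvings; ++attempt) {
    int nsteps = (int)std::ceil(t_max / dt_use);
    std::vector<double> x(n), y(n), gx(n), gy(n);
    for (int i = 0; i < n; ++i) { x[i] = V(i, 0); y[i] = V(i, 1); }
    NumericVector times(nsteps + 1), dist(nsteps + 1), evec(nsteps + 1);
    double e_prev = energy(net, x.data(), y.data(), false, nullptr);
    times[0] = 0.0;
    dist[0] = std::hypot(x[vj] - x[vi], y[vj] - y[vi]);
    evec[0] = e_prev;
    bool ok = true;
    for (int s = 1; s <= nsteps; ++s) {
      gradient(net, x.data(), y.data(), gx.data(), gy.data());
      for (int i = 0; i < n; ++i) {
        x[i] -= dt_use * gx[i] / friction;
        y[i] -= dt_use * gy[i] / friction;
      }
      double e = energy(net, x.data(), y.data(), false, nullptr);
      if (!R_FINITE(e) || e > e_prev + 1e-10 * (1.0 + std::fabs(e_prev))) {
        ok = false;
        break;
      }
      e_prev = e;
      times[s] = s * dt_use;
      dist[s] = std::hypot(x[vj] - x[vi], y[vj] - y[vi]);
      evec[s] = e;
    }
    if (ok) {
      NumericMatrix Vout(n, 2);
      for (int i = 0; i < n; ++i) { Vout(i, 0) = x[i]; Vout(i, 1) = y[i]; }
      return List::create(_["times"] = times, _["dist"] = dist,
                          _["energy"] = evec, _["V"] = Vout,
                          _["dt_used"] = dt_use);
    }
    dt_use *= 0.5;
  }
  stop("overdamped trace: energy increased even after %d step-size halvings", max_halvings);
}
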