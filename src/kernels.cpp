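// Low-level kernels for the ghost-structure coupling: the four-point smoothed
// delta, Lagrangian<->Eulerian transfer, the staggered-grid anisotropic
// Laplacian, and the fused FitzHugh-Nagumo benchmark loop.
//
// Grid convention (matches the R side): an n1 x n2 field is stored as an R
// matrix in column-major order, value(i, j) = V[i + n1 * j], with the cell
// center (i, j) at (x0 + (i + 1/2) dx, y0 + (j + 1/2) dy), i = 0..n1-1.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// 1-D four-point kernel Psi(r): piecewise cubic, support |r| < 2,
// partition of unity over the integer lattice.
static inline double psi1(double r) {
  double a = std::fabs(r);
  if (a <= 1.0)
    return 0.5 * (a + 1.0) * (a - 1.0) * (a - 2.0);
  if (a < 2.0)
    return -(1.0 / 6.0) * (a - 1.0) * (a - 2.0) * (a - 3.0);
  return 0.0;
}

// [[Rcpp::export(name = ".psi_cpp")]]
NumericVector psi_cpp(NumericVector r) {
  R_xlen_t n = r.size();
  NumericVector out(n);
  for (R_xlen_t k = 0; k < n; ++k) out[k] = psi1(r[k]);
  return out;
}

// Continuous cell-center coordinate of physical position x along one axis.
static inline double cellcoord(double x, double orig, double h) {
  return (x - orig) / h - 0.5;
}

struct Stencil {
  int i0, j0;
  double wx[4], wy[4];
};

// Build the 4x4 tensor stencil for one point; returns false if the support
// sticks out of the grid (caller decides whether that is an error).
static inline bool stencil_at(double x, double y, double x0, double y0,
                              double dx, double dy, int n1, int n2,
                              Stencil &s) {
  double cx = cellcoord(x, x0, dx);
  double cy = cellcoord(y, y0, dy);
  s.i0 = (int)std::floor(cx) - 1;
  s.j0 = (int)std::floor(cy) - 1;
  if (s.i0 < 0 || s.j0 < 0 || s.i0 + 3 >= n1 || s.j0 + 3 >= n2) return false;
  for (int a = 0; a < 4; ++a) {
    s.wx[a] = psi1(cx - (s.i0 + a));
    s.wy[a] = psi1(cy - (s.j0 + a));
  }
  return true;
}

// Spreading (Lagrangian -> Eulerian): each point contributes
// q * Psi(.)Psi(.) / (dx dy) to its 4x4 neighbourhood.  `q` must already
// include the quadrature weight.
// [[Rcpp::export(name = ".spread_cpp")]]
NumericMatrix spread_cpp(NumericVector px, NumericVector py, NumericVector q,
                         int n1, int n2, double x0, double y0, double dx,
                         double dy) {
  NumericMatrix out(n1, n2);
  double norm = 1.0 / (dx * dy);
  R_xlen_t n = px.size();
  Stencil s;
  for (R_xlen_t k = 0; k < n; ++k) {
    if (!stencil_at(px[k], py[k], x0, y0, dx, dy, n1, n2, s))
      stop("spread: point %d at (%g, %g) is within two cells of the ghost-box edge",
           (int)(k + 1), px[k], py[k]);
    double qk = q[k] * norm;
    for (int b = 0; b < 4; ++b) {
      double wyb = s.wy[b] * qk;
      double *col = &out[(R_xlen_t)(s.j0 + b) * n1 + s.i0];
      for (int a = 0; a < 4; ++a) col[a] += s.wx[a] * wyb;
    }
  }
  return out;
}

// Interpolation (Eulerian -> Lagrangian): value = sum V * Psi Psi (the
// dx dy of the quadrature cancels the kernel normalization).
// [[Rcpp::export(name = ".interp_cpp")]]
NumericVector interp_cpp(NumericVector px, NumericVector py,
                         NumericMatrix V, double x0, double y0, double dx,
                         double dy) {
  int n1 = V.nrow(), n2 = V.ncol();
  R_xlen_t n = px.size();
  NumericVector out(n);
  Stencil s;
  for (R_xlen_t k = 0; k < n; ++k) {
    if (!stencil_at(px[k], py[k], x0, y0, dx, dy, n1, n2, s))
      stop("interpolate: point %d at (%g, %g) is within two cells of the ghost-box edge",
           (int)(k + 1), px[k], py[k]);
    double acc = 0.0;
    for (int b = 0; b < 4; ++b) {
      const double *col = &V[(R_xlen_t)(s.j0 + b) * n1 + s.i0];
      double sb = 0.0;
      for (int a = 0; a < 4; ++a) sb += s.wx[a] * col[a];
      acc += s.wy[b] * sb;
    }
    out[k] = acc;
  }
  return out;
}

// Staggered-grid anisotropic diffusion sl d2/dx2 + st d2/dy2; neighbours
// outside the box are held at the Dirichlet value `vrest` (the one-cell
// ghost ring).
// [[Rcpp::export(name = ".laplacian_cpp")]]
NumericMatrix laplacian_cpp(NumericMatrix V, double sl, double st, double dx,
                            double dy, double vrest) {
  int n1 = V.nrow(), n2 = V.ncol();
  NumericMatrix out(n1, n2);
  double cx = sl / (dx * dx), cy = st / (dy * dy);
  for (int j = 0; j < n2; ++j) {
    const double *vj = &V[(R_xlen_t)j * n1];
    const double *vm = (j > 0) ? &V[(R_xlen_t)(j - 1) * n1] : nullptr;
    const double *vp = (j < n2 - 1) ? &V[(R_xlen_t)(j + 1) * n1] : nullptr;
    double *oj = &out[(R_xlen_t)j * n1];
    for (int i = 0; i < n1; ++i) {
      double w = (i > 0) ? vj[i - 1] : vrest;
      double e = (i < n1 - 1) ? vj[i + 1] : vrest;
      double so = vm ? vm[i] : vrest;
      double no = vp ? vp[i] : vrest;
      oj[i] = cx * (e - 2.0 * vj[i] + w) + cy * (no - 2.0 * vj[i] + so);
    }
  }
  return out;
}

// Nodal -> quadrature-point evaluation through the P1 basis.
// idx: nq x 3 (1-based node indices), bar: nq x 3 barycentric weights.
// [[Rcpp::export(name = ".basis_interp_cpp")]]
NumericVector basis_interp_cpp(IntegerMatrix idx, NumericMatrix bar,
                               NumericVector nodal) {
  R_xlen_t nq = idx.nrow();
  NumericVector out(nq);
  for (R_xlen_t k = 0; k < nq; ++k)
    out[k] = bar(k, 0) * nodal[idx(k, 0) - 1] +
             bar(k, 1) * nodal[idx(k, 1) - 1] +
             bar(k, 2) * nodal[idx(k, 2) - 1];
  return out;
}

// Load vector of the L2 projection: b_l = sum_Q phi_l(X_Q) q_Q w_Q.
// [[Rcpp::export(name = ".project_rhs_cpp")]]
NumericVector project_rhs_cpp(IntegerMatrix idx, NumericMatrix bar,
                              NumericVector q, NumericVector w, int nnodes) {
  R_xlen_t nq = idx.nrow();
  NumericVector out(nnodes);
  for (R_xlen_t k = 0; k < nq; ++k) {
    double qw = q[k] * w[k];
    out[idx(k, 0) - 1] += bar(k, 0) * qw;
    out[idx(k, 1) - 1] += bar(k, 1) * qw;
    out[idx(k, 2) - 1] += bar(k, 2) * qw;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Fused benchmark loop for the FitzHugh-Nagumo model.
//
// One ghost-structure step (explicit Shu-Osher TVD-RK3 for the PDE, the
// reaction field either frozen over the step or re-evaluated per stage; the
// recovery ODE advanced afterwards with the freshly interpolated potential
// frozen across its three stages; far ghost cells reset to rest).  Identical
// in exact arithmetic order to the reference R implementation of gs_step().
// ---------------------------------------------------------------------------

struct Tables {
  std::vector<int> i0, j0;
  std::vector<double> wx, wy;  // 4 per point, interleaved
};

static void build_tables(const std::vector<double> &px,
                         const std::vector<double> &py, double x0, double y0,
                         double dx, double dy, int n1, int n2, Tables &tb,
                         std::vector<unsigned char> &active) {
  size_t n = px.size();
  tb.i0.resize(n);
  tb.j0.resize(n);
  tb.wx.resize(4 * n);
  tb.wy.resize(4 * n);
  std::fill(active.begin(), active.end(), 0);
  Stencil s;
  for (size_t k = 0; k < n; ++k) {
    if (!stencil_at(px[k], py[k], x0, y0, dx, dy, n1, n2, s))
      stop("gs_run: quadrature point %d at (%g, %g) left the ghost box",
           (int)(k + 1), px[k], py[k]);
    tb.i0[k] = s.i0;
    tb.j0[k] = s.j0;
    for (int a = 0; a < 4; ++a) {
      tb.wx[4 * k + a] = s.wx[a];
      tb.wy[4 * k + a] = s.wy[a];
    }
    for (int b = 0; b < 4; ++b)
      for (int a = 0; a < 4; ++a)
        active[(size_t)(s.j0 + b) * n1 + (s.i0 + a)] = 1;
  }
}

static inline void tb_interp(const Tables &tb, const double *V, int n1,
                             double *out, size_t n) {
  for (size_t k = 0; k < n; ++k) {
    const double *wx = &tb.wx[4 * k], *wy = &tb.wy[4 * k];
    const double *base = V + (size_t)tb.j0[k] * n1 + tb.i0[k];
    double acc = 0.0;
    for (int b = 0; b < 4; ++b) {
      const double *col = base + (size_t)b * n1;
      acc += wy[b] * (wx[0] * col[0] + wx[1] * col[1] + wx[2] * col[2] +
                      wx[3] * col[3]);
    }
    out[k] = acc;
  }
}

static inline void tb_spread(const Tables &tb, const double *q, double norm,
                             double *field, int n1, size_t n) {
  for (size_t k = 0; k < n; ++k) {
    const double *wx = &tb.wx[4 * k], *wy = &tb.wy[4 * k];
    double *base = field + (size_t)tb.j0[k] * n1 + tb.i0[k];
    double qk = q[k] * norm;
    for (int b = 0; b < 4; ++b) {
      double wyb = wy[b] * qk;
      double *col = base + (size_t)b * n1;
      col[0] += wx[0] * wyb;
      col[1] += wx[1] * wyb;
      col[2] += wx[2] * wyb;
      col[3] += wx[3] * wyb;
    }
  }
}

static inline void add_lap(const double *V, double cx, double cy, int n1,
                           int n2, double vrest, double *out) {
  for (int j = 0; j < n2; ++j) {
    const double *vj = V + (size_t)j * n1;
    const double *vm = (j > 0) ? vj - n1 : nullptr;
    const double *vp = (j < n2 - 1) ? vj + n1 : nullptr;
    double *oj = out + (size_t)j * n1;
    for (int i = 0; i < n1; ++i) {
      double w = (i > 0) ? vj[i - 1] : vrest;
      double e = (i < n1 - 1) ? vj[i + 1] : vrest;
      double so = vm ? vm[i] : vrest;
      double no = vp ? vp[i] : vrest;
      oj[i] += cx * (e - 2.0 * vj[i] + w) + cy * (no - 2.0 * vj[i] + so);
    }
  }
}

// [[Rcpp::export(name = ".gs_run_fhn_cpp")]]
List gs_run_fhn_cpp(List args) {
  // grid
  int n1 = as<int>(args["n1"]), n2 = as<int>(args["n2"]);
  double x0 = as<double>(args["ox"]), y0 = as<double>(args["oy"]);
  double dx = as<double>(args["dx"]), dy = as<double>(args["dy"]);
  // physics (dimensionless FHN embedding: Cm = Am = 1)
  double Kx = as<double>(args["kx"]), Ky = as<double>(args["ky"]);
  double fa = as<double>(args["a"]), feps = as<double>(args["eps"]);
  double fbeta = as<double>(args["beta"]), fgamma = as<double>(args["gamma"]);
  double fsigma = as<double>(args["sigma"]);
  double vrest = as<double>(args["vrest"]);
  // time
  double dt = as<double>(args["dt"]);
  int nsteps = as<int>(args["nsteps"]);
  bool per_stage = as<bool>(args["per_stage"]);
  int refresh_every = as<int>(args["refresh_every"]);
  bool refresh_outside = as<bool>(args["refresh_outside"]);
  double guard = as<double>(args["guard"]);
  // Lagrangian structure (material data)
  NumericMatrix qp0 = args["qp"];            // nq x 2 material positions
  NumericVector qfrac = args["quad_frac"];   // rule weight fraction per point
  IntegerVector qelem = args["quad_elem"];   // 1-based owning element
  IntegerMatrix qidx = args["quad_nodes"];   // nq x 3 node indices
  NumericMatrix qbar = args["quad_basis"];   // nq x 3 barycentric weights
  NumericMatrix nd0 = args["nodes"];         // nnode x 2 material positions
  IntegerMatrix tri = args["elements"];      // ntri x 3
  NumericVector V0 = args["V0"];             // n1*n2
  NumericVector yv0 = args["yinit"];            // nnode recovery values
  // motion (material-coordinate radial field, optional)
  bool moving = as<bool>(args["moving"]);
  double mcx = 0, mcy = 0, mrate = 0, tstop = 0;
  if (moving) {
    mcx = as<double>(args["motion_cx"]);
    mcy = as<double>(args["motion_cy"]);
    mrate = as<double>(args["motion_rate"]);
    tstop = as<double>(args["motion_tstop"]);
  }
  // outputs requested
  IntegerVector probe_cells = args["probe_cells"];  // 0-based flat indices
  IntegerVector snap_steps = args["snap_steps"];    // record after these steps

  size_t nq = qp0.nrow(), nnode = nd0.nrow(), ng = (size_t)n1 * n2;
  int ntri = tri.nrow();

  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> yv(yv0.begin(), yv0.end());
  std::vector<double> qx(nq), qy(nq), qw(nq);
  std::vector<double> nx(nnode), ny(nnode);
  for (size_t k = 0; k < nq; ++k) { qx[k] = qp0(k, 0); qy[k] = qp0(k, 1); }
  for (size_t l = 0; l < nnode; ++l) { nx[l] = nd0(l, 0); ny[l] = nd0(l, 1); }

  // per-point velocities in material coordinates (constant in time)
  std::vector<double> qvx, qvy, nvx, nvy;
  if (moving) {
    qvx.resize(nq); qvy.resize(nq); nvx.resize(nnode); nvy.resize(nnode);
    for (size_t k = 0; k < nq; ++k) {
      double ux = qp0(k, 0) - mcx, uy = qp0(k, 1) - mcy;
      qvx[k] = mrate * ux;  // k(X) n(X) = rate * (X - Xc)
      qvy[k] = mrate * uy;
    }
    for (size_t l = 0; l < nnode; ++l) {
      double ux = nd0(l, 0) - mcx, uy = nd0(l, 1) - mcy;
      nvx[l] = mrate * ux;
      nvy[l] = mrate * uy;
    }
  }

  // current quadrature weights from current element areas
  std::vector<double> area(ntri);
  auto recompute_weights = [&]() {
    for (int e = 0; e < ntri; ++e) {
      int a = tri(e, 0) - 1, b = tri(e, 1) - 1, c = tri(e, 2) - 1;
      double ax = nx[a], ay = ny[a];
      area[e] = 0.5 * std::fabs((nx[b] - ax) * (ny[c] - ay) -
                                (nx[c] - ax) * (ny[b] - ay));
    }
    for (size_t k = 0; k < nq; ++k) qw[k] = area[qelem[k] - 1] * qfrac[k];
  };
  recompute_weights();

  // lumped mass for the nodal projection
  std::vector<double> mlump(nnode);
  auto recompute_mass = [&]() {
    std::fill(mlump.begin(), mlump.end(), 0.0);
    for (size_t k = 0; k < nq; ++k) {
      mlump[qidx(k, 0) - 1] += qbar(k, 0) * qw[k];
      mlump[qidx(k, 1) - 1] += qbar(k, 1) * qw[k];
      mlump[qidx(k, 2) - 1] += qbar(k, 2) * qw[k];
    }
  };
  recompute_mass();

  Tables tb;
  std::vector<unsigned char> active(ng);
  std::vector<double> cover(ng);
  double norm0 = 1.0 / (dx * dy);
  auto rebuild_geometry = [&]() {
    build_tables(qx, qy, x0, y0, dx, dy, n1, n2, tb, active);
    if (refresh_outside) {
      // coverage = spread of the constant 1: ~1 inside the structure, ~1/2 on
      // its boundary; cells less than half covered count as outside
      std::fill(cover.begin(), cover.end(), 0.0);
      tb_spread(tb, qw.data(), norm0, cover.data(), n1, nq);
      for (size_t g = 0; g < ng; ++g) active[g] = cover[g] >= 0.5;
    }
  };
  rebuild_geometry();

  double cx = Kx / (dx * dx), cy = Ky / (dy * dy), norm = 1.0 / (dx * dy);

  std::vector<double> uq(nq), vq(nq), rq(nq), V1(ng), V2(ng), L0(ng), L1(ng),
      L2v(ng), Rf(ng), uq1(nq), uq2(nq);
  std::vector<double> ut(nnode), f0(nnode), f1(nnode), y1(nnode), y2(nnode);

  int np = probe_cells.size();
  NumericMatrix probes(nsteps + 1, np);
  NumericVector probe_t(nsteps + 1);
  List snaps;
  std::vector<double> snap_t;
  auto maybe_snap = [&](int step, double t) {
    for (int s = 0; s < snap_steps.size(); ++s)
      if (snap_steps[s] == step) {
        NumericMatrix M(n1, n2);
        std::copy(V.begin(), V.end(), M.begin());
        snaps.push_back(M);
        snap_t.push_back(t);
      }
  };
  for (int p = 0; p < np; ++p) probes(0, p) = V[probe_cells[p]];
  probe_t[0] = 0.0;
  maybe_snap(0, 0.0);

  tb_interp(tb, V.data(), n1, uq.data(), nq);

  auto reaction = [&](const double *uu) {
    // Eulerian reaction field: spread of (cubic - v) * w; equals -I_ion of
    // the generic monodomain form with the FHN sign registration.
    for (size_t k = 0; k < nq; ++k)
      rq[k] = (uu[k] * (1.0 - uu[k]) * (uu[k] - fa) - vq[k]) * qw[k];
    std::fill(Rf.begin(), Rf.end(), 0.0);
    tb_spread(tb, rq.data(), norm, Rf.data(), n1, nq);
  };

  for (int step = 0; step < nsteps; ++step) {
    double t = step * dt;

    if (moving && t < tstop) {
      double h = std::min(dt, tstop - t);
      for (size_t k = 0; k < nq; ++k) { qx[k] += h * qvx[k]; qy[k] += h * qvy[k]; }
      for (size_t l = 0; l < nnode; ++l) { nx[l] += h * nvx[l]; ny[l] += h * nvy[l]; }
      recompute_weights();
      recompute_mass();
      rebuild_geometry();
      tb_interp(tb, V.data(), n1, uq.data(), nq);
    }

    // recovery variable at quadrature points, frozen over the step
    for (size_t k = 0; k < nq; ++k)
      vq[k] = qbar(k, 0) * yv[qidx(k, 0) - 1] +
              qbar(k, 1) * yv[qidx(k, 1) - 1] +
              qbar(k, 2) * yv[qidx(k, 2) - 1];

    // --- PDE step (TVD-RK3) ---
    reaction(uq.data());
    std::copy(Rf.begin(), Rf.end(), L0.begin());
    add_lap(V.data(), cx, cy, n1, n2, vrest, L0.data());
    for (size_t g = 0; g < ng; ++g) V1[g] = V[g] + dt * L0[g];

    if (per_stage) {
      tb_interp(tb, V1.data(), n1, uq1.data(), nq);
      reaction(uq1.data());
    }
    std::copy(Rf.begin(), Rf.end(), L1.begin());
    add_lap(V1.data(), cx, cy, n1, n2, vrest, L1.data());
    for (size_t g = 0; g < ng; ++g)
      V2[g] = V1[g] + dt * 0.25 * (-3.0 * L0[g] + L1[g]);

    if (per_stage) {
      tb_interp(tb, V2.data(), n1, uq2.data(), nq);
      reaction(uq2.data());
    }
    std::copy(Rf.begin(), Rf.end(), L2v.begin());
    add_lap(V2.data(), cx, cy, n1, n2, vrest, L2v.data());
    for (size_t g = 0; g < ng; ++g)
      V[g] = V2[g] + dt / 12.0 * (-L0[g] - L1[g] + 8.0 * L2v[g]);

    // --- nodal potential (interpolate + lumped L2 projection) ---
    tb_interp(tb, V.data(), n1, uq.data(), nq);
    std::fill(ut.begin(), ut.end(), 0.0);
    for (size_t k = 0; k < nq; ++k) {
      double uw = uq[k] * qw[k];
      ut[qidx(k, 0) - 1] += qbar(k, 0) * uw;
      ut[qidx(k, 1) - 1] += qbar(k, 1) * uw;
      ut[qidx(k, 2) - 1] += qbar(k, 2) * uw;
    }
    for (size_t l = 0; l < nnode; ++l)
      ut[l] = (mlump[l] > 0.0) ? ut[l] / mlump[l] : vrest;

    // --- recovery ODE (TVD-RK3, potential frozen) ---
    for (size_t l = 0; l < nnode; ++l) {
      double fn = feps * (fbeta * ut[l] - fgamma * yv[l] - fsigma);
      f0[l] = fn;
      y1[l] = yv[l] + dt * fn;
    }
    for (size_t l = 0; l < nnode; ++l) {
      f1[l] = feps * (fbeta * ut[l] - fgamma * y1[l] - fsigma);
      y2[l] = y1[l] + dt * 0.25 * (-3.0 * f0[l] + f1[l]);
    }
    for (size_t l = 0; l < nnode; ++l) {
      double f2 = feps * (fbeta * ut[l] - fgamma * y2[l] - fsigma);
      yv[l] = y2[l] + dt / 12.0 * (-f0[l] - f1[l] + 8.0 * f2);
    }

    // --- ghost refresh: far Omega_non cells back to rest ---
    if (refresh_every > 0 && ((step + 1) % refresh_every == 0))
      for (size_t g = 0; g < ng; ++g)
        if (!active[g]) V[g] = vrest;

    double vmax = 0.0;
    for (size_t g = 0; g < ng; ++g)
      vmax = std::max(vmax, std::fabs(V[g] - vrest));
    if (!(vmax < guard))
      stop("gs_run: |V - V_rest| = %g exceeded the blow-up guard %g at t = %g",
           vmax, guard, t + dt);

    for (int p = 0; p < np; ++p) probes(step + 1, p) = V[probe_cells[p]];
    probe_t[step + 1] = (step + 1) * dt;
    maybe_snap(step + 1, (step + 1) * dt);

    if ((step & 255) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix Vout(n1, n2);
  std::copy(V.begin(), V.end(), Vout.begin());
  NumericVector yout(yv.begin(), yv.end());
  NumericMatrix qcur(nq, 2), ncur(nnode, 2);
  for (size_t k = 0; k < nq; ++k) { qcur(k, 0) = qx[k]; qcur(k, 1) = qy[k]; }
  for (size_t l = 0; l < nnode; ++l) { ncur(l, 0) = nx[l]; ncur(l, 1) = ny[l]; }

  return List::create(_["V"] = Vout, _["y"] = yout, _["probes"] = probes,
                      _["probe_times"] = probe_t, _["snapshots"] = snaps,
                      _["snap_times"] = NumericVector(snap_t.begin(), snap_t.end()),
                      _["qp_current"] = qcur, _["nodes_current"] = ncur);
}
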