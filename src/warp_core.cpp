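// Compiled core of the hyperelastic warping registration:
// P1 tetrahedral kinematics, trilinear image sampling, energy/gradient
// assembly and a feasibility-preserving first-order minimizer.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

namespace {

inline double det3(const double F[9]) {
  return F[0] * (F[4] * F[8] - F[5] * F[7])
       - F[1] * (F[3] * F[8] - F[5] * F[6])
       + F[2] * (F[3] * F[7] - F[4] * F[6]);
}

// inverse-transpose of a 3x3 (row-major F[i*3+j] = F_ij)
inline void invT3(const double F[9], double J, double out[9]) {
  const double c00 =  (F[4] * F[8] - F[5] * F[7]);
  const double c01 = -(F[3] * F[8] - F[5] * F[6]);
  const double c02 =  (F[3] * F[7] - F[4] * F[6]);
  const double c10 = -(F[1] * F[8] - F[2] * F[7]);
  const double c11 =  (F[0] * F[8] - F[2] * F[6]);
  const double c12 = -(F[0] * F[7] - F[1] * F[6]);
  const double c20 =  (F[1] * F[5] - F[2] * F[4]);
  const double c21 = -(F[0] * F[5] - F[2] * F[3]);
  const double c22 =  (F[0] * F[4] - F[1] * F[3]);
  // inv(F) = cof(F)^T / J; inv(F)^T = cof(F) / J
  out[0] = c00 / J; out[1] = c01 / J; out[2] = c02 / J;
  out[3] = c10 / J; out[4] = c11 / J; out[5] = c12 / J;
  out[6] = c20 / J; out[7] = c21 / J; out[8] = c22 / J;
}

struct Grid {
  const double *T;
  int nx, ny, nz;
  // world -> voxel affine, row-major 3x4
  double A[12];

  inline void world2vox(const double w[3], double v[3]) const {
    for (int r = 0; r < 3; ++r)
      v[r] = A[4 * r] * w[0] + A[4 * r + 1] * w[1] + A[4 * r + 2] * w[2] + A[4 * r + 3];
  }

  inline double tri(const double *a, double x, double y, double z) const {
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    double fx = x - i0, fy = y - j0, fz = z - k0;
    int i1 = i0 + 1 < nx ? i0 + 1 : nx - 1;
    int j1 = j0 + 1 < ny ? j0 + 1 : ny - 1;
    int k1 = k0 + 1 < nz ? k0 + 1 : nz - 1;
    if (i0 < 0) { i0 = 0; fx = 0; }
    if (j0 < 0) { j0 = 0; fy = 0; }
    if (k0 < 0) { k0 = 0; fz = 0; }
    const long sxy = (long)nx * ny;
    #define AT(i, j, k) a[(i) + nx * (long)(j) + sxy * (k)]
    double c00 = AT(i0, j0, k0) * (1 - fx) + AT(i1, j0, k0) * fx;
    double c10 = AT(i0, j1, k0) * (1 - fx) + AT(i1, j1, k0) * fx;
    double c01 = AT(i0, j0, k1) * (1 - fx) + AT(i1, j0, k1) * fx;
    double c11 = AT(i0, j1, k1) * (1 - fx) + AT(i1, j1, k1) * fx;
    #undef AT
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    return c0 * (1 - fz) + c1 * fz;
  }

  // intensity + world-space gradient; outside the grid -> (0, 0-vector).
  // The gradient is the exact in-cell derivative of the trilinear
  // interpolant, so the assembled energy gradient is the true derivative
  // of the assembled energy.
  inline double sample(const double w[3], double gworld[3]) const {
    double v[3];
    world2vox(w, v);
    if (v[0] < 0 || v[0] > nx - 1 || v[1] < 0 || v[1] > ny - 1 ||
        v[2] < 0 || v[2] > nz - 1) {
      gworld[0] = gworld[1] = gworld[2] = 0.0;
      return 0.0;
    }
    int i0 = (int)std::floor(v[0]), j0 = (int)std::floor(v[1]),
        k0 = (int)std::floor(v[2]);
    double fx = v[0] - i0, fy = v[1] - j0, fz = v[2] - k0;
    int i1 = i0 + 1 < nx ? i0 + 1 : nx - 1;
    int j1 = j0 + 1 < ny ? j0 + 1 : ny - 1;
    int k1 = k0 + 1 < nz ? k0 + 1 : nz - 1;
    if (i0 < 0) { i0 = 0; fx = 0; }
    if (j0 < 0) { j0 = 0; fy = 0; }
    if (k0 < 0) { k0 = 0; fz = 0; }
    const long sxy = (long)nx * ny;
    const double *a = T;
    #define AT(i, j, k) a[(i) + nx * (long)(j) + sxy * (k)]
    const double c000 = AT(i0, j0, k0), c100 = AT(i1, j0, k0);
    const double c010 = AT(i0, j1, k0), c110 = AT(i1, j1, k0);
    const double c001 = AT(i0, j0, k1), c101 = AT(i1, j0, k1);
    const double c011 = AT(i0, j1, k1), c111 = AT(i1, j1, k1);
    #undef AT
    const double wx0 = 1 - fx, wy0 = 1 - fy, wz0 = 1 - fz;
    const double val =
      wz0 * (wy0 * (wx0 * c000 + fx * c100) + fy * (wx0 * c010 + fx * c110)) +
      fz  * (wy0 * (wx0 * c001 + fx * c101) + fy * (wx0 * c011 + fx * c111));
    double gv[3];
    gv[0] = wz0 * (wy0 * (c100 - c000) + fy * (c110 - c010)) +
            fz  * (wy0 * (c101 - c001) + fy * (c111 - c011));
    gv[1] = wz0 * (wx0 * (c010 - c000) + fx * (c110 - c100)) +
            fz  * (wx0 * (c011 - c001) + fx * (c111 - c101));
    gv[2] = wy0 * (wx0 * (c001 - c000) + fx * (c101 - c100)) +
            fy  * (wx0 * (c011 - c010) + fx * (c111 - c110));
    // dT/dworld = (dvox/dworld)^T * dT/dvox, dvox/dworld = A[, 1:3]
    for (int r = 0; r < 3; ++r)
      gworld[r] = A[r] * gv[0] + A[4 + r] * gv[1] + A[8 + r] * gv[2];
    return val;
  }
};

Grid make_grid(const NumericVector &T, const IntegerVector &dim,
               const NumericMatrix &w2v) {
  Grid g;
  g.T = T.begin();
  g.nx = dim[0]; g.ny = dim[1]; g.nz = dim[2];
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 4; ++c) g.A[4 * r + c] = w2v(r, c);
  return g;
}

// Energy and (optionally) gradient of the warping functional at nodal
// displacement u.  Returns false if any element is inverted (J <= 0).
bool energy_grad(const NumericMatrix &nodes, const IntegerMatrix &tets,
                 const NumericMatrix &dndx, const NumericVector &vol,
                 const NumericMatrix &qpw, const NumericMatrix &Rq,
                 const Grid &grid, bool use_image,
                 double C1, double kappa, double gamma,
                 const std::vector<double> &u,
                 double &E, double &Eel, double &Eim,
                 std::vector<double> *g) {
  const int n = nodes.nrow(), m = tets.nrow(), nq = qpw.nrow();
  E = Eel = Eim = 0.0;
  if (g) std::fill(g->begin(), g->end(), 0.0);
  double xd[4][3];
  for (int e = 0; e < m; ++e) {
    int id[4];
    for (int a = 0; a < 4; ++a) {
      id[a] = tets(e, a) - 1;
      for (int c = 0; c < 3; ++c)
        xd[a][c] = nodes(id[a], c) + u[id[a] + (long)n * c];
    }
    // F_ij = sum_a xd[a][i] * dndx[e, a*3 + j]
    double F[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
    for (int a = 0; a < 4; ++a) {
      const double dn0 = dndx(e, a * 3), dn1 = dndx(e, a * 3 + 1), dn2 = dndx(e, a * 3 + 2);
      for (int i = 0; i < 3; ++i) {
        F[i * 3]     += xd[a][i] * dn0;
        F[i * 3 + 1] += xd[a][i] * dn1;
        F[i * 3 + 2] += xd[a][i] * dn2;
      }
    }
    const double J = det3(F);
    if (!(J > 0.0)) return false;
    double I1 = 0.0;
    for (int k = 0; k < 9; ++k) I1 += F[k] * F[k];
    const double Jm23 = std::pow(J, -2.0 / 3.0);
    const double V = vol[e];
    const double W = C1 * (Jm23 * I1 - 3.0) + 0.5 * kappa * (J - 1.0) * (J - 1.0);
    Eel += V * W;
    if (g) {
      double FinvT[9];
      invT3(F, J, FinvT);
      const double cF = 2.0 * C1 * Jm23;
      const double cI = -(2.0 / 3.0) * C1 * Jm23 * I1 + kappa * (J - 1.0) * J;
      double P[9];
      for (int k = 0; k < 9; ++k) P[k] = cF * F[k] + cI * FinvT[k];
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 3; ++i) {
          const double gi = V * (P[i * 3] * dndx(e, a * 3) +
                                 P[i * 3 + 1] * dndx(e, a * 3 + 1) +
                                 P[i * 3 + 2] * dndx(e, a * 3 + 2));
          (*g)[id[a] + (long)n * i] += gi;
        }
    }
    if (use_image) {
      const double wq = V / nq;
      for (int q = 0; q < nq; ++q) {
        double phi[3] = {0, 0, 0};
        for (int a = 0; a < 4; ++a)
          for (int c = 0; c < 3; ++c) phi[c] += qpw(q, a) * xd[a][c];
        double gT[3];
        const double Tval = grid.sample(phi, gT);
        const double err = Rq(e, q) - Tval;
        Eim += 0.5 * gamma * err * err * wq;
        if (g) {
          // d/dphi of 0.5*gamma*(R - T(phi))^2 = -gamma*(R - T)*dT/dphi
          const double f = gamma * err * wq;
          for (int a = 0; a < 4; ++a) {
            const double w = qpw(q, a);
            for (int c = 0; c < 3; ++c)
              (*g)[id[a] + (long)n * c] += f * (-gT[c]) * w;
          }
        }
      }
    }
  }
  E = Eel + Eim;
  return true;
}

inline void project_bc(std::vector<double> &v, int n,
                       const IntegerVector &base, const double l[3],
                       double target, bool is_grad) {
  for (int t = 0; t < base.size(); ++t) {
    const int i = base[t] - 1;
    const double d = v[i] * l[0] + v[i + (long)n] * l[1] + v[i + 2L * n] * l[2];
    const double corr = is_grad ? -d : (target - d);
    v[i] += corr * l[0];
    v[i + (long)n] += corr * l[1];
    v[i + 2L * n] += corr * l[2];
  }
}

} // namespace

// Per-cell shape-function gradients (4x3, row-major per cell) and signed
// volumes of a P1 tetrahedral mesh.
// [[Rcpp::export(name = ".ws_tet_precompute")]]
List ws_tet_precompute(NumericMatrix nodes, IntegerMatrix tets) {
  const int m = tets.nrow();
  NumericMatrix dndx(m, 12);
  NumericVector vol(m);
  for (int e = 0; e < m; ++e) {
    double D[9];
    const int i0 = tets(e, 0) - 1;
    for (int a = 0; a < 3; ++a) {
      const int ia = tets(e, a + 1) - 1;
      for (int c = 0; c < 3; ++c) D[c * 3 + a] = nodes(ia, c) - nodes(i0, c);
    }
    const double J = det3(D);
    vol[e] = J / 6.0;
    double DinvT[9];
    invT3(D, J, DinvT); // DinvT = inv(D)^T, so inv(D)[r][c] = DinvT[c*3+r]
    // grad N_{a+1} = row a of inv(D); grad N_0 = -sum
    double s[3] = {0, 0, 0};
    for (int a = 0; a < 3; ++a)
      for (int c = 0; c < 3; ++c) {
        const double v = DinvT[c * 3 + a];
        dndx(e, (a + 1) * 3 + c) = v;
        s[c] += v;
      }
    for (int c = 0; c < 3; ++c) dndx(e, c) = -s[c];
  }
  return List::create(_["dndx"] = dndx, _["vol"] = vol);
}

// Trilinear interpolation of a 3D array at continuous 0-based voxel
// coordinates; points outside the grid return `outside`.
// [[Rcpp::export(name = ".ws_trilinear")]]
NumericVector ws_trilinear(NumericVector arr, IntegerVector dim,
                           NumericMatrix pts, double outside = 0.0) {
  Grid g;
  g.T = arr.begin();
  g.nx = dim[0]; g.ny = dim[1]; g.nz = dim[2];
  NumericVector out(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i) {
    const double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    if (x < 0 || x > g.nx - 1 || y < 0 || y > g.ny - 1 || z < 0 || z > g.nz - 1)
      out[i] = outside;
    else
      out[i] = g.tri(arr.begin(), x, y, z);
  }
  return out;
}

// Separable Gaussian smoothing with reflected borders; sd in voxel units
// per axis, sd <= 0 leaves the axis untouched.
// [[Rcpp::export(name = ".ws_gauss3")]]
NumericVector ws_gauss3(NumericVector arr, IntegerVector dim, NumericVector sd) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> a(arr.begin(), arr.end()), b(a.size());
  const int n[3] = {nx, ny, nz};
  const long stride[3] = {1, nx, (long)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    if (sd[ax] <= 0) continue;
    const int R = (int)std::ceil(3.0 * sd[ax]);
    std::vector<double> k(2 * R + 1);
    double ks = 0;
    for (int t = -R; t <= R; ++t) {
      k[t + R] = std::exp(-0.5 * t * t / (sd[ax] * sd[ax]));
      ks += k[t + R];
    }
    for (auto &v : k) v /= ks;
    const long s = stride[ax];
    const int len = n[ax];
    const long total = (long)nx * ny * nz;
    for (long base = 0; base < total; ++base) {
      // walk each 1D line once: base must be the first element of its line
      long idx_ax = (base / s) % len;
      if (idx_ax != 0) continue;
      for (int i = 0; i < len; ++i) {
        double acc = 0;
        for (int t = -R; t <= R; ++t) {
          int j = i + t;
          if (j < 0) j = -j - 1;          // reflect
          if (j >= len) j = 2 * len - j - 1;
          acc += k[t + R] * a[base + (long)j * s];
        }
        b[base + (long)i * s] = acc;
      }
    }
    a.swap(b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Central-difference gradient in voxel units (one-sided at borders).
// [[Rcpp::export(name = ".ws_grad3")]]
List ws_grad3(NumericVector arr, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long sxy = (long)nx * ny;
  NumericVector gx(arr.size()), gy(arr.size()), gz(arr.size());
  const double *a = arr.begin();
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const long id = i + nx * (long)j + sxy * k;
        const int ip = i + 1 < nx ? i + 1 : i, im = i > 0 ? i - 1 : i;
        const int jp = j + 1 < ny ? j + 1 : j, jm = j > 0 ? j - 1 : j;
        const int kp = k + 1 < nz ? k + 1 : k, km = k > 0 ? k - 1 : k;
        gx[id] = (a[ip + nx * (long)j + sxy * k] - a[im + nx * (long)j + sxy * k]) / (ip - im);
        gy[id] = (a[i + nx * (long)jp + sxy * k] - a[i + nx * (long)jm + sxy * k]) / (jp - jm);
        gz[id] = (a[i + nx * (long)j + sxy * kp] - a[i + nx * (long)j + sxy * km]) / (kp - km);
      }
  gx.attr("dim") = dim; gy.attr("dim") = dim; gz.attr("dim") = dim;
  return List::create(_["gx"] = gx, _["gy"] = gy, _["gz"] = gz);
}

// Sample intensity and world-space gradient of a presmoothed frame.
// [[Rcpp::export(name = ".ws_sample_grad")]]
List ws_sample_grad(NumericVector T, NumericVector Gx, NumericVector Gy,
                    NumericVector Gz, IntegerVector dim, NumericMatrix w2v,
                    NumericMatrix pts) {
  Grid g = make_grid(T, dim, w2v);
  const int np = pts.nrow();
  NumericVector val(np);
  NumericMatrix grad(np, 3);
  for (int i = 0; i < np; ++i) {
    double vx[3], w[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    g.world2vox(w, vx);
    if (vx[0] < 0 || vx[0] > g.nx - 1 || vx[1] < 0 || vx[1] > g.ny - 1 ||
        vx[2] < 0 || vx[2] > g.nz - 1) {
      val[i] = 0.0;
      continue;
    }
    val[i] = g.tri(T.begin(), vx[0], vx[1], vx[2]);
    double gv[3];
    gv[0] = g.tri(Gx.begin(), vx[0], vx[1], vx[2]);
    gv[1] = g.tri(Gy.begin(), vx[0], vx[1], vx[2]);
    gv[2] = g.tri(Gz.begin(), vx[0], vx[1], vx[2]);
    for (int r = 0; r < 3; ++r)
      grad(i, r) = g.A[r] * gv[0] + g.A[4 + r] * gv[1] + g.A[8 + r] * gv[2];
  }
  return List::create(_["value"] = val, _["gradient"] = grad);
}

// Warping energy and gradient at nodal displacement u (n x 3).
// [[Rcpp::export(name = ".ws_energy")]]
List ws_energy(NumericMatrix nodes, IntegerMatrix tets, NumericMatrix dndx,
               NumericVector vol, NumericMatrix qpw, NumericMatrix Rq,
               NumericVector T, IntegerVector dim, NumericMatrix w2v,
               double C1, double kappa, double gamma, NumericMatrix u,
               bool use_image = true, bool want_grad = true) {
  Grid grid = make_grid(T, dim, w2v);
  const int n = nodes.nrow();
  std::vector<double> uv(u.begin(), u.end());
  std::vector<double> g((long)n * 3);
  double E, Eel, Eim;
  bool ok = energy_grad(nodes, tets, dndx, vol, qpw, Rq, grid, use_image,
                        C1, kappa, gamma, uv, E, Eel, Eim,
                        want_grad ? &g : nullptr);
  NumericMatrix gm(n, 3);
  if (want_grad && ok) std::copy(g.begin(), g.end(), gm.begin());
  return List::create(_["energy"] = ok ? E : R_PosInf,
                      _["elastic"] = ok ? Eel : R_PosInf,
                      _["mismatch"] = ok ? Eim : R_PosInf,
                      _["gradient"] = gm, _["feasible"] = ok);
}

// Per-cell deformation gradients F = d(X+u)/dX for a P1 mesh (m x 9,
// row-major F_ij in column i*3+j).
// [[Rcpp::export(name = ".ws_def_grads")]]
NumericMatrix ws_def_grads(NumericMatrix nodes, IntegerMatrix tets,
                           NumericMatrix dndx, NumericMatrix u) {
  const int m = tets.nrow(), n = nodes.nrow();
  NumericMatrix F(m, 9);
  for (int e = 0; e < m; ++e)
    for (int a = 0; a < 4; ++a) {
      const int id = tets(e, a) - 1;
      for (int i = 0; i < 3; ++i) {
        const double x = nodes(id, i) + u(id, i);
        F(e, i * 3)     += x * dndx(e, a * 3);
        F(e, i * 3 + 1) += x * dndx(e, a * 3 + 1);
        F(e, i * 3 + 2) += x * dndx(e, a * 3 + 2);
      }
    }
  return F;
}
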