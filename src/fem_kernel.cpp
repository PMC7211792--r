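// Plane-strain hyperelastic element kernel for palpation simulation.
//
// Elements are 3-node constant-strain triangles grouped four-per-quadrilateral
// cell around a centre node ("crossed" pattern).  The deviatoric Ogden energy
// is integrated per triangle; near-incompressibility is enforced by a penalty
// on the cell-averaged volume ratio (mean dilatation), which avoids the
// volumetric locking of plain linear triangles.  Units: mm, N, MPa; forces
// are per unit out-of-plane thickness (N/mm).

#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct MatPar {
  double mu1, a1, mu2, a2, kappa;
};

// Deviatoric 2-term Ogden: energy W and first Piola stress P (col-major
// F = [F11, F21, F12, F22]); plane strain, lambda3 = 1.
// Returns false when det(F) <= 0 (inverted element).
bool ogden_dev(const double* F, const MatPar& m, double* P, double& W,
               double& J, double* dJdF) {
  const double F11 = F[0], F21 = F[1], F12 = F[2], F22 = F[3];
  J = F11 * F22 - F12 * F21;
  if (!(J > 1e-12)) return false;
  dJdF[0] = F22; dJdF[1] = -F12; dJdF[2] = -F21; dJdF[3] = F11;

  const double c11 = F11 * F11 + F21 * F21;
  const double c22 = F12 * F12 + F22 * F22;
  const double c12 = F11 * F12 + F21 * F22;
  const double tr = c11 + c22;
  const double D = std::sqrt((c11 - c22) * (c11 - c22) + 4.0 * c12 * c12);
  const double l1sq = 0.5 * (tr + D), l2sq = 0.5 * (tr - D);
  if (!(l2sq > 0.0)) return false;
  const double l1 = std::sqrt(l1sq), l2 = std::sqrt(l2sq);

  const double Jm13 = std::pow(J, -1.0 / 3.0);
  const double lb[3] = {Jm13 * l1, Jm13 * l2, Jm13};

  double g[3];
  W = 0.0;
  for (int k = 0; k < 3; ++k)
    g[k] = 2.0 * m.mu1 / m.a1 * std::pow(lb[k], m.a1 - 1.0) +
           2.0 * m.mu2 / m.a2 * std::pow(lb[k], m.a2 - 1.0);
  W = 2.0 * m.mu1 / (m.a1 * m.a1) *
          (std::pow(lb[0], m.a1) + std::pow(lb[1], m.a1) + std::pow(lb[2], m.a1) - 3.0) +
      2.0 * m.mu2 / (m.a2 * m.a2) *
          (std::pow(lb[0], m.a2) + std::pow(lb[1], m.a2) + std::pow(lb[2], m.a2) - 3.0);

  // dW/dlambda_a, a = 1,2 (lambda3 fixed at 1)
  const double gsum = g[0] * l1 + g[1] * l2 + g[2];
  const double dW1 = Jm13 * (g[0] - gsum / (3.0 * l1));
  const double dW2 = Jm13 * (g[1] - gsum / (3.0 * l2));
  const double b1 = dW1 / l1, b2 = dW2 / l2;  // principal 2nd-PK values

  // Spectral reconstruction of S in the eigenbasis of C
  double S11, S22, S12;
  if (D < 1e-10 * (tr + 1e-30)) {
    S11 = b1; S22 = b1; S12 = 0.0;
  } else {
    double vx = c12, vy = l1sq - c11;
    double vx2 = l1sq - c22, vy2 = c12;
    if (vx2 * vx2 + vy2 * vy2 > vx * vx + vy * vy) { vx = vx2; vy = vy2; }
    const double nrm = std::sqrt(vx * vx + vy * vy);
    if (nrm < 1e-30) { vx = 1.0; vy = 0.0; } else { vx /= nrm; vy /= nrm; }
    S11 = b1 * vx * vx + b2 * vy * vy;
    S22 = b1 * vy * vy + b2 * vx * vx;
    S12 = (b1 - b2) * vx * vy;
  }
  // P = F S
  P[0] = F11 * S11 + F12 * S12;
  P[1] = F21 * S11 + F22 * S12;
  P[2] = F11 * S12 + F12 * S22;
  P[3] = F21 * S12 + F22 * S22;
  return true;
}

// local triangles of a cell: indices into the 5 cell nodes [v0 v1 v2 v3 c]
const int TRI[4][3] = {{0, 1, 4}, {1, 2, 4}, {2, 3, 4}, {3, 0, 4}};

struct CellGeom {
  double G[4][3][2];  // shape-function gradients per triangle per node
  double A[4];        // triangle reference areas
  double Acell;
};

bool cell_geom(const double X[5][2], CellGeom& geo) {
  geo.Acell = 0.0;
  for (int t = 0; t < 4; ++t) {
    const double* p0 = X[TRI[t][0]];
    const double* p1 = X[TRI[t][1]];
    const double* p2 = X[TRI[t][2]];
    const double d1x = p1[0] - p0[0], d1y = p1[1] - p0[1];
    const double d2x = p2[0] - p0[0], d2y = p2[1] - p0[1];
    const double det = d1x * d2y - d2x * d1y;
    if (std::abs(det) < 1e-14) return false;
    geo.A[t] = 0.5 * std::abs(det);
    geo.Acell += geo.A[t];
    // inverse of [d1 d2] maps to gradients
    const double i11 = d2y / det, i12 = -d2x / det;
    const double i21 = -d1y / det, i22 = d1x / det;
    geo.G[t][1][0] = i11; geo.G[t][1][1] = i12;
    geo.G[t][2][0] = i21; geo.G[t][2][1] = i22;
    geo.G[t][0][0] = -i11 - i21; geo.G[t][0][1] = -i12 - i22;
  }
  return true;
}

// deformation gradient of triangle t at local cell displacements uc
static inline void tri_F(const CellGeom& geo, int t, const double* uc,
                         double* F) {
  F[0] = 1.0; F[1] = 0.0; F[2] = 0.0; F[3] = 1.0;
  for (int i = 0; i < 3; ++i) {
    const int n = TRI[t][i];
    const double ux = uc[2 * n], uy = uc[2 * n + 1];
    F[0] += ux * geo.G[t][i][0];
    F[2] += ux * geo.G[t][i][1];
    F[1] += uy * geo.G[t][i][0];
    F[3] += uy * geo.G[t][i][1];
  }
}

// deviatoric residual of triangle t (6-vector over its local dofs)
bool tri_dev_residual(const CellGeom& geo, const MatPar& m, int t,
                      const double* uc, double* rt, double& W, double& J,
                      double* bJ /*dJ/du, 6-vector*/) {
  double F[4], P[4], dJdF[4];
  tri_F(geo, t, uc, F);
  if (!ogden_dev(F, m, P, W, J, dJdF)) return false;
  for (int i = 0; i < 3; ++i) {
    const double gx = geo.G[t][i][0], gy = geo.G[t][i][1];
    rt[2 * i]     = geo.A[t] * (P[0] * gx + P[2] * gy);
    rt[2 * i + 1] = geo.A[t] * (P[1] * gx + P[3] * gy);
    if (bJ) {
      bJ[2 * i]     = dJdF[0] * gx + dJdF[2] * gy;
      bJ[2 * i + 1] = dJdF[1] * gx + dJdF[3] * gy;
    }
  }
  return true;
}

// residual (10-vector) and energy of one cell at local displacements uc
bool cell_residual(const CellGeom& geo, const MatPar* mats, const int* matid,
                   const double* uc, double* r, double& E) {
  double Js[4], Ws[4], rt[4][6], bJ[4][6];
  double Jbar = 0.0, kbar = 0.0;
  for (int t = 0; t < 4; ++t) {
    if (!tri_dev_residual(geo, mats[matid[t]], t, uc, rt[t], Ws[t], Js[t],
                          bJ[t]))
      return false;
    Jbar += geo.A[t] * Js[t];
    kbar += geo.A[t] * mats[matid[t]].kappa;
  }
  Jbar /= geo.Acell;
  kbar /= geo.Acell;
  const double p = kbar * (Jbar - 1.0);

  E = geo.Acell * 0.5 * kbar * (Jbar - 1.0) * (Jbar - 1.0);
  for (int k = 0; k < 10; ++k) r[k] = 0.0;
  for (int t = 0; t < 4; ++t) {
    E += geo.A[t] * Ws[t];
    for (int i = 0; i < 3; ++i) {
      const int n = TRI[t][i];
      r[2 * n]     += rt[t][2 * i]     + p * geo.A[t] * bJ[t][2 * i];
      r[2 * n + 1] += rt[t][2 * i + 1] + p * geo.A[t] * bJ[t][2 * i + 1];
    }
  }
  return true;
}

// cell tangent: finite differences of the (well-scaled) deviatoric triangle
// residuals plus the exact analytic Hessian of the mean-dilatation penalty
// (J is quadratic in u, so its first and second derivatives are closed form)
bool cell_tangent(const CellGeom& geo, const MatPar* mats, const int* matid,
                  const double* uc, double K[10][10]) {
  for (int i = 0; i < 10; ++i)
    for (int j = 0; j < 10; ++j) K[i][j] = 0.0;

  double Js[4], Ws[4], rt0[4][6], bJ[4][6];
  double Jbar = 0.0, kbar = 0.0;
  for (int t = 0; t < 4; ++t) {
    if (!tri_dev_residual(geo, mats[matid[t]], t, uc, rt0[t], Ws[t], Js[t],
                          bJ[t]))
      return false;
    Jbar += geo.A[t] * Js[t];
    kbar += geo.A[t] * mats[matid[t]].kappa;
  }
  Jbar /= geo.Acell;
  kbar /= geo.Acell;
  const double p = kbar * (Jbar - 1.0);

  // deviatoric part: FD per triangle over its 6 local dofs
  double ucp[10], rtp[6], W, J;
  for (int t = 0; t < 4; ++t) {
    for (int k = 0; k < 10; ++k) ucp[k] = uc[k];
    for (int jl = 0; jl < 6; ++jl) {
      const int gj = 2 * TRI[t][jl / 2] + (jl % 2);
      const double h = 1e-7 * (1.0 + std::abs(uc[gj]));
      const double keep = ucp[gj];
      ucp[gj] = keep + h;
      if (!tri_dev_residual(geo, mats[matid[t]], t, ucp, rtp, W, J, nullptr)) {
        ucp[gj] = keep - h;
        if (!tri_dev_residual(geo, mats[matid[t]], t, ucp, rtp, W, J, nullptr))
          return false;
        for (int il = 0; il < 6; ++il) rtp[il] = 2.0 * rt0[t][il] - rtp[il];
      }
      ucp[gj] = keep;
      for (int il = 0; il < 6; ++il) {
        const int gi = 2 * TRI[t][il / 2] + (il % 2);
        K[gi][gj] += (rtp[il] - rt0[t][il]) / h;
      }
    }
  }

  // volumetric part, exact: r_vol = p * sum_t A_t bJ_t with
  // p = kbar*(Jbar-1), Jbar = sum A_t J_t / Acell
  //  K_vol = (kbar/Acell) B B^T + p * sum_t A_t d2J_t,  B = sum_t A_t bJ_t
  double B[10] = {0};
  for (int t = 0; t < 4; ++t)
    for (int il = 0; il < 6; ++il)
      B[2 * TRI[t][il / 2] + (il % 2)] += geo.A[t] * bJ[t][il];
  for (int i = 0; i < 10; ++i)
    for (int j = 0; j < 10; ++j)
      K[i][j] += kbar / geo.Acell * B[i] * B[j];
  // d2J entries: d2J/(du_ix du_jy) = Gix Gjy - Giy Gjx (xx and yy blocks 0)
  for (int t = 0; t < 4; ++t) {
    for (int i = 0; i < 3; ++i) {
      const int gi = TRI[t][i];
      for (int j = 0; j < 3; ++j) {
        const int gj = TRI[t][j];
        const double v = geo.G[t][i][0] * geo.G[t][j][1] -
                         geo.G[t][i][1] * geo.G[t][j][0];
        K[2 * gi][2 * gj + 1] += p * geo.A[t] * v;
        K[2 * gj + 1][2 * gi] += p * geo.A[t] * v;
      }
    }
  }
  return true;
}

}  // namespace

// Assemble global internal-force residual, total strain energy and (optionally)
// the tangent stiffness as triplets, for the crossed-triangle mesh.
//
// coords : N x 2 reference coordinates
// cells  : ncell x 5 node indices (1-based): corners CCW then centre
// cellmat: ncell x 4 material index (1-based) per triangle
// mats   : nmat x 5 (mu1, alpha1, mu2, alpha2, kappa)
// u      : 2N displacements, interleaved (x1, y1, x2, y2, ...)
// [[Rcpp::export]]
List fem_assemble(const NumericMatrix& coords, const IntegerMatrix& cells,
                  const IntegerMatrix& cellmat, const NumericMatrix& mats,
                  const NumericVector& u, bool want_tangent) {
  const int ncell = cells.nrow();
  const int N = coords.nrow();
  const int nmat = mats.nrow();
  std::vector<MatPar> mp(nmat);
  for (int k = 0; k < nmat; ++k)
    mp[k] = {mats(k, 0), mats(k, 1), mats(k, 2), mats(k, 3), mats(k, 4)};

  NumericVector res(2 * N);
  double Etot = 0.0;
  bool ok = true;

  std::vector<int> Ti, Tj;
  std::vector<double> Tv;
  if (want_tangent) {
    Ti.reserve((size_t)ncell * 100);
    Tj.reserve((size_t)ncell * 100);
    Tv.reserve((size_t)ncell * 100);
  }

  double X[5][2], uc[10], r0[10], Kc[10][10];
  int matid[4], gdof[10];
  CellGeom geo;

  for (int c = 0; c < ncell && ok; ++c) {
    for (int i = 0; i < 5; ++i) {
      const int n = cells(c, i) - 1;
      X[i][0] = coords(n, 0);
      X[i][1] = coords(n, 1);
      uc[2 * i] = u[2 * n];
      uc[2 * i + 1] = u[2 * n + 1];
      gdof[2 * i] = 2 * n;
      gdof[2 * i + 1] = 2 * n + 1;
    }
    for (int t = 0; t < 4; ++t) matid[t] = cellmat(c, t) - 1;
    if (!cell_geom(X, geo)) { ok = false; break; }
    double Ec;
    if (!cell_residual(geo, mp.data(), matid, uc, r0, Ec)) { ok = false; break; }
    Etot += Ec;
    for (int k = 0; k < 10; ++k) res[gdof[k]] += r0[k];

    if (want_tangent) {
      if (!cell_tangent(geo, mp.data(), matid, uc, Kc)) { ok = false; break; }
      for (int j = 0; j < 10; ++j)
        for (int i = 0; i < 10; ++i) {
          Ti.push_back(gdof[i] + 1);
          Tj.push_back(gdof[j] + 1);
          Tv.push_back(Kc[i][j]);
        }
    }
  }

  List out = List::create(_["ok"] = ok, _["energy"] = Etot, _["residual"] = res);
  if (want_tangent) {
    out["ki"] = IntegerVector(Ti.begin(), Ti.end());
    out["kj"] = IntegerVector(Tj.begin(), Tj.end());
    out["kv"] = NumericVector(Tv.begin(), Tv.end());
  }
  return out;
}
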