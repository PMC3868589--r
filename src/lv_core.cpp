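// Compiled kernels for the quasi-static nonlinear FE engine:
//  - 8-node hexahedra (collapsed at the apex) with mean-dilatation (Q1P0)
//    volumetric treatment to avoid locking near incompressibility
//  - isochoric two-term Ogden matrix (spectral form) + uniaxial fiber
//    reinforcement (myofiber/collagen rebar by volume fraction)
//  - follower cavity pressure on the endocardium with its load stiffness
//  - linear elastic foundation on the epicardium (reference normals)
//  - divergence-theorem cavity volume with a virtual base lid
// Units: mm, kPa, ml (1 ml = 1000 mm^3).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

static const double GP = 0.5773502691896258;
static const int SX[8] = {-1, 1, 1, -1, -1, 1, 1, -1};
static const int SY[8] = {-1, -1, 1, 1, -1, -1, 1, 1};
static const int SZ[8] = {-1, -1, -1, -1, 1, 1, 1, 1};

static void shape_hex(double xi, double et, double ze,
                      double N[8], double dN[8][3]) {
  for (int a = 0; a < 8; ++a) {
    const double x1 = 1.0 + SX[a] * xi;
    const double y1 = 1.0 + SY[a] * et;
    const double z1 = 1.0 + SZ[a] * ze;
    N[a] = 0.125 * x1 * y1 * z1;
    dN[a][0] = 0.125 * SX[a] * y1 * z1;
    dN[a][1] = 0.125 * SY[a] * x1 * z1;
    dN[a][2] = 0.125 * SZ[a] * x1 * y1;
  }
}

// bilinear quad, nodes (-1,-1),(1,-1),(1,1),(-1,1)
static const int QX[4] = {-1, 1, 1, -1};
static const int QY[4] = {-1, -1, 1, 1};
static void shape_quad(double xi, double et, double N[4], double dN[4][2]) {
  for (int a = 0; a < 4; ++a) {
    N[a] = 0.25 * (1.0 + QX[a] * xi) * (1.0 + QY[a] * et);
    dN[a][0] = 0.25 * QX[a] * (1.0 + QY[a] * et);
    dN[a][1] = 0.25 * QY[a] * (1.0 + QX[a] * xi);
  }
}

// Kirchhoff stress tau and spatial tangent cc[i][j][k][l] (tau-form, for
// reference-volume assembly) of the isochoric Ogden part.
static bool material_point(const arma::mat33& F,
                           double mu1, double mu2, double al1, double al2,
                           arma::mat33& tau, double cc[3][3][3][3],
                           bool wantC) {
  const arma::mat33 b = F * F.t();
  arma::vec3 lam2;
  arma::mat33 nv;
  if (!arma::eig_sym(lam2, nv, b)) return false;
  if (lam2.min() <= 0.0) return false;

  const double mu[2] = {mu1, mu2};
  const double al[2] = {al1, al2};
  arma::vec3 eps;
  for (int i = 0; i < 3; ++i) eps(i) = 0.5 * std::log(lam2(i));
  const double ebar = (eps(0) + eps(1) + eps(2)) / 3.0;

  arma::vec3 tprin(arma::fill::zeros);
  arma::mat33 D(arma::fill::zeros);
  for (int p = 0; p < 2; ++p) {
    arma::vec3 x;
    for (int i = 0; i < 3; ++i) x(i) = std::exp(al[p] * (eps(i) - ebar));
    const double sx = x(0) + x(1) + x(2);
    for (int i = 0; i < 3; ++i) tprin(i) += mu[p] * (x(i) - sx / 3.0);
    if (wantC) {
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double d = (i == j) ? x(i) : 0.0;
          D(i, j) += mu[p] * al[p] * (d - (x(i) + x(j)) / 3.0 + sx / 9.0);
        }
    }
  }

  tau.zeros();
  for (int a = 0; a < 3; ++a)
    tau += tprin(a) * (nv.col(a) * nv.col(a).t());

  if (wantC) {
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        for (int k = 0; k < 3; ++k)
          for (int l = 0; l < 3; ++l) cc[i][j][k][l] = 0.0;
    // principal aabb block
    for (int a = 0; a < 3; ++a)
      for (int bb = 0; bb < 3; ++bb) {
        double coef = D(a, bb) - ((a == bb) ? 2.0 * tprin(a) : 0.0);
        if (coef == 0.0) continue;
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j)
            for (int k = 0; k < 3; ++k)
              for (int l = 0; l < 3; ++l)
                cc[i][j][k][l] +=
                    coef * nv(i, a) * nv(j, a) * nv(k, bb) * nv(l, bb);
      }
    // shear (a!=b) blocks, with the coincident-stretch limit
    const double scale = std::max(lam2.max(), 1e-30);
    for (int a = 0; a < 3; ++a)
      for (int bb = a + 1; bb < 3; ++bb) {
        double g;
        if (std::fabs(lam2(a) - lam2(bb)) > 1e-7 * scale) {
          g = (tprin(a) * lam2(bb) - tprin(bb) * lam2(a)) /
              (lam2(a) - lam2(bb));
        } else {
          g = 0.5 * (D(a, a) - D(a, bb)) - tprin(a);
        }
        if (g == 0.0) continue;
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j)
            for (int k = 0; k < 3; ++k)
              for (int l = 0; l < 3; ++l) {
                const double t1 = nv(i, a) * nv(j, bb) *
                                  (nv(k, a) * nv(l, bb) + nv(k, bb) * nv(l, a));
                const double t2 = nv(i, bb) * nv(j, a) *
                                  (nv(k, bb) * nv(l, a) + nv(k, a) * nv(l, bb));
                cc[i][j][k][l] += g * (t1 + t2);
              }
      }
  }

  return true;
}

// Uniaxial fiber family (rebar): Kirchhoff stress of a linear reinforcement
// whose strain reference is the configuration with fiber vector a_r = F_ref f0
// (a_r = f0 itself for a family anchored to the stress-free reference).  With
// a = F f0 and eps = (|a|^2 - |a_r|^2) / (2 |a_r|^2):
//   tau += vfE * eps * (a x a) / |a_r|^2,
//   cc  += vfE * (a x a x a x a) / |a_r|^4.
static void fiber_point(const arma::vec3& a, const arma::vec3& a_r,
                        double vfE, arma::mat33& tau, double cc[3][3][3][3],
                        bool wantC) {
  const double r2 = arma::dot(a_r, a_r);
  const double epsf = 0.5 * (arma::dot(a, a) - r2) / r2;
  tau += (vfE * epsf / r2) * (a * a.t());
  if (wantC) {
    const double c0 = vfE / (r2 * r2);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        for (int k = 0; k < 3; ++k)
          for (int l = 0; l < 3; ++l)
            cc[i][j][k][l] += c0 * a(i) * a(j) * a(k) * a(l);
  }
}

// Voigt order 11,22,33,12,23,13 (engineering shear in B)
static void fill_B(const double g[8][3], mat& B) {
  B.zeros();
  for (int a = 0; a < 8; ++a) {
    const int c = 3 * a;
    B(0, c + 0) = g[a][0];
    B(1, c + 1) = g[a][1];
    B(2, c + 2) = g[a][2];
    B(3, c + 0) = g[a][1];
    B(3, c + 1) = g[a][0];
    B(4, c + 1) = g[a][2];
    B(4, c + 2) = g[a][1];
    B(5, c + 0) = g[a][2];
    B(5, c + 2) = g[a][0];
  }
}

static void cc_to_voigt(const double cc[3][3][3][3], mat& Dm) {
  static const int VI[6] = {0, 1, 2, 0, 1, 0};
  static const int VJ[6] = {0, 1, 2, 1, 2, 2};
  for (int I = 0; I < 6; ++I)
    for (int J = 0; J < 6; ++J)
      Dm(I, J) = cc[VI[I]][VJ[I]][VI[J]][VJ[J]];
}

// u_ref: displacement field defining the strain reference of the ACTIVE
// myofiber family (time-varying elastance stiffens about the configuration
// at the start of the current time step); collagen is always anchored to the
// stress-free reference.
// [[Rcpp::export]]
List lv_assemble_cpp(const arma::mat& X, const arma::vec& u,
                     const arma::vec& u_ref,
                     const IntegerMatrix& conn,
                     const arma::mat& fmyo, const arma::mat& fcol,
                     double mu1, double mu2, double al1, double al2,
                     double Kbulk, double EfMyo, double vfMyo,
                     double EfCol, double vfCol,
                     const IntegerMatrix& endo, double p,
                     const IntegerMatrix& epif, double Kf,
                     bool want_tangent) {
  const int nn = X.n_rows;
  const int ne = conn.nrow();
  const int ndof = 3 * nn;
  vec R(ndof, arma::fill::zeros);
  vec Fpress(ndof, arma::fill::zeros);

  std::vector<int> TI, TJ;
  std::vector<double> TX;
  if (want_tangent) {
    const size_t cap = (size_t)ne * 576 + (size_t)endo.nrow() * 144 +
                       (size_t)epif.nrow() * 144;
    TI.reserve(cap);
    TJ.reserve(cap);
    TX.reserve(cap);
  }

  bool ok = true;
  double minJ = arma::datum::inf;
  double jbar_min = arma::datum::inf, jbar_max = -arma::datum::inf;
  double vol_scale_sq = 0.0;  // roundoff scale of the volumetric force

  // precomputed 2x2x2 Gauss shape data
  double Ng[8][8], dNg[8][8][3];
  for (int q = 0; q < 8; ++q)
    shape_hex(GP * SX[q], GP * SY[q], GP * SZ[q], Ng[q], dNg[q]);

  mat B(6, 24), Dm(6, 6), Ke(24, 24);
  double cc[3][3][3][3];

  for (int e = 0; e < ne && ok; ++e) {
    int nd[8];
    double Xe[8][3], xe[8][3], xr[8][3];
    for (int a = 0; a < 8; ++a) {
      nd[a] = conn(e, a) - 1;
      for (int i = 0; i < 3; ++i) {
        Xe[a][i] = X(nd[a], i);
        xe[a][i] = Xe[a][i] + u(3 * nd[a] + i);
        xr[a][i] = Xe[a][i] + u_ref(3 * nd[a] + i);
      }
    }

    // pass 1: kinematics at all qps + element dilatation
    arma::mat33 Fq[8], Frq[8];
    double detJ0[8], detJx[8], g[8][8][3];
    double Ve = 0.0, ve = 0.0;
    for (int q = 0; q < 8; ++q) {
      arma::mat33 J0(arma::fill::zeros), Jx(arma::fill::zeros),
          Jr(arma::fill::zeros);
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int k = 0; k < 3; ++k) {
            J0(i, k) += Xe[a][i] * dNg[q][a][k];
            Jx(i, k) += xe[a][i] * dNg[q][a][k];
            Jr(i, k) += xr[a][i] * dNg[q][a][k];
          }
      detJ0[q] = arma::det(J0);
      detJx[q] = arma::det(Jx);
      if (detJ0[q] <= 0.0 || detJx[q] <= 0.0) { ok = false; break; }
      const arma::mat33 Jxi = arma::inv(Jx);
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i) {
          double s = 0.0;
          for (int k = 0; k < 3; ++k) s += dNg[q][a][k] * Jxi(k, i);
          g[q][a][i] = s;
        }
      const arma::mat33 J0i = arma::inv(J0);
      Fq[q] = Jx * J0i;
      Frq[q] = Jr * J0i;
      const double Jdet = detJx[q] / detJ0[q];
      if (Jdet < minJ) minJ = Jdet;
      Ve += detJ0[q];
      ve += detJx[q];
    }
    if (!ok) break;

    const double Jbar = ve / Ve;
    const double pbar = Kbulk * (Jbar - 1.0);
    if (Jbar < jbar_min) jbar_min = Jbar;
    if (Jbar > jbar_max) jbar_max = Jbar;

    // discrete gradient of the deformed element volume: G[3a+i] = dv_e/du_{a,i}
    vec Gv(24, arma::fill::zeros);
    for (int q = 0; q < 8; ++q)
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i) Gv(3 * a + i) += detJx[q] * g[q][a][i];

    vec fe(24, arma::fill::zeros);
    if (want_tangent) Ke.zeros();

    for (int q = 0; q < 8; ++q) {
      arma::mat33 tau;
      if (!material_point(Fq[q], mu1, mu2, al1, al2, tau, cc, want_tangent)) {
        ok = false;
        break;
      }
      if (vfMyo * EfMyo > 0.0) {
        const arma::vec3 fm = fmyo.row(e * 8 + q).t();
        fiber_point(Fq[q] * fm, Frq[q] * fm, vfMyo * EfMyo, tau, cc,
                    want_tangent);
      }
      if (vfCol * EfCol > 0.0) {
        const arma::vec3 fc = fcol.row(e * 8 + q).t();
        fiber_point(Fq[q] * fc, fc, vfCol * EfCol, tau, cc, want_tangent);
      }
      // internal force (isochoric + fiber part)
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i) {
          double s = 0.0;
          for (int j = 0; j < 3; ++j) s += tau(i, j) * g[q][a][j];
          fe(3 * a + i) += detJ0[q] * s;
        }
      if (want_tangent) {
        fill_B(g[q], B);
        cc_to_voigt(cc, Dm);
        Ke += detJ0[q] * (B.t() * Dm * B);
        // geometric stiffness of the isochoric+fiber stress
        for (int a = 0; a < 8; ++a)
          for (int bb = 0; bb < 8; ++bb) {
            double s = 0.0;
            for (int i = 0; i < 3; ++i)
              for (int j = 0; j < 3; ++j)
                s += g[q][a][i] * tau(i, j) * g[q][bb][j];
            s *= detJ0[q];
            for (int i = 0; i < 3; ++i) Ke(3 * a + i, 3 * bb + i) += s;
          }
        // second variation of v_e (volumetric geometric term), times pbar
        for (int a = 0; a < 8; ++a)
          for (int bb = 0; bb < 8; ++bb)
            for (int i = 0; i < 3; ++i)
              for (int j = 0; j < 3; ++j)
                Ke(3 * a + i, 3 * bb + j) +=
                    pbar * detJx[q] *
                    (g[q][a][i] * g[q][bb][j] - g[q][bb][i] * g[q][a][j]);
      }
    }
    if (!ok) break;

    // mean-dilatation volumetric force + rank-one stiffness
    fe += pbar * Gv;
    vol_scale_sq += Kbulk * Kbulk * arma::dot(Gv, Gv);
    if (want_tangent) Ke += (Kbulk / Ve) * (Gv * Gv.t());

    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) R(3 * nd[a] + i) += fe(3 * a + i);
    if (want_tangent) {
      for (int a = 0; a < 24; ++a)
        for (int bb = 0; bb < 24; ++bb) {
          TI.push_back(3 * nd[a / 3] + a % 3 + 1);
          TJ.push_back(3 * nd[bb / 3] + bb % 3 + 1);
          TX.push_back(Ke(a, bb));
        }
    }
  }

  // follower cavity pressure on endocardial faces (current configuration).
  // Note: tangent triplets are emitted even at p = 0 so the sparsity
  // pattern is independent of the load level (it is cached by the caller).
  if (ok && (p != 0.0 || want_tangent)) {
    double Nq[4], dNq[4][2];
    for (int f = 0; f < endo.nrow(); ++f) {
      int nd4[4];
      double xf[4][3];
      for (int a = 0; a < 4; ++a) {
        nd4[a] = endo(f, a) - 1;
        for (int i = 0; i < 3; ++i)
          xf[a][i] = X(nd4[a], i) + u(3 * nd4[a] + i);
      }
      for (int q = 0; q < 4; ++q) {
        shape_quad(GP * QX[q], GP * QY[q], Nq, dNq);
        arma::vec3 tx(arma::fill::zeros), te(arma::fill::zeros);
        for (int a = 0; a < 4; ++a)
          for (int i = 0; i < 3; ++i) {
            tx(i) += dNq[a][0] * xf[a][i];
            te(i) += dNq[a][1] * xf[a][i];
          }
        const arma::vec3 nv = arma::cross(tx, te);
        for (int a = 0; a < 4; ++a)
          for (int i = 0; i < 3; ++i) {
            const double val = p * Nq[a] * nv(i);
            R(3 * nd4[a] + i) -= val;
            Fpress(3 * nd4[a] + i) += val;
          }
        if (want_tangent) {
          for (int a = 0; a < 4; ++a)
            for (int bb = 0; bb < 4; ++bb)
              for (int j = 0; j < 3; ++j) {
                arma::vec3 ej(arma::fill::zeros);
                ej(j) = 1.0;
                const arma::vec3 dn =
                    dNq[bb][0] * arma::cross(ej, te) +
                    dNq[bb][1] * arma::cross(tx, ej);
                for (int i = 0; i < 3; ++i) {
                  TI.push_back(3 * nd4[a] + i + 1);
                  TJ.push_back(3 * nd4[bb] + j + 1);
                  TX.push_back(-p * Nq[a] * dn(i));
                }
              }
        }
      }
    }
  }

  // epicardial elastic foundation: t = -Kf (u.n0) n0 on reference geometry
  if (ok && (Kf > 0.0 || want_tangent)) {
    double Nq[4], dNq[4][2];
    for (int f = 0; f < epif.nrow(); ++f) {
      int nd4[4];
      double Xf[4][3], uf[4][3];
      for (int a = 0; a < 4; ++a) {
        nd4[a] = epif(f, a) - 1;
        for (int i = 0; i < 3; ++i) {
          Xf[a][i] = X(nd4[a], i);
          uf[a][i] = u(3 * nd4[a] + i);
        }
      }
      for (int q = 0; q < 4; ++q) {
        shape_quad(GP * QX[q], GP * QY[q], Nq, dNq);
        arma::vec3 tx(arma::fill::zeros), te(arma::fill::zeros),
            ug(arma::fill::zeros);
        for (int a = 0; a < 4; ++a)
          for (int i = 0; i < 3; ++i) {
            tx(i) += dNq[a][0] * Xf[a][i];
            te(i) += dNq[a][1] * Xf[a][i];
            ug(i) += Nq[a] * uf[a][i];
          }
        arma::vec3 nv = arma::cross(tx, te);
        const double dA = arma::norm(nv);
        if (dA <= 0.0) continue;
        nv /= dA;
        const double un = arma::dot(ug, nv);
        for (int a = 0; a < 4; ++a)
          for (int i = 0; i < 3; ++i)
            R(3 * nd4[a] + i) += dA * Kf * un * Nq[a] * nv(i);
        if (want_tangent) {
          for (int a = 0; a < 4; ++a)
            for (int bb = 0; bb < 4; ++bb)
              for (int i = 0; i < 3; ++i)
                for (int j = 0; j < 3; ++j) {
                  TI.push_back(3 * nd4[a] + i + 1);
                  TJ.push_back(3 * nd4[bb] + j + 1);
                  TX.push_back(dA * Kf * Nq[a] * Nq[bb] * nv(i) * nv(j));
                }
        }
      }
    }
  }

  return List::create(
      _["ok"] = ok, _["resid"] = R, _["fpress"] = Fpress,
      _["vol_scale"] = std::sqrt(vol_scale_sq),
      _["min_J"] = minJ, _["jbar_range"] = NumericVector::create(jbar_min, jbar_max),
      _["i"] = IntegerVector(TI.begin(), TI.end()),
      _["j"] = IntegerVector(TJ.begin(), TJ.end()),
      _["x"] = NumericVector(TX.begin(), TX.end()));
}

// Enclosed cavity volume: divergence theorem over the (deformed) endocardial
// quads, closed by a fan of triangles from the base ring to a fixed lid apex.
// Face orientation: quad normals point out of the cavity (into the wall).
// [[Rcpp::export]]
double lv_cavity_volume_cpp(const arma::mat& X, const arma::vec& u,
                            const IntegerMatrix& endo,
                            const IntegerVector& ring,
                            const arma::vec& apex) {
  double V = 0.0;
  double Nq[4], dNq[4][2];
  for (int f = 0; f < endo.nrow(); ++f) {
    double xf[4][3];
    for (int a = 0; a < 4; ++a) {
      const int nd = endo(f, a) - 1;
      for (int i = 0; i < 3; ++i) xf[a][i] = X(nd, i) + u(3 * nd + i);
    }
    for (int q = 0; q < 4; ++q) {
      shape_quad(GP * QX[q], GP * QY[q], Nq, dNq);
      arma::vec3 xg(arma::fill::zeros), tx(arma::fill::zeros),
          te(arma::fill::zeros);
      for (int a = 0; a < 4; ++a)
        for (int i = 0; i < 3; ++i) {
          xg(i) += Nq[a] * xf[a][i];
          tx(i) += dNq[a][0] * xf[a][i];
          te(i) += dNq[a][1] * xf[a][i];
        }
      V += arma::dot(xg, arma::cross(tx, te)) / 3.0;
    }
  }
  // virtual lid: triangles (r_k, r_{k+1}, apex); tet-volume form
  const int m = ring.size();
  const arma::vec3 c0 = apex;
  for (int k = 0; k < m; ++k) {
    const int i1 = ring[k] - 1;
    const int i2 = ring[(k + 1) % m] - 1;
    arma::vec3 p1, p2;
    for (int i = 0; i < 3; ++i) {
      p1(i) = X(i1, i) + u(3 * i1 + i);
      p2(i) = X(i2, i) + u(3 * i2 + i);
    }
    V += arma::dot(p1, arma::cross(p2, c0)) / 6.0;
  }
  return V / 1000.0;  // mm^3 -> ml
}

// Reference quadrature volumes per element (ml) and the minimum detJ0 over
// all quadrature points (mm^3), for mesh quality checks.
// [[Rcpp::export]]
List lv_hex_volumes_cpp(const arma::mat& X, const IntegerMatrix& conn) {
  const int ne = conn.nrow();
  NumericVector vol(ne);
  double minJ = arma::datum::inf;
  double Ng[8][8], dNg[8][8][3];
  for (int q = 0; q < 8; ++q)
    shape_hex(GP * SX[q], GP * SY[q], GP * SZ[q], Ng[q], dNg[q]);
  for (int e = 0; e < ne; ++e) {
    double Xe[8][3];
    for (int a = 0; a < 8; ++a) {
      const int nd = conn(e, a) - 1;
      for (int i = 0; i < 3; ++i) Xe[a][i] = X(nd, i);
    }
    double v = 0.0;
    for (int q = 0; q < 8; ++q) {
      arma::mat33 J0(arma::fill::zeros);
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int k = 0; k < 3; ++k) J0(i, k) += Xe[a][i] * dNg[q][a][k];
      const double d = arma::det(J0);
      if (d < minJ) minJ = d;
      v += d;
    }
    vol[e] = v / 1000.0;
  }
  return List::create(_["volumes"] = vol, _["min_detJ"] = minJ);
}

// Per-element mean dilatation Jbar at a displaced state (diagnostic/export).
// [[Rcpp::export]]
NumericVector lv_jbar_cpp(const arma::mat& X, const arma::vec& u,
                          const IntegerMatrix& conn) {
  const int ne = conn.nrow();
  NumericVector out(ne);
  double Ng[8][8], dNg[8][8][3];
  for (int q = 0; q < 8; ++q)
    shape_hex(GP * SX[q], GP * SY[q], GP * SZ[q], Ng[q], dNg[q]);
  for (int e = 0; e < ne; ++e) {
    double Xe[8][3], xe[8][3];
    for (int a = 0; a < 8; ++a) {
      const int nd = conn(e, a) - 1;
      for (int i = 0; i < 3; ++i) {
        Xe[a][i] = X(nd, i);
        xe[a][i] = Xe[a][i] + u(3 * nd + i);
      }
    }
    double V0 = 0.0, v1 = 0.0;
    for (int q = 0; q < 8; ++q) {
      arma::mat33 J0(arma::fill::zeros), Jx(arma::fill::zeros);
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int k = 0; k < 3; ++k) {
            J0(i, k) += Xe[a][i] * dNg[q][a][k];
            Jx(i, k) += xe[a][i] * dNg[q][a][k];
          }
      V0 += arma::det(J0);
      v1 += arma::det(Jx);
    }
    out[e] = v1 / V0;
  }
  return out;
}

// Accumulate triplet values into the compressed numeric slot of the cached
// sparsity pattern: out[map[k]-1] += x[k].
// [[Rcpp::export]]
NumericVector lv_accum_cpp(const NumericVector& x, const IntegerVector& map,
                           int n) {
  NumericVector out(n);
  for (R_xlen_t k = 0; k < x.size(); ++k) out[map[k] - 1] += x[k];
  return out;
}
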