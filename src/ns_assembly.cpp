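#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Stabilized P1/P1 ALE Navier-Stokes residual and tangent on triangles.
//
// Unknown layout: node k (0-based) owns dofs 3k (u_x), 3k+1 (u_y), 3k+2 (p).
// The residual is evaluated at the generalized-alpha intermediate levels:
// `u` is the velocity at n+alpha_f, `udot` the acceleration at n+alpha_m,
// `p` the pressure at n+1, all on the n+alpha_f mesh configuration with
// mesh velocity `umesh`.  The tangent is taken with respect to the solver
// unknowns (the end-of-step accelerations and pressures): fac_a = dudot/dv,
// fac_u = du/dv fold the time-integrator chain rule into the kernel, so a
// steady solve is fac_a = 0, fac_u = 1 with dt <= 0 dropping the transient
// term from tau.
//
// Stabilization: SUPG/PSPG with the element metric tensor G, plus grad-div
// (LSIC) with tau_C = 1/(tau_M tr G).  tau is frozen at the element centroid
// convective velocity; its derivative is omitted from the tangent (standard
// practice; Newton still converges quadratically in the tested regimes).

// [[Rcpp::export(name = ".cpp_ns_assemble")]]
List cpp_ns_assemble(NumericMatrix coords, IntegerMatrix tri,
                     NumericMatrix u, NumericMatrix udot, NumericVector p,
                     NumericMatrix umesh, NumericMatrix fq,
                     double rho, double mu, double dt,
                     double fac_a, double fac_u, double ci,
                     bool lsic, bool want_jac) {
  const int nn = coords.nrow(), ne = tri.nrow();
  const double nu = mu / rho;
  NumericVector res(3 * nn);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  if (want_jac) { ti.reserve(81 * ne); tj.reserve(81 * ne); tx.reserve(81 * ne); }

  // reference-element shape values at the 3 edge-midpoint quad points
  const double NQ[3][3] = {{0.5, 0.5, 0.0}, {0.0, 0.5, 0.5}, {0.5, 0.0, 0.5}};

  for (int e = 0; e < ne; ++e) {
    const int n0 = tri(e, 0) - 1, n1 = tri(e, 1) - 1, n2 = tri(e, 2) - 1;
    const int nd[3] = {n0, n1, n2};
    const double x1 = coords(n0, 0), y1 = coords(n0, 1);
    const double x2 = coords(n1, 0), y2 = coords(n1, 1);
    const double x3 = coords(n2, 0), y3 = coords(n2, 1);
    const double det = (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1);
    if (det <= 0.0)
      stop("assembly abort: inverted or degenerate element %d (det J = %g)",
           e + 1, det);
    const double A = 0.5 * det;
    // inverse Jacobian rows: dxi_k/dx_j
    const double ji[2][2] = {{(y3 - y1) / det, -(x3 - x1) / det},
                             {-(y2 - y1) / det, (x2 - x1) / det}};
    double dN[3][2];
    dN[1][0] = ji[0][0]; dN[1][1] = ji[0][1];
    dN[2][0] = ji[1][0]; dN[2][1] = ji[1][1];
    dN[0][0] = -dN[1][0] - dN[2][0];
    dN[0][1] = -dN[1][1] - dN[2][1];
    // element metric tensor G_ab = sum_k ji[k][a] ji[k][b]
    double G[2][2] = {{0, 0}, {0, 0}};
    for (int k = 0; k < 2; ++k)
      for (int a = 0; a < 2; ++a)
        for (int b = 0; b < 2; ++b) G[a][b] += ji[k][a] * ji[k][b];
    const double trG = G[0][0] + G[1][1];
    const double GG = G[0][0] * G[0][0] + 2.0 * G[0][1] * G[0][1] +
                      G[1][1] * G[1][1];

    // element-constant gradients
    double gradu[2][2] = {{0, 0}, {0, 0}}, gradp[2] = {0, 0};
    for (int i = 0; i < 3; ++i) {
      const int n = nd[i];
      for (int d = 0; d < 2; ++d)
        for (int a = 0; a < 2; ++a) gradu[d][a] += dN[i][a] * u(n, d);
      gradp[0] += dN[i][0] * p[n];
      gradp[1] += dN[i][1] * p[n];
    }
    const double divu = gradu[0][0] + gradu[1][1];

    // centroid convective velocity for tau
    double cc[2] = {0, 0};
    for (int i = 0; i < 3; ++i) {
      const int n = nd[i];
      cc[0] += (u(n, 0) - umesh(n, 0)) / 3.0;
      cc[1] += (u(n, 1) - umesh(n, 1)) / 3.0;
    }
    const double cGc = cc[0] * (G[0][0] * cc[0] + G[0][1] * cc[1]) +
                       cc[1] * (G[1][0] * cc[0] + G[1][1] * cc[1]);
    double tden = cGc + ci * nu * nu * GG;
    if (dt > 0.0) tden += 4.0 / (dt * dt);
    const double tauM = (tden > 0.0) ? 1.0 / std::sqrt(tden) : 0.0;
    const double tauC = (lsic && tauM > 0.0) ? 1.0 / (tauM * trG) : 0.0;

    double Ke[9][9];
    if (want_jac)
      for (int a = 0; a < 9; ++a)
        for (int b = 0; b < 9; ++b) Ke[a][b] = 0.0;

    const double w = A / 3.0;
    for (int q = 0; q < 3; ++q) {
      const double* N = NQ[q];
      double uq[2] = {0, 0}, aq[2] = {0, 0}, cq[2] = {0, 0};
      for (int i = 0; i < 3; ++i) {
        const int n = nd[i];
        for (int d = 0; d < 2; ++d) {
          uq[d] += N[i] * u(n, d);
          aq[d] += N[i] * udot(n, d);
          cq[d] += N[i] * (u(n, d) - umesh(n, d));
        }
      }
      double pq = N[0] * p[n0] + N[1] * p[n1] + N[2] * p[n2];
      const double fqv[2] = {fq(e, 2 * q), fq(e, 2 * q + 1)};
      double conv[2], rM[2];
      for (int d = 0; d < 2; ++d) {
        conv[d] = cq[0] * gradu[d][0] + cq[1] * gradu[d][1];
        rM[d] = rho * (aq[d] + conv[d]) + gradp[d] - fqv[d];
      }
      double cdN[3];
      for (int i = 0; i < 3; ++i)
        cdN[i] = cq[0] * dN[i][0] + cq[1] * dN[i][1];

      for (int i = 0; i < 3; ++i) {
        const int n = nd[i];
        for (int d = 0; d < 2; ++d) {
          double r = N[i] * (rho * (aq[d] + conv[d]) - fqv[d]);
          for (int a = 0; a < 2; ++a)
            r += mu * dN[i][a] * (gradu[d][a] + gradu[a][d]);
          r += -dN[i][d] * pq;
          r += tauM * cdN[i] * rM[d];
          r += tauC * dN[i][d] * divu;
          res[3 * n + d] += w * r;
        }
        double rc = N[i] * divu +
                    (tauM / rho) * (dN[i][0] * rM[0] + dN[i][1] * rM[1]);
        res[3 * n + 2] += w * rc;
      }

      if (want_jac) {
        for (int i = 0; i < 3; ++i) {
          for (int j = 0; j < 3; ++j) {
            const double dNdN = dN[i][0] * dN[j][0] + dN[i][1] * dN[j][1];
            for (int d = 0; d < 2; ++d) {
              for (int ee = 0; ee < 2; ++ee) {
                const double del = (d == ee) ? 1.0 : 0.0;
                const double drM = rho * (fac_a * N[j] * del +
                                          fac_u * (N[j] * gradu[d][ee] +
                                                   cdN[j] * del));
                double k = N[i] * drM;
                k += fac_u * mu * (del * dNdN + dN[i][ee] * dN[j][d]);
                k += tauM * cdN[i] * drM;
                k += fac_u * tauC * dN[i][d] * dN[j][ee];
                Ke[3 * i + d][3 * j + ee] += w * k;
              }
              // momentum wrt pressure
              Ke[3 * i + d][3 * j + 2] +=
                  w * (-dN[i][d] * N[j] + tauM * cdN[i] * dN[j][d]);
            }
            for (int ee = 0; ee < 2; ++ee) {
              double kc = fac_u * N[i] * dN[j][ee];
              for (int a = 0; a < 2; ++a) {
                const double del = (a == ee) ? 1.0 : 0.0;
                const double drM = rho * (fac_a * N[j] * del +
                                          fac_u * (N[j] * gradu[a][ee] +
                                                   cdN[j] * del));
                kc += (tauM / rho) * dN[i][a] * drM;
              }
              Ke[3 * i + 2][3 * j + ee] += w * kc;
            }
            Ke[3 * i + 2][3 * j + 2] += w * (tauM / rho) * dNdN;
          }
        }
      }
    }

    if (want_jac) {
      for (int i = 0; i < 3; ++i)
        for (int di = 0; di < 3; ++di)
          for (int j = 0; j < 3; ++j)
            for (int dj = 0; dj < 3; ++dj) {
              const double v = Ke[3 * i + di][3 * j + dj];
              if (v != 0.0) {
                ti.push_back(3 * nd[i] + di + 1);
                tj.push_back(3 * nd[j] + dj + 1);
                tx.push_back(v);
              }
            }
    }
  }

  if (want_jac)
    return List::create(_["res"] = res, _["i"] = wrap(ti), _["j"] = wrap(tj),
                        _["x"] = wrap(tx));
  return List::create(_["res"] = res);
}

// Plane-strain linear elasticity stiffness with per-element Young's modulus
// (Jacobian stiffening: the caller passes E_e = E0 / det J_e of the
// reference mesh).  Dof layout: node k owns 2k (x), 2k+1 (y).
// [[Rcpp::export(name = ".cpp_elasticity_assemble")]]
List cpp_elasticity_assemble(NumericMatrix coords, IntegerMatrix tri,
                             NumericVector Ee, double nu) {
  const int ne = tri.nrow();
  std::vector<int> ti, tj;
  std::vector<double> tx;
  ti.reserve(36 * ne); tj.reserve(36 * ne); tx.reserve(36 * ne);
  for (int e = 0; e < ne; ++e) {
    const int nd[3] = {tri(e, 0) - 1, tri(e, 1) - 1, tri(e, 2) - 1};
    const double x1 = coords(nd[0], 0), y1 = coords(nd[0], 1);
    const double x2 = coords(nd[1], 0), y2 = coords(nd[1], 1);
    const double x3 = coords(nd[2], 0), y3 = coords(nd[2], 1);
    const double det = (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1);
    if (det <= 0.0)
      stop("elasticity assembly: inverted element %d (det J = %g)", e + 1, det);
    const double A = 0.5 * det;
    double dN[3][2];
    dN[1][0] = (y3 - y1) / det;  dN[1][1] = -(x3 - x1) / det;
    dN[2][0] = -(y2 - y1) / det; dN[2][1] = (x2 - x1) / det;
    dN[0][0] = -dN[1][0] - dN[2][0];
    dN[0][1] = -dN[1][1] - dN[2][1];
    const double E = Ee[e];
    const double c0 = E / ((1.0 + nu) * (1.0 - 2.0 * nu));
    const double D11 = c0 * (1.0 - nu), D12 = c0 * nu;
    const double D33 = 0.5 * E / (1.0 + nu);
    for (int i = 0; i < 3; ++i) {
      const double bi = dN[i][0], gi = dN[i][1];
      for (int j = 0; j < 3; ++j) {
        const double bj = dN[j][0], gj = dN[j][1];
        const double kxx = A * (bi * D11 * bj + gi * D33 * gj);
        const double kxy = A * (bi * D12 * gj + gi * D33 * bj);
        const double kyx = A * (gi * D12 * bj + bi * D33 * gj);
        const double kyy = A * (gi * D11 * gj + bi * D33 * bj);
        ti.push_back(2 * nd[i] + 1); tj.push_back(2 * nd[j] + 1); tx.push_back(kxx);
        ti.push_back(2 * nd[i] + 1); tj.push_back(2 * nd[j] + 2); tx.push_back(kxy);
        ti.push_back(2 * nd[i] + 2); tj.push_back(2 * nd[j] + 1); tx.push_back(kyx);
        ti.push_back(2 * nd[i] + 2); tj.push_back(2 * nd[j] + 2); tx.push_back(kyy);
      }
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj), _["x"] = wrap(tx));
}
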