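// Compiled kernels: Q1/P0 hyperelastic element assembly (generalized plane
// strain with fixed axial pre-stretch), reaction-diffusion FE matrices on the
// pulled-back metric, and the backward-Euler loop of the 0D vascular network.
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double GP1 = -0.5773502691896258;
static const double GP2 = 0.5773502691896258;

struct MechParams {
  double mu, k1, k2, cphi2, sphi2, kappa;   // ECM (both layers) + bulk modulus
  double Csmc, Pmax;                        // SMC active-strain law
  double c1, c2, c3, kappa_c;               // Yeoh (calcified sub-region)
  double lz;                                // axial pre-stretch
};

// bilinear shape function derivatives wrt (xi,eta); node order CCW
static inline void shape_deriv(double xi, double et, double dN[2][4]) {
  dN[0][0] = -0.25 * (1 - et); dN[0][1] = 0.25 * (1 - et);
  dN[0][2] = 0.25 * (1 + et);  dN[0][3] = -0.25 * (1 + et);
  dN[1][0] = -0.25 * (1 - xi); dN[1][1] = -0.25 * (1 + xi);
  dN[1][2] = 0.25 * (1 + xi);  dN[1][3] = 0.25 * (1 - xi);
}
static inline void shape_fun(double xi, double et, double N[4]) {
  N[0] = 0.25 * (1 - xi) * (1 - et); N[1] = 0.25 * (1 + xi) * (1 - et);
  N[2] = 0.25 * (1 + xi) * (1 + et); N[3] = 0.25 * (1 - xi) * (1 + et);
}

// Per-gauss-point reference data computed once per element
struct GPData {
  double dNdX[2][4]; // shape gradients wrt reference X
  double wdet;       // gauss weight x |J0|
  double cth, sth;   // components of e_theta at the GP (reference angle)
};

static bool elem_gpdata(const double Xe[2][4], GPData gp[4]) {
  const double pts[4][2] = {{GP1, GP1}, {GP2, GP1}, {GP2, GP2}, {GP1, GP2}};
  double Ns[4];
  for (int g = 0; g < 4; ++g) {
    double dN[2][4];
    shape_deriv(pts[g][0], pts[g][1], dN);
    // J0 = dX/dxi (2x2)
    double J00 = 0, J01 = 0, J10 = 0, J11 = 0;
    for (int a = 0; a < 4; ++a) {
      J00 += Xe[0][a] * dN[0][a]; J01 += Xe[0][a] * dN[1][a];
      J10 += Xe[1][a] * dN[0][a]; J11 += Xe[1][a] * dN[1][a];
    }
    double det = J00 * J11 - J01 * J10;
    if (det <= 0.0) return false;
    double i00 = J11 / det, i01 = -J01 / det, i10 = -J10 / det, i11 = J00 / det;
    for (int a = 0; a < 4; ++a) {
      // dN/dX = J0^{-T} dN/dxi
      gp[g].dNdX[0][a] = i00 * dN[0][a] + i10 * dN[1][a];
      gp[g].dNdX[1][a] = i01 * dN[0][a] + i11 * dN[1][a];
    }
    gp[g].wdet = det; // gauss weights are 1
    shape_fun(pts[g][0], pts[g][1], Ns);
    double xg = 0, yg = 0;
    for (int a = 0; a < 4; ++a) { xg += Ns[a] * Xe[0][a]; yg += Ns[a] * Xe[1][a]; }
    double r = std::sqrt(xg * xg + yg * yg);
    if (r < 1e-12) { gp[g].cth = 0; gp[g].sth = 1; }
    else { gp[g].cth = -yg / r; gp[g].sth = xg / r; } // e_theta = (-sin, cos)
  }
  return true;
}

// In-plane 2nd Piola-Kirchhoff stress (2x2) for the generalized plane-strain
// kinematics with C = blockdiag(C2, lz^2). Also returns S_zz if requested.
static inline void stress2d(const double C2[3], // xx, yy, xy
                            double J, int region, double pe, double la,
                            double lcs, double cth, double sth,
                            const MechParams& mp, double S[3], double* Szz) {
  double lz2 = mp.lz * mp.lz;
  double I1 = C2[0] + C2[1] + lz2;
  double detC2 = C2[0] * C2[1] - C2[2] * C2[2];
  double Ci[3] = {C2[1] / detC2, C2[0] / detC2, -C2[2] / detC2}; // inv(C2)
  double Jm23 = std::pow(J, -2.0 / 3.0);
  double szz = 0;
  if (region == 2) { // calcified: 3-term Yeoh deviatoric part
    double Ib = Jm23 * I1 - 3.0;
    double psip = mp.c1 + 2.0 * mp.c2 * Ib + 3.0 * mp.c3 * Ib * Ib;
    double f = 2.0 * psip * Jm23;
    S[0] = f * (1.0 - (I1 / 3.0) * Ci[0]);
    S[1] = f * (1.0 - (I1 / 3.0) * Ci[1]);
    S[2] = f * (-(I1 / 3.0) * Ci[2]);
    szz = f * (1.0 - I1 / (3.0 * lz2));
  } else {
    double f = mp.mu * Jm23;
    S[0] = f * (1.0 - (I1 / 3.0) * Ci[0]);
    S[1] = f * (1.0 - (I1 / 3.0) * Ci[1]);
    S[2] = f * (-(I1 / 3.0) * Ci[2]);
    szz = f * (1.0 - I1 / (3.0 * lz2));
    // collagen fiber families (+-phi from circumferential): identical I4
    double Ctt = cth * cth * C2[0] + sth * sth * C2[1] + 2.0 * cth * sth * C2[2];
    double I4 = mp.cphi2 * Ctt + mp.sphi2 * lz2;
    // inelastic straightening acts on the squared fiber invariant (the
    // reading that reproduces the stated tone calibration)
    double lcs4 = lcs * lcs * lcs * lcs;
    double E = I4 / lcs4 - 1.0;
    if (E > 0.0) {
      double dpsi = mp.k1 * E * std::exp(mp.k2 * E * E); // per family
      double f4 = 2.0 * 2.0 * dpsi / lcs4;               // 2 families
      S[0] += f4 * mp.cphi2 * cth * cth;
      S[1] += f4 * mp.cphi2 * sth * sth;
      S[2] += f4 * mp.cphi2 * cth * sth;
      szz += f4 * mp.sphi2 / 2.0; // d I4/d Czz = sphi2 per family
    }
    if (region == 0) { // healthy media: SMC active-strain contribution
      double lth = std::sqrt(Ctt);
      double le = lth / la;
      double x = 2.0 * mp.Csmc / mp.Pmax * (le - 1.0);
      double Psm = mp.Pmax * (2.0 / (1.0 + std::exp(-x)) - 1.0);
      double fs = Psm / (le * la * la);
      S[0] += fs * cth * cth;
      S[1] += fs * sth * sth;
      S[2] += fs * cth * sth;
    }
  }
  // perturbed-Lagrangian volumetric part, S_vol = pe * J * C^{-1}
  S[0] += pe * J * Ci[0];
  S[1] += pe * J * Ci[1];
  S[2] += pe * J * Ci[2];
  szz += pe * J / lz2;
  if (Szz) *Szz = szz;
}

// Element residual with element-wise condensed pressure pe = kappa*mean(J-1).
static bool elem_residual(const double Xe[2][4], const GPData gp[4],
                          const double Ue[2][4], int region, double la,
                          double lcs, const MechParams& mp, double re[8],
                          double* pe_out, double* Jbar_out) {
  double F2s[4][4]; // per GP: F11 F12 F21 F22
  double Js[4];
  double vol = 0, intJ = 0;
  for (int g = 0; g < 4; ++g) {
    double F11 = 1, F12 = 0, F21 = 0, F22 = 1;
    for (int a = 0; a < 4; ++a) {
      F11 += Ue[0][a] * gp[g].dNdX[0][a];
      F12 += Ue[0][a] * gp[g].dNdX[1][a];
      F21 += Ue[1][a] * gp[g].dNdX[0][a];
      F22 += Ue[1][a] * gp[g].dNdX[1][a];
    }
    double detF2 = F11 * F22 - F12 * F21;
    if (detF2 <= 0.0) return false;
    F2s[g][0] = F11; F2s[g][1] = F12; F2s[g][2] = F21; F2s[g][3] = F22;
    Js[g] = mp.lz * detF2;
    vol += gp[g].wdet;
    intJ += gp[g].wdet * (Js[g] - 1.0);
  }
  double kap = (region == 2) ? mp.kappa_c : mp.kappa;
  double pe = kap * intJ / vol;
  for (int k = 0; k < 8; ++k) re[k] = 0;
  for (int g = 0; g < 4; ++g) {
    double F11 = F2s[g][0], F12 = F2s[g][1], F21 = F2s[g][2], F22 = F2s[g][3];
    double C2[3] = {F11 * F11 + F21 * F21, F12 * F12 + F22 * F22,
                    F11 * F12 + F21 * F22};
    double S[3];
    stress2d(C2, Js[g], region, pe, la, lcs, gp[g].cth, gp[g].sth, mp, S, nullptr);
    // P = F S (2x2, S symmetric)
    double P11 = F11 * S[0] + F12 * S[2];
    double P12 = F11 * S[2] + F12 * S[1];
    double P21 = F21 * S[0] + F22 * S[2];
    double P22 = F21 * S[2] + F22 * S[1];
    double w = gp[g].wdet;
    for (int a = 0; a < 4; ++a) {
      re[2 * a] += w * (P11 * gp[g].dNdX[0][a] + P12 * gp[g].dNdX[1][a]);
      re[2 * a + 1] += w * (P21 * gp[g].dNdX[0][a] + P22 * gp[g].dNdX[1][a]);
    }
  }
  if (pe_out) *pe_out = pe;
  if (Jbar_out) *Jbar_out = 1.0 + intJ / vol;
  return true;
}

static MechParams unpack_params(const List& pars) {
  MechParams mp;
  mp.mu = as<double>(pars["mu"]);
  mp.k1 = as<double>(pars["k1"]);
  mp.k2 = as<double>(pars["k2"]);
  double phi = as<double>(pars["phi_rad"]);
  mp.cphi2 = std::cos(phi) * std::cos(phi);
  mp.sphi2 = std::sin(phi) * std::sin(phi);
  mp.kappa = as<double>(pars["kappa"]);
  mp.Csmc = as<double>(pars["C_smc"]);
  mp.Pmax = as<double>(pars["P_smc_max"]);
  mp.c1 = as<double>(pars["c1"]);
  mp.c2 = as<double>(pars["c2"]);
  mp.c3 = as<double>(pars["c3"]);
  mp.kappa_c = as<double>(pars["kappa_c"]);
  mp.lz = as<double>(pars["lambda_z"]);
  return mp;
}

// [[Rcpp::export]]
List mech_assemble_cpp(const arma::mat& coords, const arma::imat& elems,
                       const arma::ivec& region, const arma::vec& lambda_a,
                       const arma::vec& lambda_cs, const arma::vec& u,
                       double p_lum_kPa, const arma::ivec& inner_loop,
                       const List& pars, bool want_tangent, bool want_fields) {
  const int nn = coords.n_rows, ne = elems.n_rows;
  MechParams mp = unpack_params(pars);
  arma::vec res(2 * nn, arma::fill::zeros);
  arma::vec pe_all(ne, arma::fill::zeros), Jbar_all(ne, arma::fill::zeros);
  bool ok = true;
  const double h = 1e-6;
  int nb = inner_loop.n_elem;
  int ntrip = want_tangent ? (64 * ne + 8 * nb) : 0;
  arma::ivec ti(ntrip), tj(ntrip);
  arma::vec tx(ntrip);
  int tc = 0;
  arma::mat fields;
  if (want_fields) fields.zeros(ne, 14);

  for (int e = 0; e < ne && ok; ++e) {
    double Xe[2][4], Ue[2][4];
    int nid[4];
    for (int a = 0; a < 4; ++a) {
      nid[a] = elems(e, a) - 1;
      Xe[0][a] = coords(nid[a], 0);
      Xe[1][a] = coords(nid[a], 1);
      Ue[0][a] = u(2 * nid[a]);
      Ue[1][a] = u(2 * nid[a] + 1);
    }
    GPData gp[4];
    if (!elem_gpdata(Xe, gp)) { ok = false; break; }
    int reg = region(e);
    double la = lambda_a(e), lcs = lambda_cs(e);
    double re[8], pe, Jbar;
    if (!elem_residual(Xe, gp, Ue, reg, la, lcs, mp, re, &pe, &Jbar)) {
      ok = false; break;
    }
    pe_all(e) = pe; Jbar_all(e) = Jbar;
    for (int a = 0; a < 4; ++a) {
      res(2 * nid[a]) += re[2 * a];
      res(2 * nid[a] + 1) += re[2 * a + 1];
    }
    if (want_tangent) {
      double ke[8][8];
      double rp[8], rm[8];
      double Up[2][4];
      for (int j = 0; j < 8; ++j) {
        std::memcpy(Up, Ue, sizeof(Up));
        Up[j % 2][j / 2] = Ue[j % 2][j / 2] + h;
        bool okp = elem_residual(Xe, gp, Up, reg, la, lcs, mp, rp, nullptr, nullptr);
        Up[j % 2][j / 2] = Ue[j % 2][j / 2] - h;
        bool okm = elem_residual(Xe, gp, Up, reg, la, lcs, mp, rm, nullptr, nullptr);
        if (!okp || !okm) { ok = false; break; }
        for (int i = 0; i < 8; ++i) ke[i][j] = (rp[i] - rm[i]) / (2 * h);
      }
      if (!ok) break;
      for (int i = 0; i < 8; ++i)
        for (int j = 0; j < 8; ++j) {
          ti(tc) = 2 * nid[i / 2] + (i % 2) + 1;
          tj(tc) = 2 * nid[j / 2] + (j % 2) + 1;
          tx(tc) = ke[i][j];
          ++tc;
        }
    }
    if (want_fields) {
      // volume-averaged kinematic and stress measures for post-processing
      double w0 = 0, Jm = 0, Ci[3] = {0, 0, 0}, sig[4] = {0, 0, 0, 0};
      double lth_m = 0, sig_tt_smc = 0;
      for (int g = 0; g < 4; ++g) {
        double F11 = 1, F12 = 0, F21 = 0, F22 = 1;
        for (int a = 0; a < 4; ++a) {
          F11 += Ue[0][a] * gp[g].dNdX[0][a];
          F12 += Ue[0][a] * gp[g].dNdX[1][a];
          F21 += Ue[1][a] * gp[g].dNdX[0][a];
          F22 += Ue[1][a] * gp[g].dNdX[1][a];
        }
        double detF2 = F11 * F22 - F12 * F21;
        double J = mp.lz * detF2;
        double C2[3] = {F11 * F11 + F21 * F21, F12 * F12 + F22 * F22,
                        F11 * F12 + F21 * F22};
        double detC2 = C2[0] * C2[1] - C2[2] * C2[2];
        double S[3], Szz;
        stress2d(C2, J, reg, pe, la, lcs, gp[g].cth, gp[g].sth, mp, S, &Szz);
        // Cauchy = (1/J) F S F^T (in-plane) and lz^2 Szz / J
        double P11 = F11 * S[0] + F12 * S[2], P12 = F11 * S[2] + F12 * S[1];
        double P21 = F21 * S[0] + F22 * S[2], P22 = F21 * S[2] + F22 * S[1];
        double sxx = (P11 * F11 + P12 * F12) / J;
        double syy = (P21 * F21 + P22 * F22) / J;
        double sxy = (P11 * F21 + P12 * F22) / J;
        double szz = mp.lz * mp.lz * Szz / J;
        double w = gp[g].wdet;
        w0 += w; Jm += w * J;
        Ci[0] += w * C2[1] / detC2; Ci[1] += w * C2[0] / detC2;
        Ci[2] += w * (-C2[2] / detC2);
        sig[0] += w * sxx; sig[1] += w * syy; sig[2] += w * sxy; sig[3] += w * szz;
        double Ctt = gp[g].cth * gp[g].cth * C2[0] + gp[g].sth * gp[g].sth * C2[1] +
                     2 * gp[g].cth * gp[g].sth * C2[2];
        double lth = std::sqrt(Ctt);
        lth_m += w * lth;
        if (reg == 0) {
          double le = lth / la;
          double x = 2.0 * mp.Csmc / mp.Pmax * (le - 1.0);
          double Psm = mp.Pmax * (2.0 / (1.0 + std::exp(-x)) - 1.0);
          // circumferential Cauchy SMC stress: sigma_tt = le * Psm * lth / (J ... )
          // via sigma_smc = (1/J) F S_smc F^T projected on pushed e_theta:
          sig_tt_smc += w * (Psm / (le * la * la)) * lth * lth / J;
        }
      }
      double tr3 = (sig[0] + sig[1] + sig[3]) / w0 / 3.0;
      double sxx = sig[0] / w0 - tr3, syy = sig[1] / w0 - tr3,
             szz = sig[3] / w0 - tr3, sxy = sig[2] / w0;
      double vm = std::sqrt(1.5 * (sxx * sxx + syy * syy + szz * szz + 2 * sxy * sxy));
      fields(e, 0) = pe;
      fields(e, 1) = Jm / w0;
      fields(e, 2) = Ci[0] / w0; fields(e, 3) = Ci[1] / w0; fields(e, 4) = Ci[2] / w0;
      fields(e, 5) = sig[0] / w0; fields(e, 6) = sig[1] / w0;
      fields(e, 7) = sig[2] / w0; fields(e, 8) = sig[3] / w0;
      fields(e, 9) = vm;
      fields(e, 10) = lth_m / w0;
      fields(e, 11) = sig_tt_smc / w0;
      fields(e, 12) = la;
      fields(e, 13) = w0; // reference element area
    }
  }

  // follower pressure load on the (deformed) inner boundary loop; potential
  // -p*lz*A_lumen, nodal force p*lz*dA/dx
  if (ok && p_lum_kPa != 0.0) {
    double f = p_lum_kPa * mp.lz;
    std::vector<double> xb(nb), yb(nb);
    for (int i = 0; i < nb; ++i) {
      int n0 = inner_loop(i) - 1;
      xb[i] = coords(n0, 0) + u(2 * n0);
      yb[i] = coords(n0, 1) + u(2 * n0 + 1);
    }
    for (int i = 0; i < nb; ++i) {
      int ip = (i + 1) % nb, im = (i - 1 + nb) % nb;
      int n0 = inner_loop(i) - 1;
      res(2 * n0) -= f * 0.5 * (yb[ip] - yb[im]);
      res(2 * n0 + 1) -= f * 0.5 * (xb[im] - xb[ip]);
      if (want_tangent) {
        int np = inner_loop(ip) - 1, nm = inner_loop(im) - 1;
        // d res_x(i) / d y(ip) = -f/2 ; d res_x(i)/d y(im) = +f/2
        ti(tc) = 2 * n0 + 1; tj(tc) = 2 * np + 2; tx(tc) = -0.5 * f; ++tc;
        ti(tc) = 2 * n0 + 1; tj(tc) = 2 * nm + 2; tx(tc) = 0.5 * f; ++tc;
        // d res_y(i) / d x(im) = -f/2 ; d res_y(i)/d x(ip) = +f/2
        ti(tc) = 2 * n0 + 2; tj(tc) = 2 * nm + 1; tx(tc) = -0.5 * f; ++tc;
        ti(tc) = 2 * n0 + 2; tj(tc) = 2 * np + 1; tx(tc) = 0.5 * f; ++tc;
        ti(tc) = 2 * n0 + 1; tj(tc) = 2 * n0 + 1; tx(tc) = 0.0; ++tc;
        ti(tc) = 2 * n0 + 2; tj(tc) = 2 * n0 + 2; tx(tc) = 0.0; ++tc;
        ti(tc) = 2 * n0 + 1; tj(tc) = 2 * n0 + 2; tx(tc) = 0.0; ++tc;
        ti(tc) = 2 * n0 + 2; tj(tc) = 2 * n0 + 1; tx(tc) = 0.0; ++tc;
      }
    }
  }

  List out = List::create(
      _["ok"] = ok, _["residual"] = res, _["pe"] = pe_all, _["Jbar"] = Jbar_all);
  if (want_tangent) {
    out["ti"] = arma::ivec(ti.head(tc));
    out["tj"] = arma::ivec(tj.head(tc));
    out["tx"] = arma::vec(tx.head(tc));
  }
  if (want_fields) out["fields"] = fields;
  return out;
}

// Diffusion (metric-weighted) and consistent mass matrices for the species
// transport problem on the reference mesh. 'include' lists elements (1-based)
// that carry diffusion/reaction (healthy tissue).
// [[Rcpp::export]]
List transport_assemble_cpp(const arma::mat& coords, const arma::imat& elems,
                            const arma::ivec& include, const arma::vec& Jbar,
                            const arma::mat& Cinv) {
  int ninc = include.n_elem;
  arma::ivec ki(16 * ninc), kj(16 * ninc);
  arma::vec kx(16 * ninc), mx(16 * ninc);
  int tc = 0;
  const double pts[4][2] = {{GP1, GP1}, {GP2, GP1}, {GP2, GP2}, {GP1, GP2}};
  for (int ii = 0; ii < ninc; ++ii) {
    int e = include(ii) - 1;
    double Xe[2][4];
    int nid[4];
    for (int a = 0; a < 4; ++a) {
      nid[a] = elems(e, a) - 1;
      Xe[0][a] = coords(nid[a], 0);
      Xe[1][a] = coords(nid[a], 1);
    }
    GPData gp[4];
    if (!elem_gpdata(Xe, gp)) stop("inverted element in transport assembly");
    double D11 = Jbar(e) * Cinv(e, 0), D22 = Jbar(e) * Cinv(e, 1),
           D12 = Jbar(e) * Cinv(e, 2);
    double ke[4][4] = {{0}}, me[4][4] = {{0}};
    for (int g = 0; g < 4; ++g) {
      double N[4];
      shape_fun(pts[g][0], pts[g][1], N);
      double w = gp[g].wdet;
      for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b) {
          double gx_a = gp[g].dNdX[0][a], gy_a = gp[g].dNdX[1][a];
          double gx_b = gp[g].dNdX[0][b], gy_b = gp[g].dNdX[1][b];
          ke[a][b] += w * (gx_a * (D11 * gx_b + D12 * gy_b) +
                           gy_a * (D12 * gx_b + D22 * gy_b));
          me[a][b] += w * N[a] * N[b];
        }
    }
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 4; ++b) {
        ki(tc) = nid[a] + 1; kj(tc) = nid[b] + 1;
        kx(tc) = ke[a][b]; mx(tc) = me[a][b];
        ++tc;
      }
  }
  return List::create(_["i"] = ki, _["j"] = kj, _["kx"] = kx, _["mx"] = mx);
}

static inline double surro_area(double p, double a, double b, double c, double d) {
  double s = 1.0 / (1.0 + std::exp(-b * (p / c - 1.0)));
  return a * s + d;
}
static inline double surro_dadp(double p, double a, double b, double c, double d) {
  double s = 1.0 / (1.0 + std::exp(-b * (p / c - 1.0)));
  return a * b / c * s * (1.0 - s);
}

// Backward-Euler run of the 3-segment network. Returns the physical window
// (last n_h beats) sampled at every step: columns
// t_h, P1, PS, P3, Qh, QSp, QSm, pS, qS, A, r, tau
// [[Rcpp::export]]
arma::mat ode0d_run_cpp(double f_h, double V_h, double R1, double C1, double R3,
                        double C3, double Pout, double mu, double ell_mm,
                        double a, double b, double c, double d, int n_pre,
                        int n_h, int steps_per_beat, int inflow_mode,
                        double Q_const, int fixed_rc, double RS0, double CS0) {
  double Th = 1.0 / f_h;
  double dt = Th / steps_per_beat;
  int ntot = (n_pre + n_h) * steps_per_beat;
  int istart = n_pre * steps_per_beat;
  arma::mat out(ntot - istart + 1, 12);
  double y1 = Pout, y2 = Pout, y3 = Pout;
  const double RCONV = 133.322e6; // Pa*s/m^3 -> mmHg*s/mL
  const double ell_m = ell_mm * 1e-3;
  auto RS_of = [&](double p) {
    if (fixed_rc) return RS0;
    double A_m2 = surro_area(p, a, b, c, d) * 1e-6;
    return 8.0 * M_PI * mu * ell_m / (A_m2 * A_m2) / RCONV;
  };
  auto CS_of = [&](double p) {
    if (fixed_rc) return CS0;
    return ell_mm * surro_dadp(p, a, b, c, d) * 1e-3;
  };
  auto Qin = [&](double th) {
    if (inflow_mode == 1) return Q_const;
    double tb = th - Th * std::floor(th / Th);
    if (tb < 0.5 * Th) {
      double Qa = 4.0 * f_h * V_h;
      return 0.5 * Qa * (1.0 - std::cos(4.0 * M_PI * f_h * tb));
    }
    return 0.0;
  };
  int row = 0;
  auto record = [&](double th) {
    double pS = 0.5 * (y2 + y3);
    double RS = RS_of(pS);
    double QSp = (y1 - y2) / R1;
    double QSm = (y2 - y3) / RS;
    double qS = 0.5 * (QSp + QSm);
    double A = fixed_rc ? 0.0 : surro_area(pS, a, b, c, d);
    double r = fixed_rc ? 0.0 : std::sqrt(A / M_PI);
    double tau = (r > 0) ? 4.0 * mu * qS / (M_PI * r * r * r) * 1e3 : 0.0;
    out(row, 0) = th; out(row, 1) = y1; out(row, 2) = y2; out(row, 3) = y3;
    out(row, 4) = Qin(th); out(row, 5) = QSp; out(row, 6) = QSm;
    out(row, 7) = pS; out(row, 8) = qS; out(row, 9) = A; out(row, 10) = r;
    out(row, 11) = tau;
    ++row;
  };
  for (int n = 0; n < ntot; ++n) {
    double tnew = (n + 1 - istart) * dt; // physical time relative to window start
    double th_abs = (n + 1) * dt;
    double Q = Qin(th_abs);
    double y1n = y1, y2n = y2, y3n = y3;
    double x1 = y1, x2 = y2, x3 = y3;
    for (int it = 0; it < 100; ++it) {
      double pS = 0.5 * (x2 + x3);
      double RS = RS_of(pS);
      double CS = CS_of(pS);
      // M = B1/dt + B2
      double m11 = C1 / dt + 1.0 / R1, m12 = -1.0 / R1, m13 = 0.0;
      double m21 = -1.0 / R1, m22 = CS / dt + 1.0 / R1 + 1.0 / RS, m23 = -1.0 / RS;
      double m31 = 0.0, m32 = -1.0 / RS, m33 = C3 / dt + 1.0 / RS + 1.0 / R3;
      double b1 = C1 * y1n / dt + Q;
      double b2 = CS * y2n / dt;
      double b3 = C3 * y3n / dt + Pout / R3;
      double det = m11 * (m22 * m33 - m23 * m32) - m12 * (m21 * m33 - m23 * m31) +
                   m13 * (m21 * m32 - m22 * m31);
      double n1 = (b1 * (m22 * m33 - m23 * m32) - m12 * (b2 * m33 - m23 * b3) +
                   m13 * (b2 * m32 - m22 * b3)) / det;
      double n2 = (m11 * (b2 * m33 - m23 * b3) - b1 * (m21 * m33 - m23 * m31) +
                   m13 * (m21 * b3 - b2 * m31)) / det;
      double n3 = (m11 * (m22 * b3 - b2 * m32) - m12 * (m21 * b3 - b2 * m31) +
                   b1 * (m21 * m32 - m22 * m31)) / det;
      double diff = std::fabs(n1 - x1) + std::fabs(n2 - x2) + std::fabs(n3 - x3);
      x1 = n1; x2 = n2; x3 = n3;
      if (diff < 1e-11 * (1.0 + std::fabs(x1) + std::fabs(x2) + std::fabs(x3))) break;
    }
    y1 = x1; y2 = x2; y3 = x3;
    if (n + 1 == istart) { record(0.0); }
    else if (n + 1 > istart) { record(tnew); }
  }
  if (istart == 0) {
    // no pre-beats: first row is the initial state
    arma::mat out2(ntot + 1, 12);
    out2.rows(1, ntot) = out.rows(0, ntot - 1);
    double y10 = Pout;
    out2(0, 0) = 0; out2(0, 1) = y10; out2(0, 2) = y10; out2(0, 3) = y10;
    out2(0, 4) = Qin(0.0); out2(0, 5) = 0; out2(0, 6) = 0; out2(0, 7) = y10;
    out2(0, 8) = 0;
    double A = fixed_rc ? 0.0 : surro_area(y10, a, b, c, d);
    out2(0, 9) = A; out2(0, 10) = fixed_rc ? 0.0 : std::sqrt(A / M_PI);
    out2(0, 11) = 0;
    return out2;
  }
  return out;
}
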