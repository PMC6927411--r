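// Energy/force kernels for the analytic many-body water potential.
//
// Units: kcal/mol, Angstrom, e.  Forces are -dE/dx in kcal/mol/A.
//
// Model terms (see R-level documentation):
//   1B   : harmonic stretch + cubic correction, harmonic bend (per molecule)
//   elec : fixed point charges, intermolecular only (direct sum for clusters,
//          Ewald with intramolecular exclusions for periodic boxes)
//   ind  : one isotropic polarizable site per O, Thole-damped fields and
//          dipole-dipole tensors, solved self-consistently; in periodic
//          systems interactions are minimum-image and smoothly switched off
//          at the real-space cutoff (no reciprocal-space induction)
//   disp : Tang-Toennies damped -C6/r^6 on O-O pairs
//   2B   : Born-Mayer O-O repulsion times a quintic switch
//   3B   : Axilrod-Teller-Muto triple-dipole term on O triples times the
//          product of pair switches

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double KC = 332.06371;        // kcal*A/mol/e^2
static const double HARD_FLOOR = 0.3;      // A

struct WParams {
  double qO, qH, alphaO, thole_a;
  double C6, b_disp, A_bm, b_bm, k3b;
  double kbond, D_morse, r0, kang, theta0;
  double sw2_in, sw2_out, sw3_in, sw3_out;
  double cutoff;          // <=0 for clusters
  double ewald_tol;
  double scf_tol; int scf_maxit;
  bool use2b, use3b;
};

static WParams read_params(const List& p) {
  WParams w;
  w.qO = p["qO"]; w.qH = p["qH"]; w.alphaO = p["alphaO"];
  w.thole_a = p["thole_a"];
  w.C6 = p["C6"]; w.b_disp = p["b_disp"];
  w.A_bm = p["A_bm"]; w.b_bm = p["b_bm"]; w.k3b = p["k3b"];
  w.kbond = p["kbond"]; w.D_morse = p["D_morse"]; w.r0 = p["r0"];
  w.kang = p["kang"]; w.theta0 = p["theta0"];
  w.sw2_in = p["sw2_in"]; w.sw2_out = p["sw2_out"];
  w.sw3_in = p["sw3_in"]; w.sw3_out = p["sw3_out"];
  w.cutoff = p["cutoff"]; w.ewald_tol = p["ewald_tol"];
  w.scf_tol = p["scf_tol"]; w.scf_maxit = p["scf_maxit"];
  w.use2b = p["use2b"]; w.use3b = p["use3b"];
  return w;
}

// quintic smoothstep switch: 1 below r_in, 0 above r_out, C2-continuous
static inline void switch5(double r, double rin, double rout,
                           double& s, double& ds) {
  if (r <= rin)      { s = 1.0; ds = 0.0; return; }
  if (r >= rout)     { s = 0.0; ds = 0.0; return; }
  double x = (r - rin) / (rout - rin);
  double x2 = x * x, x3 = x2 * x;
  s  = 1.0 - x3 * (10.0 - 15.0 * x + 6.0 * x2);
  ds = -30.0 * x2 * (1.0 - 2.0 * x + x2) / (rout - rin);
}

// smooth cutoff switch for periodic real-space terms (on from 0.85*rc to rc)
static inline void cutsw(double r, double rc, double& s, double& ds) {
  if (rc <= 0.0) { s = 1.0; ds = 0.0; return; }
  switch5(r, 0.85 * rc, rc, s, ds);
}

static inline void min_image(double* d, double L) {
  if (L > 0.0)
    for (int k = 0; k < 3; ++k) d[k] -= L * std::round(d[k] / L);
}

// Tang-Toennies incomplete-gamma damping of order 6 and its r-derivative
static inline void tt6(double b, double r, double& f, double& df) {
  double x = b * r, term = 1.0, sum = 1.0;
  for (int k = 1; k <= 6; ++k) { term *= x / k; sum += term; }
  double ex = std::exp(-x);
  f  = 1.0 - ex * sum;
  df = b * ex * term;            // b * e^-x * x^6/6!
}

// Thole exponential damping lambda3/lambda5 and r-derivatives
static inline void thole(double r, double a, double& l3, double& dl3,
                         double& l5, double& dl5) {
  double t = (r * r * r) / (a * a * a);
  double et = std::exp(-t);
  l3 = 1.0 - et;
  l5 = 1.0 - (1.0 + t) * et;
  double dtdr = 3.0 * t / r;
  dl3 = et * dtdr;
  dl5 = t * et * dtdr;
}

struct EvalOut {
  double e1b = 0, elec = 0, eind = 0, edisp = 0, e2b = 0, e3b = 0;
  arma::mat F;                    // natoms x 3
  arma::mat dipoles;              // nmol x 3 (e*A)
  int scf_iters = 0;
};

// ---------------------------------------------------------------- 1B -------
// Morse stretch: V = D (1 - e^{-a d})^2 with a = sqrt(k/2D), whose expansion
// is the harmonic term (k/2) d^2 plus the cubic anharmonic correction
// -(k a / 2) d^3 + ... while staying bounded for large stretches.
static void one_body(const arma::mat& X, int nmol, const WParams& w,
                     bool grad, EvalOut& out) {
  double aM = std::sqrt(w.kbond / (2.0 * w.D_morse));
  for (int m = 0; m < nmol; ++m) {
    int iO = 3 * m, iH1 = 3 * m + 1, iH2 = 3 * m + 2;
    arma::rowvec rO = X.row(iO);
    arma::rowvec b1 = X.row(iH1) - rO, b2 = X.row(iH2) - rO;
    double r1 = arma::norm(b1), r2 = arma::norm(b2);
    double d1 = r1 - w.r0, d2 = r2 - w.r0;
    double e1 = std::exp(-aM * d1), e2 = std::exp(-aM * d2);
    out.e1b += w.D_morse * ((1 - e1) * (1 - e1) + (1 - e2) * (1 - e2));
    double c = arma::dot(b1, b2) / (r1 * r2);
    c = std::max(-1.0, std::min(1.0, c));
    double th = std::acos(c), dth = th - w.theta0;
    out.e1b += 0.5 * w.kang * dth * dth;
    if (grad) {
      double dV1 = 2.0 * w.D_morse * aM * (1 - e1) * e1;
      double dV2 = 2.0 * w.D_morse * aM * (1 - e2) * e2;
      arma::rowvec u1 = b1 / r1, u2 = b2 / r2;
      out.F.row(iH1) -= dV1 * u1;  out.F.row(iO) += dV1 * u1;
      out.F.row(iH2) -= dV2 * u2;  out.F.row(iO) += dV2 * u2;
      double s = std::sqrt(std::max(1e-12, 1.0 - c * c));
      double dVth = w.kang * dth;
      // dtheta/db1 etc.
      // dE/db = dVth * dtheta/db with dtheta/dc = -1/s
      arma::rowvec dc1 = (u2 - c * u1) / r1;
      arma::rowvec dc2 = (u1 - c * u2) / r2;
      arma::rowvec g1 = dVth * (-1.0 / s) * dc1;
      arma::rowvec g2 = dVth * (-1.0 / s) * dc2;
      out.F.row(iH1) -= g1;  out.F.row(iO) += g1;
      out.F.row(iH2) -= g2;  out.F.row(iO) += g2;
    }
  }
}

// ------------------------------------------------- permanent electrostatics
static void elec_direct(const arma::mat& X, const arma::vec& q, int nmol,
                        bool grad, EvalOut& out) {
  int n = X.n_rows;
  for (int i = 0; i < n; ++i) for (int j = i + 1; j < n; ++j) {
    if (i / 3 == j / 3) continue;                 // intramolecular excluded
    arma::rowvec d = X.row(i) - X.row(j);
    double r = arma::norm(d);
    double e = KC * q[i] * q[j] / r;
    out.elec += e;
    if (grad) {
      arma::rowvec f = e / (r * r) * d;           // -dE/dri
      out.F.row(i) += f;  out.F.row(j) -= f;
    }
  }
}

static void elec_ewald(const arma::mat& X, const arma::vec& q, int nmol,
                       double L, double rc, double tol, bool grad,
                       EvalOut& out) {
  int n = X.n_rows;
  double s = std::sqrt(-std::log(tol));
  double alpha = s / rc;
  double kmax = 2.0 * alpha * s;
  int nmax = (int)std::ceil(kmax * L / (2.0 * M_PI));
  // real space (all pairs within rc, minimum image)
  for (int i = 0; i < n; ++i) for (int j = i + 1; j < n; ++j) {
    double d[3] = { X(i,0)-X(j,0), X(i,1)-X(j,1), X(i,2)-X(j,2) };
    min_image(d, L);
    double r2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
    bool samemol = (i / 3 == j / 3);
    double r = std::sqrt(r2);
    if (r < rc && !samemol) {
      double erfc_ = std::erfc(alpha * r);
      double e = KC * q[i] * q[j] * erfc_ / r;
      out.elec += e;
      if (grad) {
        double fr = KC * q[i] * q[j] *
          (erfc_ / r2 + 2.0 * alpha / std::sqrt(M_PI) *
           std::exp(-alpha * alpha * r2) / r) / r;
        for (int k = 0; k < 3; ++k) {
          out.F(i,k) += fr * d[k];  out.F(j,k) -= fr * d[k];
        }
      }
    }
    if (samemol) {
      // remove the screened+reciprocal contribution of excluded pairs
      double erf_ = std::erf(alpha * r);
      out.elec -= KC * q[i] * q[j] * erf_ / r;
      if (grad) {
        double fr = -KC * q[i] * q[j] *
          (erf_ / r2 - 2.0 * alpha / std::sqrt(M_PI) *
           std::exp(-alpha * alpha * r2) / r) / r;
        for (int k = 0; k < 3; ++k) {
          out.F(i,k) += fr * d[k];  out.F(j,k) -= fr * d[k];
        }
      }
    }
  }
  // reciprocal space, half-sphere with weight 2
  double V = L * L * L;
  double twoPiL = 2.0 * M_PI / L;
  // tabulated complex exponentials e^{i*2*pi*m*x/L}
  std::vector<std::complex<double> > ex((nmax + 1) * n), ey((2*nmax+1) * n),
                                     ez((2*nmax+1) * n);
  for (int i = 0; i < n; ++i) {
    std::complex<double> ux(std::cos(twoPiL * X(i,0)), std::sin(twoPiL * X(i,0)));
    std::complex<double> uy(std::cos(twoPiL * X(i,1)), std::sin(twoPiL * X(i,1)));
    std::complex<double> uz(std::cos(twoPiL * X(i,2)), std::sin(twoPiL * X(i,2)));
    ex[i] = 1.0;
    for (int m = 1; m <= nmax; ++m) ex[m * n + i] = ex[(m-1) * n + i] * ux;
    ey[nmax * n + i] = 1.0; ez[nmax * n + i] = 1.0;
    for (int m = 1; m <= nmax; ++m) {
      ey[(nmax+m) * n + i] = ey[(nmax+m-1) * n + i] * uy;
      ey[(nmax-m) * n + i] = std::conj(ey[(nmax+m) * n + i]);
      ez[(nmax+m) * n + i] = ez[(nmax+m-1) * n + i] * uz;
      ez[(nmax-m) * n + i] = std::conj(ez[(nmax+m) * n + i]);
    }
  }
  std::vector<std::complex<double> > eik(n);
  double k2max = kmax * kmax;
  for (int mx = 0; mx <= nmax; ++mx)
  for (int my = (mx == 0 ? 0 : -nmax); my <= nmax; ++my)
  for (int mz = ((mx == 0 && my == 0) ? 1 : -nmax); mz <= nmax; ++mz) {
    double kx = twoPiL * mx, ky = twoPiL * my, kz = twoPiL * mz;
    double k2 = kx*kx + ky*ky + kz*kz;
    if (k2 > k2max) continue;
    std::complex<double> S(0.0, 0.0);
    for (int i = 0; i < n; ++i) {
      eik[i] = ex[mx * n + i] * ey[(nmax+my) * n + i] * ez[(nmax+mz) * n + i];
      S += q[i] * eik[i];
    }
    double A = 2.0 /*half-space*/ * 2.0 * M_PI * KC / V *
               std::exp(-k2 / (4.0 * alpha * alpha)) / k2;
    out.elec += A * std::norm(S);
    if (grad) {
      for (int i = 0; i < n; ++i) {
        double im = std::imag(std::conj(S) * eik[i]);
        double f = 2.0 * A * q[i] * im;
        out.F(i,0) += f * kx; out.F(i,1) += f * ky; out.F(i,2) += f * kz;
      }
    }
  }
  // self energy
  double q2 = arma::dot(q, q);
  out.elec -= KC * alpha / std::sqrt(M_PI) * q2;
}

// ------------------------------------------------------------- induction --
// polarizable site = O atom of each molecule
static void induction(const arma::mat& X, const arma::vec& q, int nmol,
                      double L, const WParams& w, bool grad, EvalOut& out) {
  double rc = (L > 0.0) ? w.cutoff : -1.0;
  double alpha_md = w.alphaO / KC;      // e^2*A^2*mol/kcal
  arma::mat E(nmol, 3, arma::fill::zeros);     // permanent field at O sites
  int n = X.n_rows;
  // permanent field (charges of other molecules only)
  for (int m = 0; m < nmol; ++m) {
    int iO = 3 * m;
    for (int j = 0; j < n; ++j) {
      if (j / 3 == m) continue;
      double d[3] = { X(iO,0)-X(j,0), X(iO,1)-X(j,1), X(iO,2)-X(j,2) };
      min_image(d, L);
      double r = std::sqrt(d[0]*d[0]+d[1]*d[1]+d[2]*d[2]);
      if (rc > 0.0 && r >= rc) continue;
      double l3, dl3, l5, dl5, sc, dsc;
      thole(r, w.thole_a, l3, dl3, l5, dl5);
      cutsw(r, rc, sc, dsc);
      double g3 = l3 * sc;
      double c = KC * q[j] * g3 / (r * r * r);
      for (int k = 0; k < 3; ++k) E(m,k) += c * d[k];
    }
  }
  // self-consistent iteration mu = alpha (E + T mu)
  arma::mat mu = alpha_md * E;
  arma::mat Tmu(nmol, 3);
  int it = 0; double res = 1.0;
  for (; it < w.scf_maxit; ++it) {
    Tmu.zeros();
    for (int a = 0; a < nmol; ++a) for (int b = a + 1; b < nmol; ++b) {
      double d[3] = { X(3*a,0)-X(3*b,0), X(3*a,1)-X(3*b,1), X(3*a,2)-X(3*b,2) };
      min_image(d, L);
      double r = std::sqrt(d[0]*d[0]+d[1]*d[1]+d[2]*d[2]);
      if (rc > 0.0 && r >= rc) continue;
      double l3, dl3, l5, dl5, sc, dsc;
      thole(r, w.thole_a, l3, dl3, l5, dl5);
      cutsw(r, rc, sc, dsc);
      double g3 = l3 * sc, g5 = l5 * sc;
      double r2 = r * r, r3 = r2 * r, r5 = r3 * r2;
      double mbR = (mu(b,0)*d[0]+mu(b,1)*d[1]+mu(b,2)*d[2]);
      double maR = (mu(a,0)*d[0]+mu(a,1)*d[1]+mu(a,2)*d[2]);
      for (int k = 0; k < 3; ++k) {
        Tmu(a,k) += KC * (3.0 * g5 * mbR * d[k] / r5 - g3 * mu(b,k) / r3);
        Tmu(b,k) += KC * (3.0 * g5 * maR * d[k] / r5 - g3 * mu(a,k) / r3);
      }
    }
    arma::mat mu_new = alpha_md * (E + Tmu);
    res = arma::abs(mu_new - mu).max();
    mu = mu + 0.8 * (mu_new - mu);
    if (res < w.scf_tol) { mu = mu_new; break; }
  }
  if (res >= w.scf_tol) {
    // diagnostic: smallest eigenvalue of A = I/alpha - T
    arma::mat A(3 * nmol, 3 * nmol, arma::fill::zeros);
    A.diag() += 1.0 / alpha_md;
    for (int a = 0; a < nmol; ++a) for (int b = 0; b < nmol; ++b) {
      if (a == b) continue;
      double d[3] = { X(3*a,0)-X(3*b,0), X(3*a,1)-X(3*b,1), X(3*a,2)-X(3*b,2) };
      min_image(d, L);
      double r = std::sqrt(d[0]*d[0]+d[1]*d[1]+d[2]*d[2]);
      if (rc > 0.0 && r >= rc) continue;
      double l3, dl3, l5, dl5, sc, dsc;
      thole(r, w.thole_a, l3, dl3, l5, dl5);
      cutsw(r, rc, sc, dsc);
      double g3 = l3 * sc, g5 = l5 * sc;
      double r2 = r * r, r3 = r2 * r, r5 = r3 * r2;
      for (int u = 0; u < 3; ++u) for (int v = 0; v < 3; ++v)
        A(3*a+u, 3*b+v) -= KC * (3.0 * g5 * d[u] * d[v] / r5
                                 - (u == v ? g3 / r3 : 0.0));
    }
    arma::vec ev = arma::eig_sym(A);
    stop("induced-dipole SCF did not converge in %d iterations "
         "(residual %g; smallest eigenvalue of the polarization matrix %g "
         "suggests %s)", w.scf_maxit, res, ev.min(),
         ev.min() <= 0 ? "a polarization catastrophe" : "slow mixing");
  }
  out.scf_iters = it + 1;
  out.dipoles = mu;
  // induction energy at self-consistency
  out.eind = -0.5 * arma::accu(mu % E);
  if (!grad) return;
  // forces: -dU/dx with U = sum mu^2/2a - mu.E - 1/2 mu T mu at fixed mu
  // charge-dipole part
  for (int m = 0; m < nmol; ++m) {
    int iO = 3 * m;
    for (int j = 0; j < n; ++j) {
      if (j / 3 == m) continue;
      double d[3] = { X(iO,0)-X(j,0), X(iO,1)-X(j,1), X(iO,2)-X(j,2) };
      min_image(d, L);
      double r = std::sqrt(d[0]*d[0]+d[1]*d[1]+d[2]*d[2]);
      if (rc > 0.0 && r >= rc) continue;
      double l3, dl3, l5, dl5, sc, dsc;
      thole(r, w.thole_a, l3, dl3, l5, dl5);
      cutsw(r, rc, sc, dsc);
      double g3 = l3 * sc, dg3 = dl3 * sc + l3 * dsc;
      double r2 = r * r, r3 = r2 * r, r5 = r3 * r2;
      double muR = mu(m,0)*d[0]+mu(m,1)*d[1]+mu(m,2)*d[2];
      // U_pair = -q KC g3 (mu.R)/r^3 ; dU/dR below
      for (int k = 0; k < 3; ++k) {
        double dU = -KC * q[j] * (g3 * (mu(m,k) / r3 - 3.0 * muR * d[k] / r5)
                                  + dg3 * muR * d[k] / (r * r3));
        out.F(iO,k) -= dU;
        out.F(j,k)  += dU;
      }
    }
  }
  // dipole-dipole part
  for (int a = 0; a < nmol; ++a) for (int b = a + 1; b < nmol; ++b) {
    double d[3] = { X(3*a,0)-X(3*b,0), X(3*a,1)-X(3*b,1), X(3*a,2)-X(3*b,2) };
    min_image(d, L);
    double r = std::sqrt(d[0]*d[0]+d[1]*d[1]+d[2]*d[2]);
    if (rc > 0.0 && r >= rc) continue;
    double l3, dl3, l5, dl5, sc, dsc;
    thole(r, w.thole_a, l3, dl3, l5, dl5);
    cutsw(r, rc, sc, dsc);
    double g3 = l3 * sc, dg3 = dl3 * sc + l3 * dsc;
    double g5 = l5 * sc, dg5 = dl5 * sc + l5 * dsc;
    double r2 = r * r, r3 = r2 * r, r5 = r3 * r2, r7 = r5 * r2;
    double maR = mu(a,0)*d[0]+mu(a,1)*d[1]+mu(a,2)*d[2];
    double mbR = mu(b,0)*d[0]+mu(b,1)*d[1]+mu(b,2)*d[2];
    double mab = mu(a,0)*mu(b,0)+mu(a,1)*mu(b,1)+mu(a,2)*mu(b,2);
    // U_pair = -KC [3 g5 (ma.R)(mb.R)/r^5 - g3 (ma.mb)/r^3]
    for (int k = 0; k < 3; ++k) {
      double dU = -KC * (
          3.0 * g5 * (mu(a,k) * mbR + mu(b,k) * maR) / r5
        - 15.0 * g5 * maR * mbR * d[k] / r7
        + 3.0 * dg5 * maR * mbR * d[k] / (r * r5)
        + 3.0 * g3 * mab * d[k] / r5
        - dg3 * mab * d[k] / (r * r3));
      out.F(3*a,k) -= dU;
      out.F(3*b,k) += dU;
    }
  }
}

// ----------------------------------------------- dispersion + short 2B ----
static void pair_oo(const arma::mat& X, int nmol, double L, const WParams& w,
                    bool grad, EvalOut& out) {
  double rc = (L > 0.0) ? w.cutoff : -1.0;
  for (int a = 0; a < nmol; ++a) for (int b = a + 1; b < nmol; ++b) {
    double d[3] = { X(3*a,0)-X(3*b,0), X(3*a,1)-X(3*b,1), X(3*a,2)-X(3*b,2) };
    min_image(d, L);
    double r = std::sqrt(d[0]*d[0]+d[1]*d[1]+d[2]*d[2]);
    if (rc > 0.0 && r >= rc) continue;
    double sc, dsc;
    cutsw(r, rc, sc, dsc);
    // dispersion
    double f6, df6;
    tt6(w.b_disp, r, f6, df6);
    double r6 = std::pow(r, 6);
    double ed = -w.C6 * f6 / r6;
    out.edisp += ed * sc;
    double dEd = (-w.C6 * df6 / r6 + 6.0 * w.C6 * f6 / (r6 * r)) * sc
                 + ed * dsc;                    // dE/dr
    // Born-Mayer 2B with its own switch
    double e2 = 0.0, dE2 = 0.0;
    if (w.use2b) {
      double s2, ds2;
      switch5(r, w.sw2_in, w.sw2_out, s2, ds2);
      double bm = w.A_bm * std::exp(-w.b_bm * r);
      e2 = bm * s2 * sc;
      dE2 = (-w.b_bm * bm * s2 + bm * ds2) * sc + bm * s2 * dsc;
      out.e2b += e2;
    }
    if (grad) {
      double fr = -(dEd + dE2) / r;
      for (int k = 0; k < 3; ++k) {
        out.F(3*a,k) += fr * d[k];  out.F(3*b,k) -= fr * d[k];
      }
    }
  }
}

// ------------------------------------------------------------ short 3B ----
static void triple_atm(const arma::mat& X, int nmol, double L,
                       const WParams& w, bool grad, EvalOut& out) {
  if (!w.use3b) return;
  for (int a = 0; a < nmol; ++a)
  for (int b = a + 1; b < nmol; ++b) {
    double u[3] = { X(3*b,0)-X(3*a,0), X(3*b,1)-X(3*a,1), X(3*b,2)-X(3*a,2) };
    min_image(u, L);
    double s1 = u[0]*u[0]+u[1]*u[1]+u[2]*u[2];
    double rab = std::sqrt(s1);
    if (rab >= w.sw3_out) continue;
    for (int c = b + 1; c < nmol; ++c) {
      double v[3] = { X(3*c,0)-X(3*a,0), X(3*c,1)-X(3*a,1), X(3*c,2)-X(3*a,2) };
      min_image(v, L);
      double s2 = v[0]*v[0]+v[1]*v[1]+v[2]*v[2];
      double rac = std::sqrt(s2);
      if (rac >= w.sw3_out) continue;
      double wv[3] = { v[0]-u[0], v[1]-u[1], v[2]-u[2] };
      double s3 = wv[0]*wv[0]+wv[1]*wv[1]+wv[2]*wv[2];
      double rbc = std::sqrt(s3);
      if (rbc >= w.sw3_out) continue;
      // ATM: E = k [ (s1 s2 s3)^{-3/2} - 3 p1 p2 p3 (s1 s2 s3)^{-5/2} ]
      double p1 = u[0]*v[0]+u[1]*v[1]+u[2]*v[2];        // u.v
      double p2 = u[0]*wv[0]+u[1]*wv[1]+u[2]*wv[2];     // u.w
      double p3 = v[0]*wv[0]+v[1]*wv[1]+v[2]*wv[2];     // v.w
      double S = s1 * s2 * s3;
      double S32 = std::pow(S, -1.5), S52 = std::pow(S, -2.5);
      double G = S32 - 3.0 * p1 * p2 * p3 * S52;
      double swA, dswA, swB, dswB, swC, dswC;
      switch5(rab, w.sw3_in, w.sw3_out, swA, dswA);
      switch5(rac, w.sw3_in, w.sw3_out, swB, dswB);
      switch5(rbc, w.sw3_in, w.sw3_out, swC, dswC);
      double sw = swA * swB * swC;
      out.e3b += w.k3b * G * sw;
      if (!grad) continue;
      // dG wrt u,v,w (w depends on u,v: total derivative below)
      double dS32 = -1.5 * S32 / S, dS52 = -2.5 * S52 / S;
      // G = S^{-3/2} - 3 p1 p2 p3 S^{-5/2}
      double dG_dS = dS32 - 3.0 * p1 * p2 * p3 * dS52;
      double dG_dp1 = -3.0 * p2 * p3 * S52;
      double dG_dp2 = -3.0 * p1 * p3 * S52;
      double dG_dp3 = -3.0 * p1 * p2 * S52;
      double gu[3], gv[3], gw[3];                 // dG/du etc. (partial)
      for (int k = 0; k < 3; ++k) {
        gu[k] = dG_dS * 2.0 * u[k] * s2 * s3 + dG_dp1 * v[k] + dG_dp2 * wv[k];
        gv[k] = dG_dS * 2.0 * v[k] * s1 * s3 + dG_dp1 * u[k] + dG_dp3 * wv[k];
        gw[k] = dG_dS * 2.0 * wv[k] * s1 * s2 + dG_dp2 * u[k] + dG_dp3 * v[k];
      }
      // switch gradients: rab depends on u, rac on v, rbc on w
      double cA = G * dswA * swB * swC / rab;
      double cB = G * swA * dswB * swC / rac;
      double cC = G * swA * swB * dswC / rbc;
      // dE/du = k [ sw*gu + cA*u ] - plus w-chain: w = v - u
      for (int k = 0; k < 3; ++k) {
        double dEdu = w.k3b * (sw * (gu[k] - gw[k]) + cA * u[k] - cC * wv[k]);
        double dEdv = w.k3b * (sw * (gv[k] + gw[k]) + cB * v[k] + cC * wv[k]);
        // u = rb - ra, v = rc - ra
        out.F(3*b,k) -= dEdu;
        out.F(3*c,k) -= dEdv;
        out.F(3*a,k) += dEdu + dEdv;
      }
    }
  }
}

static void check_floor(const arma::mat& X, double L) {
  int n = X.n_rows;
  for (int i = 0; i < n; ++i) for (int j = i + 1; j < n; ++j) {
    double d[3] = { X(i,0)-X(j,0), X(i,1)-X(j,1), X(i,2)-X(j,2) };
    min_image(d, L);
    double r2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
    if (r2 < HARD_FLOOR * HARD_FLOOR)
      stop("atoms %d and %d closer than the %.1f A hard floor (r = %.3f A); "
           "the potential is undefined here", i + 1, j + 1, HARD_FLOOR,
           std::sqrt(r2));
  }
}

// [[Rcpp::export]]
List water_eval_cpp(NumericMatrix coords, double box_edge, List params,
                    bool do_forces) {
  arma::mat X(coords.begin(), coords.nrow(), 3, true);
  WParams w = read_params(params);
  int n = X.n_rows, nmol = n / 3;
  double L = box_edge;                         // <= 0 for cluster
  if (L > 0.0 && w.cutoff > 0.5 * L)
    stop("cutoff %.2f A exceeds half the box edge (%.2f A)", w.cutoff, 0.5*L);
  check_floor(X, L);
  EvalOut out;
  out.F.zeros(n, 3);
  arma::vec q(n);
  for (int m = 0; m < nmol; ++m) {
    q[3*m] = w.qO; q[3*m+1] = w.qH; q[3*m+2] = w.qH;
  }
  one_body(X, nmol, w, do_forces, out);
  if (nmol > 1) {
    if (L > 0.0) elec_ewald(X, q, nmol, L, w.cutoff, w.ewald_tol,
                            do_forces, out);
    else elec_direct(X, q, nmol, do_forces, out);
    induction(X, q, nmol, L, w, do_forces, out);
    pair_oo(X, nmol, L, w, do_forces, out);
    if (nmol > 2) triple_atm(X, nmol, L, w, do_forces, out);
  } else {
    out.dipoles.zeros(nmol, 3);
  }
  double total = out.e1b + out.elec + out.eind + out.edisp + out.e2b + out.e3b;
  return List::create(
    _["energy"] = total,
    _["terms"] = NumericVector::create(
      _["one_body"] = out.e1b, _["electrostatic"] = out.elec,
      _["induction"] = out.eind, _["dispersion"] = out.edisp,
      _["short_2b"] = out.e2b, _["short_3b"] = out.e3b),
    _["forces"] = wrap(out.F),
    _["dipoles"] = wrap(out.dipoles),
    _["scf_iters"] = out.scf_iters);
}

// Generic point-charge Ewald sum (no exclusions): energy and forces.
// [[Rcpp::export]]
List ewald_cpp(NumericMatrix coords, NumericVector charges, double box_edge,
               double cutoff, double tol, bool do_forces) {
  arma::mat X(coords.begin(), coords.nrow(), 3, true);
  arma::vec q(charges.begin(), charges.size(), true);
  int n = X.n_rows;
  double L = box_edge;
  if (std::abs(arma::accu(q)) > 1e-8)
    stop("Ewald sum requires a charge-neutral system (net charge %g)",
         arma::accu(q));
  if (cutoff > 0.5 * L)
    stop("cutoff exceeds half the box edge");
  double s = std::sqrt(-std::log(tol));
  double alpha = s / cutoff;
  double kmax = 2.0 * alpha * s;
  int nmax = (int)std::ceil(kmax * L / (2.0 * M_PI));
  double E = 0.0;
  arma::mat F(n, 3, arma::fill::zeros);
  for (int i = 0; i < n; ++i) for (int j = i + 1; j < n; ++j) {
    double d[3] = { X(i,0)-X(j,0), X(i,1)-X(j,1), X(i,2)-X(j,2) };
    min_image(d, L);
    double r2 = d[0]*d[0]+d[1]*d[1]+d[2]*d[2];
    if (r2 >= cutoff * cutoff) continue;
    double r = std::sqrt(r2);
    double erfc_ = std::erfc(alpha * r);
    E += KC * q[i] * q[j] * erfc_ / r;
    if (do_forces) {
      double fr = KC * q[i] * q[j] *
        (erfc_ / r2 + 2.0 * alpha / std::sqrt(M_PI) *
         std::exp(-alpha * alpha * r2) / r) / r;
      for (int k = 0; k < 3; ++k) { F(i,k) += fr*d[k]; F(j,k) -= fr*d[k]; }
    }
  }
  double V = L * L * L, twoPiL = 2.0 * M_PI / L, k2max = kmax * kmax;
  for (int mx = 0; mx <= nmax; ++mx)
  for (int my = (mx == 0 ? 0 : -nmax); my <= nmax; ++my)
  for (int mz = ((mx == 0 && my == 0) ? 1 : -nmax); mz <= nmax; ++mz) {
    double kx = twoPiL*mx, ky = twoPiL*my, kz = twoPiL*mz;
    double k2 = kx*kx+ky*ky+kz*kz;
    if (k2 > k2max) continue;
    std::complex<double> S(0.0, 0.0);
    std::vector<std::complex<double> > eik(n);
    for (int i = 0; i < n; ++i) {
      double ph = kx*X(i,0)+ky*X(i,1)+kz*X(i,2);
      eik[i] = std::complex<double>(std::cos(ph), std::sin(ph));
      S += q[i] * eik[i];
    }
    double A = 2.0 * 2.0 * M_PI * KC / V * std::exp(-k2/(4.0*alpha*alpha)) / k2;
    E += A * std::norm(S);
    if (do_forces) {
      for (int i = 0; i < n; ++i) {
        double f = 2.0 * A * q[i] * std::imag(std::conj(S) * eik[i]);
        F(i,0) += f*kx; F(i,1) += f*ky; F(i,2) += f*kz;
      }
    }
  }
  E -= KC * alpha / std::sqrt(M_PI) * arma::dot(q, q);
  return List::create(_["energy"] = E, _["forces"] = wrap(F),
                      _["alpha"] = alpha, _["nmax"] = nmax);
}
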