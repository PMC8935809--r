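// Bundled AM1 semi-empirical engine: restricted Hartree-Fock SCF over the
// NDDO integral approximation with the published AM1 parameterization
// (Dewar, Zoebisch, Healy & Stewart 1985; halogen and sulfur extensions).
// Energies are heats of formation in kcal/mol; geometry optimization uses
// BFGS on Cartesian coordinates with pairwise finite-difference gradients
// evaluated at frozen (converged) density, which is exact at SCF stationarity.
//
// Unit conventions follow the historical MOPAC ones so that computed heats
// of formation line up with the literature AM1 values: lengths in angstrom
// at the interface, bohr inside the integral code; energies in eV inside
// the SCF, converted to kcal/mol at the end.

#include <RcppArmadillo.h>
#include <deque>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double A0      = 0.529167;   // angstrom per bohr (MOPAC value)
static const double EV      = 27.21;      // eV per hartree (MOPAC value)
static const double EV2KCAL = 23.061;     // kcal/mol per eV (MOPAC value)

// ---------------------------------------------------------------------------
// element parameters
// ---------------------------------------------------------------------------

struct Elem {
  int z;            // atomic number
  int zval;         // core (valence) charge
  int nq;           // principal quantum number of the valence shell
  bool has_p;
  double uss, upp;  // one-electron one-center energies, eV
  double bs, bp;    // resonance betas, eV
  double zs, zp;    // Slater exponents, bohr^-1
  double alpha;     // core-core exponent, 1/angstrom
  double gss, gsp, gpp, gp2, hsp;  // one-center two-electron integrals, eV
  int ng;           // number of AM1 core Gaussians
  double gk[4], gl[4], gm[4];      // K (eV*angstrom), L (1/angstrom^2), M (angstrom)
  double eheat;     // experimental heat of formation of the atom, kcal/mol
  // derived
  double eisol;     // energy of the isolated atom, eV
  double dd, qq;    // multipole charge separations, bohr
  double rho0, rho1, rho2;  // Klopman additive terms, bohr
};

static Elem ELEMS[8];
static bool ELEMS_READY = false;

// index into ELEMS by atomic number, -1 if unsupported
static int elem_slot(int z) {
  switch (z) {
    case 1:  return 0;  // H
    case 6:  return 1;  // C
    case 7:  return 2;  // N
    case 8:  return 3;  // O
    case 9:  return 4;  // F
    case 16: return 5;  // S
    case 17: return 6;  // Cl
    case 35: return 7;  // Br
  }
  return -1;
}

// isolated-atom energy from the one-center parameters, Hund ground state
static double compute_eisol(const Elem &e) {
  int ns = std::min(e.zval, 2);
  int np = e.zval - ns;
  int nsa = std::min(ns, 1), nsb = ns - nsa;
  int npa = std::min(np, 3), npb = np - npa;
  double hpp = 0.5 * (e.gpp - e.gp2);
  double en = ns * e.uss + np * e.upp;
  en += (ns * (ns - 1) / 2) * e.gss;
  en += ns * np * e.gsp;
  en -= (nsa * npa + nsb * npb) * e.hsp;
  int same_orb = npb;                                     // doubly occupied p pairs
  int ss_pairs = npa * (npa - 1) / 2 + npb * (npb - 1) / 2;
  int os_diff  = npb * (npa - 1);
  en += same_orb * e.gpp;
  en += (ss_pairs + os_diff) * e.gp2;
  en -= ss_pairs * hpp;
  return en;
}

// self-interaction of the square-quadrupole charge configuration (used to
// solve for rho2); rho and qq in bohr, result in hartree
static double quad_self(double qq, double rho) {
  double add2 = 4.0 * rho * rho;
  // charges +-1/4 at (+-qq, +-qq), sign pattern sign(x*y)
  double d1 = 0.0;                       // coincident pairs, same sign
  double d2 = 4.0 * qq * qq;             // side, opposite sign
  double d3 = 8.0 * qq * qq;             // diagonal, same sign
  return 4.0 * (1.0 / 16.0) / std::sqrt(d1 + add2)
       - 8.0 * (1.0 / 16.0) / std::sqrt(d2 + add2)
       + 4.0 * (1.0 / 16.0) / std::sqrt(d3 + add2);
}

// dipole self-interaction (solve for rho1)
static double dip_self(double dd, double rho) {
  return 1.0 / (4.0 * rho) - 1.0 / (4.0 * std::sqrt(dd * dd + rho * rho));
}

template <typename F>
static double bisect(F f, double target, double lo, double hi) {
  double flo = f(lo) - target, fhi = f(hi) - target;
  if (flo * fhi > 0) return (std::fabs(flo) < std::fabs(fhi)) ? lo : hi;
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi);
    double fm = f(mid) - target;
    if (fm * flo <= 0) { hi = mid; } else { lo = mid; flo = fm; }
  }
  return 0.5 * (lo + hi);
}

static void finish_elem(Elem &e) {
  e.eisol = compute_eisol(e);
  if (e.has_p) {
    int n = e.nq;
    e.dd = (2.0 * n + 1.0) * std::pow(4.0 * e.zs * e.zp, n + 0.5) /
           (std::sqrt(3.0) * std::pow(e.zs + e.zp, 2.0 * n + 2.0));
    e.qq = std::sqrt((4.0 * n * n + 6.0 * n + 2.0) / 20.0) / e.zp;
  } else {
    e.dd = 0.0; e.qq = 0.0;
  }
  e.rho0 = EV / (2.0 * e.gss);
  if (e.has_p) {
    double hsp_au = e.hsp / EV;
    double hpp_au = 0.5 * (e.gpp - e.gp2) / EV;
    double dd = e.dd, qq = e.qq;
    e.rho1 = bisect([dd](double r) { return dip_self(dd, r); }, hsp_au, 0.005, 50.0);
    e.rho2 = bisect([qq](double r) { return quad_self(qq, r); }, hpp_au, 0.005, 50.0);
  } else {
    e.rho1 = e.rho0; e.rho2 = e.rho0;
  }
}

static void set_gauss(Elem &e, std::initializer_list<double> k,
                      std::initializer_list<double> l,
                      std::initializer_list<double> m) {
  e.ng = (int)k.size();
  int i = 0; for (double v : k) e.gk[i++] = v;
  i = 0;     for (double v : l) e.gl[i++] = v;
  i = 0;     for (double v : m) e.gm[i++] = v;
}

static void init_elems() {
  if (ELEMS_READY) return;
  Elem e;

  // hydrogen
  e = Elem(); e.z = 1; e.zval = 1; e.nq = 1; e.has_p = false;
  e.uss = -11.396427; e.upp = 0.0;
  e.bs = -6.173787; e.bp = 0.0;
  e.zs = 1.188078; e.zp = 0.0;
  e.alpha = 2.882324;
  e.gss = 12.848; e.gsp = 0; e.gpp = 0; e.gp2 = 0; e.hsp = 0;
  set_gauss(e, {0.122796, 0.005090, -0.018336}, {5.0, 5.0, 2.0}, {1.2, 1.8, 2.1});
  e.eheat = 52.102;
  finish_elem(e); ELEMS[0] = e;

  // carbon
  e = Elem(); e.z = 6; e.zval = 4; e.nq = 2; e.has_p = true;
  e.uss = -52.028658; e.upp = -39.614239;
  e.bs = -15.715783; e.bp = -7.719283;
  e.zs = 1.808665; e.zp = 1.685116;
  e.alpha = 2.648274;
  e.gss = 12.23; e.gsp = 11.47; e.gpp = 11.08; e.gp2 = 9.84; e.hsp = 2.43;
  set_gauss(e, {0.011355, 0.045924, -0.020061, -0.001260},
               {5.0, 5.0, 5.0, 5.0}, {1.60, 1.85, 2.05, 2.65});
  e.eheat = 170.89;
  finish_elem(e); ELEMS[1] = e;

  // nitrogen
  e = Elem(); e.z = 7; e.zval = 5; e.nq = 2; e.has_p = true;
  e.uss = -71.860000; e.upp = -57.167581;
  e.bs = -20.299110; e.bp = -18.238666;
  e.zs = 2.315410; e.zp = 2.157940;
  e.alpha = 2.947286;
  e.gss = 13.59; e.gsp = 12.66; e.gpp = 12.98; e.gp2 = 11.59; e.hsp = 3.14;
  set_gauss(e, {0.025251, 0.028953, -0.005806}, {5.0, 5.0, 2.0}, {1.50, 2.10, 2.40});
  e.eheat = 113.00;
  finish_elem(e); ELEMS[2] = e;

  // oxygen
  e = Elem(); e.z = 8; e.zval = 6; e.nq = 2; e.has_p = true;
  e.uss = -97.830000; e.upp = -78.262380;
  e.bs = -29.272773; e.bp = -29.272773;
  e.zs = 3.108032; e.zp = 2.524039;
  e.alpha = 4.455371;
  e.gss = 15.42; e.gsp = 14.48; e.gpp = 14.52; e.gp2 = 12.98; e.hsp = 3.94;
  set_gauss(e, {0.280962, 0.081430}, {5.0, 7.0}, {0.847918, 1.445071});
  e.eheat = 59.559;
  finish_elem(e); ELEMS[3] = e;

  // fluorine
  e = Elem(); e.z = 9; e.zval = 7; e.nq = 2; e.has_p = true;
  e.uss = -136.105579; e.upp = -104.889885;
  e.bs = -69.590277; e.bp = -27.922360;
  e.zs = 3.770082; e.zp = 2.494670;
  e.alpha = 5.517800;
  e.gss = 16.92; e.gsp = 17.25; e.gpp = 16.71; e.gp2 = 14.91; e.hsp = 4.83;
  set_gauss(e, {0.242079, 0.003607}, {4.80, 4.60}, {0.930, 1.660});
  e.eheat = 18.89;
  finish_elem(e); ELEMS[4] = e;

  // sulfur
  e = Elem(); e.z = 16; e.zval = 6; e.nq = 3; e.has_p = true;
  e.uss = -56.694056; e.upp = -48.717049;
  e.bs = -3.920566; e.bp = -7.905278;
  e.zs = 2.366515; e.zp = 1.667263;
  e.alpha = 2.461648;
  e.gss = 11.786329; e.gsp = 8.663127; e.gpp = 10.039308; e.gp2 = 7.781688; e.hsp = 2.532137;
  set_gauss(e, {-0.509195, -0.011863, 0.012334},
               {4.593691, 5.865731, 13.557336}, {0.770665, 1.503313, 2.009173});
  e.eheat = 66.40;
  finish_elem(e); ELEMS[5] = e;

  // chlorine
  e = Elem(); e.z = 17; e.zval = 7; e.nq = 3; e.has_p = true;
  e.uss = -111.613948; e.upp = -76.640107;
  e.bs = -24.594670; e.bp = -14.637216;
  e.zs = 3.631376; e.zp = 2.076799;
  e.alpha = 2.919368;
  e.gss = 15.03; e.gsp = 13.16; e.gpp = 11.30; e.gp2 = 9.97; e.hsp = 2.42;
  set_gauss(e, {0.094243, 0.027168}, {4.0, 4.0}, {1.30, 2.10});
  e.eheat = 28.99;
  finish_elem(e); ELEMS[6] = e;

  // bromine
  e = Elem(); e.z = 35; e.zval = 7; e.nq = 4; e.has_p = true;
  e.uss = -104.656063; e.upp = -74.930052;
  e.bs = -19.399880; e.bp = -8.957195;
  e.zs = 3.064133; e.zp = 2.038333;
  e.alpha = 2.576546;
  e.gss = 15.03643948; e.gsp = 13.03468242; e.gpp = 11.27632539;
  e.gp2 = 9.85442552; e.hsp = 2.45586832;
  set_gauss(e, {0.066685, 0.025568}, {4.0, 4.0}, {1.50, 2.30});
  e.eheat = 26.74;
  finish_elem(e); ELEMS[7] = e;

  ELEMS_READY = true;
}

// ---------------------------------------------------------------------------
// Slater-orbital overlap integrals (prolate-spheroidal A/B-function method)
// ---------------------------------------------------------------------------

static const int PMAX = 14;

struct Poly2 {
  double c[PMAX][PMAX];
  int dx, dy;
  Poly2() : dx(0), dy(0) { std::memset(c, 0, sizeof(c)); }
};

static Poly2 poly_const(double v) { Poly2 p; p.c[0][0] = v; return p; }

static Poly2 poly_mul(const Poly2 &a, const Poly2 &b) {
  Poly2 r; r.dx = a.dx + b.dx; r.dy = a.dy + b.dy;
  for (int i = 0; i <= a.dx; ++i)
    for (int j = 0; j <= a.dy; ++j) {
      if (a.c[i][j] == 0.0) continue;
      for (int k = 0; k <= b.dx; ++k)
        for (int l = 0; l <= b.dy; ++l)
          if (b.c[k][l] != 0.0) r.c[i + k][j + l] += a.c[i][j] * b.c[k][l];
    }
  return r;
}

// (xi + s*eta)^pow
static Poly2 poly_binom(double s, int pow) {
  Poly2 r = poly_const(1.0);
  Poly2 base; base.dx = 1; base.dy = 1; base.c[1][0] = 1.0; base.c[0][1] = s;
  for (int i = 0; i < pow; ++i) r = poly_mul(r, base);
  return r;
}

static void afun(double p, int nmax, double *A) {
  double ep = std::exp(-p);
  A[0] = ep / p;
  for (int n = 1; n <= nmax; ++n) A[n] = (n * A[n - 1] + ep) / p;
}

static void bfun(double pt, int nmax, double *B) {
  if (std::fabs(pt) < 0.35) {
    for (int n = 0; n <= nmax; ++n) {
      double sum = 0.0, term = 1.0;  // (-pt)^k / k!
      for (int k = 0; k < 40; ++k) {
        if ((n + k) % 2 == 0) sum += term * 2.0 / (n + k + 1);
        term *= -pt / (k + 1);
        if (std::fabs(term) < 1e-17) break;
      }
      B[n] = sum;
    }
  } else {
    double ep = std::exp(pt), em = std::exp(-pt);
    B[0] = (ep - em) / pt;
    for (int n = 1; n <= nmax; ++n)
      B[n] = (n * B[n - 1] + ((n % 2 == 0) ? (ep - em) : (-ep - em))) / pt;
  }
}

static double factorial(int n) {
  double f = 1.0; for (int i = 2; i <= n; ++i) f *= i; return f;
}

// overlap between Slater orbitals on centers separated by R (bohr), with the
// inter-atomic axis as local z.  la/lb: 0 = s, 1 = p.  m: 0 = sigma, 1 = pi.
static double slater_overlap(int na, int la, double za,
                             int nb, int lb, double zb,
                             double R, int m) {
  if (m == 1 && (la != 1 || lb != 1)) return 0.0;
  Poly2 P;
  if (m == 1) {
    // pi-pi: (xi+eta)^(na-2) (xi-eta)^(nb-2) (xi^2-1)(1-eta^2)
    Poly2 f = poly_mul(poly_binom(1.0, na - 2), poly_binom(-1.0, nb - 2));
    Poly2 g; g.dx = 2; g.dy = 2;
    // (xi^2-1)(1-eta^2) = xi^2 - xi^2 eta^2 - 1 + eta^2
    g.c[2][0] = 1.0; g.c[2][2] = -1.0; g.c[0][0] = -1.0; g.c[0][2] = 1.0;
    P = poly_mul(f, g);
  } else {
    Poly2 fa, fb;
    if (la == 0) fa = poly_binom(1.0, na - 1);
    else {
      Poly2 t; t.dx = 1; t.dy = 1; t.c[0][0] = 1.0; t.c[1][1] = 1.0;  // 1 + xi eta
      fa = poly_mul(poly_binom(1.0, na - 2), t);
    }
    if (lb == 0) fb = poly_binom(-1.0, nb - 1);
    else {
      Poly2 t; t.dx = 1; t.dy = 1; t.c[0][0] = -1.0; t.c[1][1] = 1.0;  // xi eta - 1
      fb = poly_mul(poly_binom(-1.0, nb - 2), t);
    }
    P = poly_mul(fa, fb);
  }
  // volume element factor (xi^2 - eta^2)
  Poly2 vol; vol.dx = 2; vol.dy = 2; vol.c[2][0] = 1.0; vol.c[0][2] = -1.0;
  P = poly_mul(P, vol);

  double p  = 0.5 * R * (za + zb);
  double pt = 0.5 * R * (za - zb);
  double A[PMAX + 2], B[PMAX + 2];
  afun(p, P.dx, A);
  bfun(pt, P.dy, B);

  double sum = 0.0;
  for (int i = 0; i <= P.dx; ++i)
    for (int j = 0; j <= P.dy; ++j)
      if (P.c[i][j] != 0.0) sum += P.c[i][j] * A[i] * B[j];

  double Nra = std::pow(2.0 * za, na + 0.5) / std::sqrt(factorial(2 * na));
  double Nrb = std::pow(2.0 * zb, nb + 0.5) / std::sqrt(factorial(2 * nb));
  double ang = std::sqrt((2.0 * la + 1.0) * (2.0 * lb + 1.0)) / (4.0 * M_PI);
  double phi = (m == 1) ? M_PI : 2.0 * M_PI;
  return Nra * Nrb * ang * phi * std::pow(0.5 * R, na + nb + 1) * sum;
}

// ---------------------------------------------------------------------------
// NDDO two-electron integrals via point-charge multipole configurations
// ---------------------------------------------------------------------------

struct Cfg {
  int n;            // number of point charges
  double q[4];
  double r[4][3];   // positions relative to the atom, bohr
  int l;            // multipole order (selects the additive term)
};

// charge configurations for an orbital-pair distribution (i <= j, 0 = s,
// 1..3 = p_x, p_y, p_z); may contribute up to two configurations
static int dist_cfgs(const Elem &e, int i, int j, Cfg out[2]) {
  int n = 0;
  if (i == 0 && j == 0) {
    Cfg c; c.n = 1; c.q[0] = 1.0; c.r[0][0] = c.r[0][1] = c.r[0][2] = 0.0; c.l = 0;
    out[n++] = c;
  } else if (i == 0) {
    int ax = j - 1;
    Cfg c; c.n = 2; c.l = 1;
    c.q[0] = 0.5; c.q[1] = -0.5;
    for (int k = 0; k < 3; ++k) { c.r[0][k] = 0.0; c.r[1][k] = 0.0; }
    c.r[0][ax] = e.dd; c.r[1][ax] = -e.dd;
    out[n++] = c;
  } else if (i == j) {
    int ax = i - 1;
    Cfg cq; cq.n = 1; cq.q[0] = 1.0; cq.r[0][0] = cq.r[0][1] = cq.r[0][2] = 0.0; cq.l = 0;
    out[n++] = cq;
    Cfg c; c.n = 3; c.l = 2;
    c.q[0] = 0.25; c.q[1] = 0.25; c.q[2] = -0.5;
    for (int k = 0; k < 3; ++k) { c.r[0][k] = 0.0; c.r[1][k] = 0.0; c.r[2][k] = 0.0; }
    c.r[0][ax] = 2.0 * e.qq; c.r[1][ax] = -2.0 * e.qq;
    out[n++] = c;
  } else {
    int a1 = i - 1, a2 = j - 1;
    Cfg c; c.n = 4; c.l = 2;
    double s[4][2] = {{1, 1}, {1, -1}, {-1, 1}, {-1, -1}};
    for (int t = 0; t < 4; ++t) {
      c.q[t] = 0.25 * s[t][0] * s[t][1];
      for (int k = 0; k < 3; ++k) c.r[t][k] = 0.0;
      c.r[t][a1] = s[t][0] * e.qq;
      c.r[t][a2] = s[t][1] * e.qq;
    }
    out[n++] = c;
  }
  return n;
}

static inline int pidx(int i, int j) {  // index of unordered orbital pair, i<=j
  static const int map[4][4] = {{0, 1, 2, 3}, {1, 4, 5, 6}, {2, 5, 7, 8}, {3, 6, 8, 9}};
  return map[i][j];
}
static const int PAIR_I[10] = {0, 0, 0, 0, 1, 1, 1, 2, 2, 3};
static const int PAIR_J[10] = {0, 1, 2, 3, 1, 2, 3, 2, 3, 3};

// two-center two-electron integrals in the local diatomic frame (B on the
// +z axis); result in eV.  The point-charge multipole model is only defined
// on-axis; arbitrary orientations are handled by tensor rotation afterwards.
static void pair_eris_local(const Elem &ea, const Elem &eb, const double *Rvec,
                            double g[10][10]) {
  double rhoA[3] = {ea.rho0, ea.rho1, ea.rho2};
  double rhoB[3] = {eb.rho0, eb.rho1, eb.rho2};
  int npa = ea.has_p ? 10 : 1;
  int npb = eb.has_p ? 10 : 1;
  Cfg ca[2], cb[2];
  for (int pa = 0; pa < npa; ++pa) {
    int na = dist_cfgs(ea, PAIR_I[pa], PAIR_J[pa], ca);
    for (int pb = 0; pb < npb; ++pb) {
      int nb = dist_cfgs(eb, PAIR_I[pb], PAIR_J[pb], cb);
      double v = 0.0;
      for (int ia = 0; ia < na; ++ia)
        for (int ib = 0; ib < nb; ++ib) {
          double add = rhoA[ca[ia].l] + rhoB[cb[ib].l];
          double add2 = add * add;
          for (int s = 0; s < ca[ia].n; ++s)
            for (int t = 0; t < cb[ib].n; ++t) {
              double dx = ca[ia].r[s][0] - (Rvec[0] + cb[ib].r[t][0]);
              double dy = ca[ia].r[s][1] - (Rvec[1] + cb[ib].r[t][1]);
              double dz = ca[ia].r[s][2] - (Rvec[2] + cb[ib].r[t][2]);
              v += ca[ia].q[s] * cb[ib].q[t] /
                   std::sqrt(dx * dx + dy * dy + dz * dz + add2);
            }
        }
      g[pa][pb] = v * EV;
    }
  }
}

// rotate local-frame integrals to the global frame; Rvec in bohr
static void pair_eris(const Elem &ea, const Elem &eb, const double *Rvec,
                      double g[10][10]) {
  double R = std::sqrt(Rvec[0] * Rvec[0] + Rvec[1] * Rvec[1] + Rvec[2] * Rvec[2]);
  double loc[10][10];
  double Rloc[3] = {0.0, 0.0, R};
  pair_eris_local(ea, eb, Rloc, loc);
  int npa = ea.has_p ? 10 : 1;
  int npb = eb.has_p ? 10 : 1;
  if (!ea.has_p && !eb.has_p) { g[0][0] = loc[0][0]; return; }
  // orthonormal local axes: ez along A->B, ex/ey any perpendicular pair
  double u[3] = {Rvec[0] / R, Rvec[1] / R, Rvec[2] / R};
  double ax[3], ay[3];
  if (std::fabs(u[2]) < 0.99) { ax[0] = -u[1]; ax[1] = u[0]; ax[2] = 0.0; }
  else                        { ax[0] = 1.0;  ax[1] = 0.0;  ax[2] = 0.0; }
  // orthogonalize and normalize ax against u
  double d = ax[0] * u[0] + ax[1] * u[1] + ax[2] * u[2];
  for (int k = 0; k < 3; ++k) ax[k] -= d * u[k];
  double nx = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
  for (int k = 0; k < 3; ++k) ax[k] /= nx;
  ay[0] = u[1] * ax[2] - u[2] * ax[1];
  ay[1] = u[2] * ax[0] - u[0] * ax[2];
  ay[2] = u[0] * ax[1] - u[1] * ax[0];
  // orbital transformation: global orbital a = sum_k O[a][k] * local orbital k
  double O[4][4] = {{1, 0, 0, 0}, {0, 0, 0, 0}, {0, 0, 0, 0}, {0, 0, 0, 0}};
  for (int i = 0; i < 3; ++i) {
    O[i + 1][1] = ax[i]; O[i + 1][2] = ay[i]; O[i + 1][3] = u[i];
  }
  int limA = ea.has_p ? 4 : 1, limB = eb.has_p ? 4 : 1;
  // first contract the A-side pair, then the B-side pair
  double half[10][10];
  for (int pa = 0; pa < npa; ++pa) {
    int a = PAIR_I[pa], b = PAIR_J[pa];
    for (int pb = 0; pb < npb; ++pb) half[pa][pb] = 0.0;
    for (int k = 0; k < limA; ++k) {
      if (O[a][k] == 0.0) continue;
      for (int l = 0; l < limA; ++l) {
        double w = O[a][k] * O[b][l];
        if (w == 0.0) continue;
        const double *row = loc[pidx(std::min(k, l), std::max(k, l))];
        for (int pb = 0; pb < npb; ++pb) half[pa][pb] += w * row[pb];
      }
    }
  }
  for (int pa = 0; pa < npa; ++pa) {
    for (int pb = 0; pb < npb; ++pb) {
      int c = PAIR_I[pb], dd2 = PAIR_J[pb];
      double v = 0.0;
      for (int m = 0; m < limB; ++m) {
        if (O[c][m] == 0.0) continue;
        for (int n = 0; n < limB; ++n) {
          double w = O[c][m] * O[dd2][n];
          if (w == 0.0) continue;
          v += w * half[pa][pidx(std::min(m, n), std::max(m, n))];
        }
      }
      g[pa][pb] = v;
    }
  }
}

// overlap block S[4][4] between the orbitals of atoms A and B (global frame);
// Rvec in bohr
static void pair_overlap(const Elem &ea, const Elem &eb, const double *Rvec,
                         double S[4][4]) {
  double R = std::sqrt(Rvec[0] * Rvec[0] + Rvec[1] * Rvec[1] + Rvec[2] * Rvec[2]);
  double u[3] = {Rvec[0] / R, Rvec[1] / R, Rvec[2] / R};
  double sss = slater_overlap(ea.nq, 0, ea.zs, eb.nq, 0, eb.zs, R, 0);
  double sps = 0, pss = 0, ss_ = 0, pp_ = 0;
  if (eb.has_p) sps = slater_overlap(ea.nq, 0, ea.zs, eb.nq, 1, eb.zp, R, 0);
  if (ea.has_p) pss = slater_overlap(ea.nq, 1, ea.zp, eb.nq, 0, eb.zs, R, 0);
  if (ea.has_p && eb.has_p) {
    ss_ = slater_overlap(ea.nq, 1, ea.zp, eb.nq, 1, eb.zp, R, 0);  // sigma-sigma
    pp_ = slater_overlap(ea.nq, 1, ea.zp, eb.nq, 1, eb.zp, R, 1);  // pi-pi
  }
  S[0][0] = sss;
  for (int k = 0; k < 3; ++k) {
    S[0][k + 1] = sps * u[k];
    S[k + 1][0] = pss * u[k];
    for (int l = 0; l < 3; ++l)
      S[k + 1][l + 1] = ss_ * u[k] * u[l] + pp_ * ((k == l ? 1.0 : 0.0) - u[k] * u[l]);
  }
}

// core-core repulsion for a pair, eV; R in angstrom, gss_ss = (sAsA|sBsB) eV
static double pair_core(const Elem &ea, const Elem &eb, double R, double gss_ss) {
  bool a_nh = (ea.z == 7 || ea.z == 8) && eb.z == 1;
  bool b_nh = (eb.z == 7 || eb.z == 8) && ea.z == 1;
  double scale = 1.0;
  if (a_nh)      scale += R * std::exp(-ea.alpha * R) + std::exp(-eb.alpha * R);
  else if (b_nh) scale += std::exp(-ea.alpha * R) + R * std::exp(-eb.alpha * R);
  else           scale += std::exp(-ea.alpha * R) + std::exp(-eb.alpha * R);
  double e = ea.zval * eb.zval * gss_ss * scale;
  double gsum = 0.0;
  for (int k = 0; k < ea.ng; ++k)
    gsum += ea.gk[k] * std::exp(-ea.gl[k] * (R - ea.gm[k]) * (R - ea.gm[k]));
  for (int k = 0; k < eb.ng; ++k)
    gsum += eb.gk[k] * std::exp(-eb.gl[k] * (R - eb.gm[k]) * (R - eb.gm[k]));
  e += ea.zval * eb.zval / R * gsum;
  return e;
}

// ---------------------------------------------------------------------------
// molecule / SCF machinery
// ---------------------------------------------------------------------------

struct PairBlock {
  double S[4][4];
  double g[10][10];
  double enuc;
};

struct Molecule {
  int nat;
  std::vector<int> slot;       // element slot per atom
  std::vector<int> first;      // first basis index per atom
  std::vector<int> nbas_at;    // 1 or 4
  int nbas;
  int nelec;
  arma::mat xyz;               // angstrom, nat x 3

  void setup(const std::vector<int> &z, int charge) {
    init_elems();
    nat = (int)z.size();
    slot.resize(nat); first.resize(nat); nbas_at.resize(nat);
    nbas = 0; nelec = 0;
    for (int i = 0; i < nat; ++i) {
      int s = elem_slot(z[i]);
      if (s < 0) stop("unsupported element (Z=%d) in AM1 engine", z[i]);
      slot[i] = s;
      first[i] = nbas;
      nbas_at[i] = ELEMS[s].has_p ? 4 : 1;
      nbas += nbas_at[i];
      nelec += ELEMS[s].zval;
    }
    nelec -= charge;
    if (nelec % 2 != 0)
      stop("odd electron count: the bundled AM1 engine is closed-shell (RHF) only");
  }

  void pair_block(int i, int j, const double *xyzi, const double *xyzj,
                  PairBlock &pb) const {
    const Elem &ea = ELEMS[slot[i]], &eb = ELEMS[slot[j]];
    double Rv[3], Rb[3];
    for (int k = 0; k < 3; ++k) { Rv[k] = xyzj[k] - xyzi[k]; Rb[k] = Rv[k] / A0; }
    double R = std::sqrt(Rv[0] * Rv[0] + Rv[1] * Rv[1] + Rv[2] * Rv[2]);
    pair_eris(ea, eb, Rb, pb.g);
    pair_overlap(ea, eb, Rb, pb.S);
    pb.enuc = pair_core(ea, eb, R, pb.g[0][0]);
  }
};

struct SCF {
  const Molecule *mol;
  std::vector<PairBlock> blocks;   // upper-triangle pair blocks
  double enuc;                     // eV
  arma::mat H;                     // core hamiltonian, eV
  arma::mat P;                     // density
  bool have_P = false;
  double eelec = 0.0;              // eV
  bool converged = false;
  int iterations = 0;

  static int pair_id(int i, int j, int nat) {  // i < j
    return i * nat - i * (i + 1) / 2 + (j - i - 1);
  }

  void build(const arma::mat &xyz) {
    int nat = mol->nat, nb = mol->nbas;
    blocks.resize(nat * (nat - 1) / 2);
    enuc = 0.0;
    H.zeros(nb, nb);
    // one-center one-electron terms
    for (int i = 0; i < nat; ++i) {
      const Elem &e = ELEMS[mol->slot[i]];
      int f = mol->first[i];
      H(f, f) = e.uss;
      for (int k = 1; k < mol->nbas_at[i]; ++k) H(f + k, f + k) = e.upp;
    }
    // pair terms
    double xi[3], xj[3];
    for (int i = 0; i < nat; ++i)
      for (int j = i + 1; j < nat; ++j) {
        PairBlock &pb = blocks[pair_id(i, j, nat)];
        for (int k = 0; k < 3; ++k) { xi[k] = xyz(i, k); xj[k] = xyz(j, k); }
        mol->pair_block(i, j, xi, xj, pb);
        enuc += pb.enuc;
        const Elem &ea = ELEMS[mol->slot[i]], &eb = ELEMS[mol->slot[j]];
        int fa = mol->first[i], fb = mol->first[j];
        int na = mol->nbas_at[i], nbn = mol->nbas_at[j];
        // resonance
        for (int mu = 0; mu < na; ++mu) {
          double bmu = (mu == 0) ? ea.bs : ea.bp;
          for (int la = 0; la < nbn; ++la) {
            double bla = (la == 0) ? eb.bs : eb.bp;
            double h = 0.5 * (bmu + bla) * pb.S[mu][la];
            H(fa + mu, fb + la) += h;
            H(fb + la, fa + mu) += h;
          }
        }
        // core attraction:  V_mu nu (A) from core B = -ZB (mu nu | sB sB)
        for (int mu = 0; mu < na; ++mu)
          for (int nu = mu; nu < na; ++nu) {
            double v = -eb.zval * pb.g[pidx(mu, nu)][0];
            H(fa + mu, fa + nu) += v;
            if (nu != mu) H(fa + nu, fa + mu) += v;
          }
        for (int la = 0; la < nbn; ++la)
          for (int si = la; si < nbn; ++si) {
            double v = -ea.zval * pb.g[0][pidx(la, si)];
            H(fb + la, fb + si) += v;
            if (si != la) H(fb + si, fb + la) += v;
          }
      }
  }

  // one-center two-electron integral (mu nu | la si), orbitals 0..3 local
  static double g1c(const Elem &e, int m, int n, int l, int s) {
    if (m > n) std::swap(m, n);
    if (l > s) std::swap(l, s);
    if (m == n && l == s) {
      if (m == 0 && l == 0) return e.gss;
      if (m == 0 || l == 0) return e.gsp;
      return (m == l) ? e.gpp : e.gp2;
    }
    if (m == n || l == s) return 0.0;
    if (m == l && n == s) {
      if (m == 0) return e.hsp;
      return 0.5 * (e.gpp - e.gp2);
    }
    return 0.0;
  }

  void fock(const arma::mat &Pm, arma::mat &F) const {
    int nat = mol->nat;
    F = H;
    // one-center two-electron part (generic RHF contraction over <=4 orbitals)
    for (int a = 0; a < nat; ++a) {
      const Elem &e = ELEMS[mol->slot[a]];
      int f = mol->first[a], nb = mol->nbas_at[a];
      for (int m = 0; m < nb; ++m)
        for (int n = 0; n < nb; ++n)
          for (int l = 0; l < nb; ++l)
            for (int s = 0; s < nb; ++s) {
              double gmnls = g1c(e, m, n, l, s);
              double gmlns = g1c(e, m, l, n, s);
              if (gmnls == 0.0 && gmlns == 0.0) continue;
              F(f + m, f + n) += Pm(f + l, f + s) * (gmnls - 0.5 * gmlns);
            }
    }
    // two-center two-electron part
    for (int i = 0; i < nat; ++i)
      for (int j = i + 1; j < nat; ++j) {
        const PairBlock &pb = blocks[pair_id(i, j, nat)];
        int fa = mol->first[i], fb = mol->first[j];
        int na = mol->nbas_at[i], nbn = mol->nbas_at[j];
        // coulomb
        for (int mu = 0; mu < na; ++mu)
          for (int nu = mu; nu < na; ++nu) {
            double sum = 0.0;
            for (int la = 0; la < nbn; ++la) {
              sum += Pm(fb + la, fb + la) * pb.g[pidx(mu, nu)][pidx(la, la)];
              for (int si = la + 1; si < nbn; ++si)
                sum += 2.0 * Pm(fb + la, fb + si) * pb.g[pidx(mu, nu)][pidx(la, si)];
            }
            F(fa + mu, fa + nu) += sum;
            if (nu != mu) F(fa + nu, fa + mu) += sum;
          }
        for (int la = 0; la < nbn; ++la)
          for (int si = la; si < nbn; ++si) {
            double sum = 0.0;
            for (int mu = 0; mu < na; ++mu) {
              sum += Pm(fa + mu, fa + mu) * pb.g[pidx(mu, mu)][pidx(la, si)];
              for (int nu = mu + 1; nu < na; ++nu)
                sum += 2.0 * Pm(fa + mu, fa + nu) * pb.g[pidx(mu, nu)][pidx(la, si)];
            }
            F(fb + la, fb + si) += sum;
            if (si != la) F(fb + si, fb + la) += sum;
          }
        // exchange
        for (int mu = 0; mu < na; ++mu)
          for (int la = 0; la < nbn; ++la) {
            double sum = 0.0;
            for (int nu = 0; nu < na; ++nu)
              for (int si = 0; si < nbn; ++si)
                sum += Pm(fa + nu, fb + si) * pb.g[pidx(std::min(mu, nu), std::max(mu, nu))]
                                                  [pidx(std::min(la, si), std::max(la, si))];
            F(fa + mu, fb + la) -= 0.5 * sum;
            F(fb + la, fa + mu) = F(fa + mu, fb + la);
          }
      }
  }

  bool run(int maxit = 400, double ptol = 1e-8) {
    int nb = mol->nbas, nocc = mol->nelec / 2;
    if (!have_P) {
      P.zeros(nb, nb);
      double scalefac = (double)mol->nelec;
      double ztot = 0.0;
      for (int a = 0; a < mol->nat; ++a) ztot += ELEMS[mol->slot[a]].zval;
      scalefac /= ztot;
      for (int a = 0; a < mol->nat; ++a) {
        int f = mol->first[a], nba = mol->nbas_at[a];
        double occ = ELEMS[mol->slot[a]].zval * scalefac / nba;
        for (int k = 0; k < nba; ++k) P(f + k, f + k) = occ;
      }
      have_P = true;
    }
    arma::mat F, C, Pold;
    arma::vec eps;
    std::deque<arma::mat> diis_F, diis_E;
    double elast = 0.0;
    converged = false;
    for (int it = 0; it < maxit; ++it) {
      iterations = it + 1;
      fock(P, F);
      eelec = 0.5 * arma::accu(P % (H + F));
      // DIIS extrapolation on the commutator [F, P]
      arma::mat err = F * P - P * F;
      double emax = arma::abs(err).max();
      double dE = eelec - elast; elast = eelec;
      if (it > 0 && emax < 1e-6 && std::fabs(dE) < ptol * 100) { converged = true; }
      diis_F.push_back(F); diis_E.push_back(err);
      if ((int)diis_F.size() > 8) { diis_F.pop_front(); diis_E.pop_front(); }
      arma::mat Fuse = F;
      int nd = (int)diis_F.size();
      if (nd >= 2 && !converged) {
        arma::mat Bm(nd + 1, nd + 1, arma::fill::ones);
        Bm(nd, nd) = 0.0;
        for (int a = 0; a < nd; ++a)
          for (int b = 0; b < nd; ++b)
            Bm(a, b) = arma::accu(diis_E[a] % diis_E[b]);
        arma::vec rhs(nd + 1, arma::fill::zeros); rhs(nd) = 1.0;
        arma::vec coef;
        bool ok = arma::solve(coef, Bm, rhs, arma::solve_opts::no_approx);
        if (ok && coef.is_finite()) {
          Fuse.zeros();
          for (int a = 0; a < nd; ++a) Fuse += coef(a) * diis_F[a];
        }
      }
      if (converged) break;
      arma::eig_sym(eps, C, Fuse);
      Pold = P;
      arma::mat Cocc = C.cols(0, nocc - 1);
      P = 2.0 * Cocc * Cocc.t();
      if (it < 3 || emax > 0.5) P = 0.5 * P + 0.5 * Pold;  // damp early iterations
    }
    return converged;
  }

  double heat_of_formation() const {
    double e = eelec + enuc;  // eV
    double iso = 0.0, heat = 0.0;
    for (int a = 0; a < mol->nat; ++a) {
      iso += ELEMS[mol->slot[a]].eisol;
      heat += ELEMS[mol->slot[a]].eheat;
    }
    return (e - iso) * EV2KCAL + heat;
  }

  // pairwise interaction energy terms for the frozen-density gradient, eV
  double pair_energy(int i, int j, const double *xi, const double *xj) const {
    PairBlock pb;
    mol->pair_block(i, j, xi, xj, pb);
    const Elem &ea = ELEMS[mol->slot[i]], &eb = ELEMS[mol->slot[j]];
    int fa = mol->first[i], fb = mol->first[j];
    int na = mol->nbas_at[i], nbn = mol->nbas_at[j];
    double e = pb.enuc;
    for (int mu = 0; mu < na; ++mu) {
      double bmu = (mu == 0) ? ea.bs : ea.bp;
      for (int la = 0; la < nbn; ++la) {
        double bla = (la == 0) ? eb.bs : eb.bp;
        e += 2.0 * P(fa + mu, fb + la) * 0.5 * (bmu + bla) * pb.S[mu][la];
      }
    }
    for (int mu = 0; mu < na; ++mu)
      for (int nu = 0; nu < na; ++nu)
        e += -eb.zval * P(fa + mu, fa + nu) *
             pb.g[pidx(std::min(mu, nu), std::max(mu, nu))][0];
    for (int la = 0; la < nbn; ++la)
      for (int si = 0; si < nbn; ++si)
        e += -ea.zval * P(fb + la, fb + si) *
             pb.g[0][pidx(std::min(la, si), std::max(la, si))];
    for (int mu = 0; mu < na; ++mu)
      for (int nu = 0; nu < na; ++nu)
        for (int la = 0; la < nbn; ++la)
          for (int si = 0; si < nbn; ++si) {
            double gint = pb.g[pidx(std::min(mu, nu), std::max(mu, nu))]
                              [pidx(std::min(la, si), std::max(la, si))];
            e += gint * (P(fa + mu, fa + nu) * P(fb + la, fb + si)
                         - 0.5 * P(fa + mu, fb + la) * P(fa + nu, fb + si));
          }
    return e;
  }

  // gradient in kcal/mol/angstrom at frozen density
  void gradient(const arma::mat &xyz, arma::mat &grad) const {
    int nat = mol->nat;
    grad.zeros(nat, 3);
    const double del = 5e-4;
    double xi[3], xj[3];
    for (int i = 0; i < nat; ++i)
      for (int j = i + 1; j < nat; ++j) {
        for (int k = 0; k < 3; ++k) { xi[k] = xyz(i, k); xj[k] = xyz(j, k); }
        for (int k = 0; k < 3; ++k) {
          double save = xj[k];
          xj[k] = save + del;
          double ep = pair_energy(i, j, xi, xj);
          xj[k] = save - del;
          double em = pair_energy(i, j, xi, xj);
          xj[k] = save;
          double d = (ep - em) / (2.0 * del) * EV2KCAL;
          grad(j, k) += d;
          grad(i, k) -= d;
        }
      }
  }
};

// ---------------------------------------------------------------------------
// exported interface
// ---------------------------------------------------------------------------

static void check_geom(const IntegerVector &z, const NumericMatrix &xyz) {
  if (xyz.nrow() != z.size() || xyz.ncol() != 3)
    stop("xyz must be a length(z) x 3 matrix");
}

// [[Rcpp::export(name = ".am1_energy")]]
List am1_energy_cpp(IntegerVector z, NumericMatrix xyz, int charge = 0) {
  check_geom(z, xyz);
  Molecule mol;
  mol.setup(std::vector<int>(z.begin(), z.end()), charge);
  mol.xyz = as<arma::mat>(xyz);
  SCF scf; scf.mol = &mol;
  scf.build(mol.xyz);
  bool ok = scf.run();
  double hf = ok ? scf.heat_of_formation() : NA_REAL;
  arma::mat F; scf.fock(scf.P, F);
  arma::vec eps; arma::mat C;
  arma::eig_sym(eps, C, F);
  return List::create(_["hf"] = hf, _["converged"] = ok,
                      _["scf_iterations"] = scf.iterations,
                      _["eelec_ev"] = scf.eelec, _["enuc_ev"] = scf.enuc,
                      _["orbital_ev"] = wrap(eps),
                      _["pop"] = wrap(arma::vec(scf.P.diag())));
}

// [[Rcpp::export(name = ".am1_gradient")]]
NumericMatrix am1_gradient_cpp(IntegerVector z, NumericMatrix xyz, int charge = 0) {
  check_geom(z, xyz);
  Molecule mol;
  mol.setup(std::vector<int>(z.begin(), z.end()), charge);
  mol.xyz = as<arma::mat>(xyz);
  SCF scf; scf.mol = &mol;
  scf.build(mol.xyz);
  if (!scf.run()) stop("SCF failed to converge");
  arma::mat g;
  scf.gradient(mol.xyz, g);
  return wrap(g);
}

// [[Rcpp::export(name = ".am1_optimize")]]
List am1_optimize_cpp(IntegerVector z, NumericMatrix xyz, int charge = 0,
                      double gtol = 0.5, int maxiter = 600) {
  check_geom(z, xyz);
  int nat = z.size();
  Molecule mol;
  mol.setup(std::vector<int>(z.begin(), z.end()), charge);
  arma::mat x = as<arma::mat>(xyz);
  SCF scf; scf.mol = &mol;

  auto energy = [&](const arma::mat &xx, bool &ok) -> double {
    scf.build(xx);
    ok = scf.run();
    return ok ? (scf.eelec + scf.enuc) * EV2KCAL : NA_REAL;
  };

  int n = 3 * nat;
  arma::vec xv(n), gv(n), gv_old(n);
  for (int i = 0; i < nat; ++i)
    for (int k = 0; k < 3; ++k) xv(3 * i + k) = x(i, k);
  arma::mat Hinv = arma::eye(n, n) * (1.0 / 300.0);

  bool scf_ok = false;
  double e = energy(x, scf_ok);
  if (!scf_ok)
    return List::create(_["hf"] = NA_REAL, _["converged"] = false,
                        _["scf_failed"] = true, _["xyz"] = xyz,
                        _["gnorm"] = NA_REAL, _["iterations"] = 0);
  arma::mat gm;
  scf.gradient(x, gm);
  for (int i = 0; i < nat; ++i)
    for (int k = 0; k < 3; ++k) gv(3 * i + k) = gm(i, k);

  bool geom_ok = false;
  bool fresh_H = true;
  int it = 0;
  double gnorm = arma::norm(gv);
  for (it = 0; it < maxiter; ++it) {
    gnorm = arma::norm(gv);
    if (gnorm < gtol) { geom_ok = true; break; }
    arma::vec p = -(Hinv * gv);
    double pg = arma::dot(p, gv);
    if (pg > 0) { Hinv = arma::eye(n, n) * (1.0 / 300.0); p = -gv / 300.0; pg = arma::dot(p, gv); }
    // cap the step length
    double pmax = arma::abs(p).max();
    if (pmax > 0.3) p *= 0.3 / pmax;
    pg = arma::dot(p, gv);
    double alpha = 1.0, enew = 0.0;
    arma::vec xnew;
    bool accepted = false;
    for (int ls = 0; ls < 14; ++ls) {
      xnew = xv + alpha * p;
      arma::mat xm(nat, 3);
      for (int i = 0; i < nat; ++i)
        for (int k = 0; k < 3; ++k) xm(i, k) = xnew(3 * i + k);
      bool ok2 = false;
      enew = energy(xm, ok2);
      if (ok2 && enew <= e + 1e-4 * alpha * pg) { accepted = true; x = xm; break; }
      alpha *= 0.5;
    }
    if (!accepted) {
      // stale curvature information can produce bad directions; retry once
      // from a fresh steepest-descent Hessian before giving up
      if (!fresh_H) { Hinv = arma::eye(n, n) * (1.0 / 300.0); fresh_H = true; continue; }
      break;
    }
    fresh_H = false;
    arma::vec s = xnew - xv;
    xv = xnew;
    gv_old = gv;
    scf.gradient(x, gm);
    for (int i = 0; i < nat; ++i)
      for (int k = 0; k < 3; ++k) gv(3 * i + k) = gm(i, k);
    arma::vec y = gv - gv_old;
    double sy = arma::dot(s, y);
    if (sy > 1e-10) {
      arma::vec Hy = Hinv * y;
      double yHy = arma::dot(y, Hy);
      Hinv += ((sy + yHy) / (sy * sy)) * (s * s.t())
            - (Hy * s.t() + s * Hy.t()) / sy;
    }
    e = enew;
    if ((it & 7) == 0) Rcpp::checkUserInterrupt();
  }
  gnorm = arma::norm(gv);

  // final tight single point
  scf.build(x);
  bool okf = scf.run();
  double hf = okf ? scf.heat_of_formation() : NA_REAL;
  return List::create(_["hf"] = hf, _["converged"] = okf && geom_ok,
                      _["scf_failed"] = !okf, _["xyz"] = wrap(x),
                      _["gnorm"] = gnorm, _["iterations"] = it);
}

// [[Rcpp::export(name = ".am1_param_checksum")]]
double am1_param_checksum() {
  init_elems();
  double s = 0.0;
  for (int i = 0; i < 8; ++i) {
    const Elem &e = ELEMS[i];
    s += e.uss + e.upp + e.bs + e.bp + e.zs + e.zp + e.alpha
       + e.gss + e.gsp + e.gpp + e.gp2 + e.hsp + e.eheat + e.eisol;
    for (int k = 0; k < e.ng; ++k) s += e.gk[k] + e.gl[k] + e.gm[k];
  }
  return s;
}

// [[Rcpp::export(name = ".am1_eisol")]]
NumericVector am1_eisol() {
  init_elems();
  NumericVector out(8);
  CharacterVector nm(8);
  const char *names[8] = {"H", "C", "N", "O", "F", "S", "Cl", "Br"};
  for (int i = 0; i < 8; ++i) { out[i] = ELEMS[i].eisol; nm[i] = names[i]; }
  out.names() = nm;
  return out;
}

// [[Rcpp::export(name = ".slater_overlap")]]
double slater_overlap_r(int na, int la, double za, int nb, int lb, double zb,
                        double R_bohr, int m) {
  return slater_overlap(na, la, za, nb, lb, zb, R_bohr, m);
}
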