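// Compiled core: ideal-geometry coordinate construction (NeRF), fused
// energy + analytic torsion-gradient evaluation, and vectorized spline
// evaluation.  The R layer owns all bookkeeping (bin schemas, spline
// fitting, selection, optimization loop); this file only evaluates.
//
// Atom layout: 7 pseudo-atom slots per residue, in chain order
//   0 N, 1 H, 2 CA, 3 CB, 4 SC, 5 C, 6 O
// This ordering makes the set of atoms moved by each torsion a suffix of
// the atom list: phi(i) moves everything from CB(i) on, psi(i) moves
// everything from O(i) on.  Torsion gradients are then obtained from
// per-atom Cartesian forces by a single suffix-sum (torque) pass.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double D2R = M_PI / 180.0;

// Engh-Huber style ideal covalent geometry
static const double BL_N_CA  = 1.458;
static const double BL_CA_C  = 1.525;
static const double BL_C_N   = 1.329;
static const double BL_C_O   = 1.231;
static const double BL_N_H   = 1.010;
static const double BL_CA_CB = 1.521;
static const double AN_N_CA_C  = 111.2;
static const double AN_CA_C_N  = 116.2;
static const double AN_C_N_CA  = 121.7;
static const double AN_CA_C_O  = 120.5;
static const double AN_C_N_H   = 119.15;
static const double AN_N_CA_CB = 110.5;
// improper dihedral C-N-CA-CB fixing the L-configuration at CA
static const double DH_C_N_CA_CB = -122.55;

static inline void vsub(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline void vcross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double vnorm(const double* a) { return std::sqrt(vdot(a, a)); }
// positive remainder of u modulo n without libm fmod
static inline double wrap_pos(double u, double n) {
  double w = u - n * std::floor(u / n);
  if (w >= n) w -= n;
  if (w < 0) w += n;
  return w;
}
static inline void vunit(double* a) {
  double n = vnorm(a);
  if (n > 0) { a[0] /= n; a[1] /= n; a[2] /= n; }
}

// Place atom D given reference atoms A-B-C, bond length r = |C-D|, bond
// angle theta = angle(B,C,D) and dihedral chi = dihedral(A,B,C,D), both in
// radians.  Sign convention matches the IUPAC atan2 dihedral below.
static void nerf(const double* A, const double* B, const double* C,
                 double r, double theta, double chi, double* D) {
  double bc[3], ab[3], n[3], m[3];
  vsub(C, B, bc); vunit(bc);
  vsub(B, A, ab);
  vcross(ab, bc, n); vunit(n);
  vcross(n, bc, m);
  double d0 = -r * std::cos(theta);
  double d1 = r * std::sin(theta) * std::cos(chi);
  double d2 = r * std::sin(theta) * std::sin(chi);
  for (int k = 0; k < 3; k++)
    D[k] = C[k] + bc[k] * d0 + m[k] * d1 + n[k] * d2;
}

// IUPAC dihedral (cis = 0), radians in (-pi, pi]
static double dihedral4(const double* A, const double* B, const double* C,
                        const double* D) {
  double b1[3], b2[3], b3[3], n1[3], n2[3], m1[3];
  vsub(B, A, b1); vsub(C, B, b2); vsub(D, C, b3);
  vcross(b1, b2, n1);
  vcross(b2, b3, n2);
  double b2n[3] = { b2[0], b2[1], b2[2] };
  vunit(b2n);
  vcross(b2n, n1, m1);
  double x = vdot(n1, n2);
  double y = vdot(m1, n2);
  return std::atan2(y, x);
}

// [[Rcpp::export]]
NumericVector cpp_ideal_geometry() {
  NumericVector v = NumericVector::create(
    _["b_n_ca"] = BL_N_CA, _["b_ca_c"] = BL_CA_C, _["b_c_n"] = BL_C_N,
    _["b_c_o"] = BL_C_O, _["b_n_h"] = BL_N_H, _["b_ca_cb"] = BL_CA_CB,
    _["a_n_ca_c"] = AN_N_CA_C, _["a_ca_c_n"] = AN_CA_C_N,
    _["a_c_n_ca"] = AN_C_N_CA, _["a_ca_c_o"] = AN_CA_C_O,
    _["a_c_n_h"] = AN_C_N_H, _["a_n_ca_cb"] = AN_N_CA_CB,
    _["d_c_n_ca_cb"] = DH_C_N_CA_CB, _["omega"] = 180.0);
  return v;
}

// Build all coordinates from torsions (radians).  phi[0] and psi[L-1] are
// ignored.  is_gly residues get CB = SC = CA.  sc_dist gives the CA->SC
// distance per residue (0 for glycine).  Residue 1 has no amide H; its H
// slot is filled with the N coordinates (callers mask it out).
static void build_coords_impl(int L, const int* is_gly,
                              const double* sc_dist, const double* phi,
                              const double* psi, double* X /* 7L x 3 */) {
  // X stored row-major conceptually via helper
  #define AT(i, s, k) X[3 * (7 * (i) + (s)) + (k)]
  double th_ncac = AN_N_CA_C * D2R, th_cacn = AN_CA_C_N * D2R,
         th_cnca = AN_C_N_CA * D2R, th_caco = AN_CA_C_O * D2R,
         th_cnh = AN_C_N_H * D2R, th_ncacb = AN_N_CA_CB * D2R,
         dh_cb = DH_C_N_CA_CB * D2R;
  // first residue canonical frame
  AT(0, 0, 0) = 0; AT(0, 0, 1) = 0; AT(0, 0, 2) = 0;
  AT(0, 2, 0) = BL_N_CA; AT(0, 2, 1) = 0; AT(0, 2, 2) = 0;
  AT(0, 5, 0) = BL_N_CA - BL_CA_C * std::cos(th_ncac);
  AT(0, 5, 1) = BL_CA_C * std::sin(th_ncac);
  AT(0, 5, 2) = 0;
  for (int i = 1; i < L; i++) {
    const double *Np = &AT(i - 1, 0, 0), *CAp = &AT(i - 1, 2, 0),
                 *Cp = &AT(i - 1, 5, 0);
    nerf(Np, CAp, Cp, BL_C_N, th_cacn, psi[i - 1], &AT(i, 0, 0));
    nerf(CAp, Cp, &AT(i, 0, 0), BL_N_CA, th_cnca, M_PI, &AT(i, 2, 0));
    nerf(Cp, &AT(i, 0, 0), &AT(i, 2, 0), BL_CA_C, th_ncac, phi[i],
         &AT(i, 5, 0));
  }
  for (int i = 0; i < L; i++) {
    const double *N = &AT(i, 0, 0), *CA = &AT(i, 2, 0), *C = &AT(i, 5, 0);
    // carbonyl O: dihedral N-CA-C-O = psi + pi (anti to the next N)
    double psi_eff = (i < L - 1) ? psi[i] : M_PI;
    nerf(N, CA, C, BL_C_O, th_caco, psi_eff + M_PI, &AT(i, 6, 0));
    // amide H (i >= 1): in the peptide plane, anti to CA(i) across N
    if (i >= 1) {
      nerf(&AT(i - 1, 2, 0), &AT(i - 1, 5, 0), N, BL_N_H, th_cnh, 0.0,
           &AT(i, 1, 0));
    } else {
      AT(i, 1, 0) = N[0]; AT(i, 1, 1) = N[1]; AT(i, 1, 2) = N[2];
    }
    if (is_gly[i]) {
      for (int k = 0; k < 3; k++) {
        AT(i, 3, k) = CA[k];
        AT(i, 4, k) = CA[k];
      }
    } else {
      nerf(C, N, CA, BL_CA_CB, th_ncacb, dh_cb, &AT(i, 3, 0));
      double u[3];
      vsub(&AT(i, 3, 0), CA, u); vunit(u);
      for (int k = 0; k < 3; k++) AT(i, 4, k) = CA[k] + sc_dist[i] * u[k];
    }
  }
  #undef AT
}

// [[Rcpp::export]]
NumericMatrix cpp_build_coords(IntegerVector is_gly, NumericVector sc_dist,
                               NumericVector phi, NumericVector psi) {
  int L = phi.size();
  std::vector<double> X(3 * 7 * L);
  build_coords_impl(L, &is_gly[0], &sc_dist[0], &phi[0], &psi[0], &X[0]);
  NumericMatrix out(7 * L, 3);
  for (int a = 0; a < 7 * L; a++)
    for (int k = 0; k < 3; k++) out(a, k) = X[3 * a + k];
  return out;
}

// ---------------------------------------------------------------------------
// spline evaluation
// ---------------------------------------------------------------------------

// Natural cubic spline with uniform knots t0 + h * (0..K-1), values y and
// second derivatives M (M[0] = M[K-1] = 0).  kind_dist controls the
// out-of-range behaviour: repulsive linear wall below the first knot
// (slope at least rep_slope) and a C1 ease-out to slope zero within
// cap_width above the last knot; otherwise plain linear extrapolation.
static void nat_spline_eval(const double* y, const double* M, int K,
                            double t0, double h, double x, bool kind_dist,
                            double rep_slope, double cap_width, double* E,
                            double* dE) {
  double tK = t0 + h * (K - 1);
  if (x < t0) {
    double s0 = (y[1] - y[0]) / h - h * M[1] / 6.0;
    if (kind_dist && s0 > -rep_slope) s0 = -rep_slope;
    *E = y[0] + s0 * (x - t0);
    *dE = s0;
    return;
  }
  if (x > tK) {
    double sK = (y[K - 1] - y[K - 2]) / h + h * M[K - 2] / 6.0;
    double t = x - tK;
    if (kind_dist) {
      if (t < cap_width) {
        *E = y[K - 1] + sK * (t - t * t / (2.0 * cap_width));
        *dE = sK * (1.0 - t / cap_width);
      } else {
        *E = y[K - 1] + sK * cap_width / 2.0;
        *dE = 0.0;
      }
    } else {
      *E = y[K - 1] + sK * t;
      *dE = sK;
    }
    return;
  }
  int i = (int)std::floor((x - t0) / h);
  if (i > K - 2) i = K - 2;
  if (i < 0) i = 0;
  double a = t0 + i * h;
  double u1 = a + h - x, u2 = x - a;
  *E = M[i] * u1 * u1 * u1 / (6 * h) + M[i + 1] * u2 * u2 * u2 / (6 * h) +
       (y[i] / h - M[i] * h / 6) * u1 + (y[i + 1] / h - M[i + 1] * h / 6) * u2;
  *dE = -M[i] * u1 * u1 / (2 * h) + M[i + 1] * u2 * u2 / (2 * h) -
        (y[i] / h - M[i] * h / 6) + (y[i + 1] / h - M[i + 1] * h / 6);
}

// Periodic uniform cubic B-spline with n coefficients c covering one full
// period n*h starting at knot t0.  Interpolates S(t0 + k h) =
// (c[k-1] + 4 c[k] + c[k+1]) / 6 (cyclic).
static void per_spline_eval(const double* c, int n, double t0, double h,
                            double x, double* E, double* dE) {
  double u = wrap_pos((x - t0) / h, (double)n);
  int k = (int)std::floor(u);
  if (k >= n) k = n - 1;
  double t = u - k;
  int km1 = (k - 1 + n) % n, kp1 = (k + 1) % n, kp2 = (k + 2) % n;
  double omt = 1.0 - t;
  double b0 = omt * omt * omt / 6.0;
  double b1 = (3 * t * t * t - 6 * t * t + 4) / 6.0;
  double b2 = (-3 * t * t * t + 3 * t * t + 3 * t + 1) / 6.0;
  double b3 = t * t * t / 6.0;
  *E = c[km1] * b0 + c[k] * b1 + c[kp1] * b2 + c[kp2] * b3;
  double d0 = -3 * omt * omt / 6.0;
  double d1 = (9 * t * t - 12 * t) / 6.0;
  double d2 = (-9 * t * t + 6 * t + 3) / 6.0;
  double d3 = 3 * t * t / 6.0;
  *dE = (c[km1] * d0 + c[k] * d1 + c[kp1] * d2 + c[kp2] * d3) / h;
}

// [[Rcpp::export]]
NumericMatrix cpp_eval_nat_spline(NumericMatrix Y, NumericMatrix M,
                                  double t0, double h, NumericVector x,
                                  bool kind_dist, double rep_slope,
                                  double cap_width) {
  int n = Y.nrow(), K = Y.ncol();
  if ((int)x.size() != n) stop("x length must match spline rows");
  NumericMatrix out(n, 2);
  std::vector<double> yr(K), mr(K);
  for (int p = 0; p < n; p++) {
    for (int k = 0; k < K; k++) { yr[k] = Y(p, k); mr[k] = M(p, k); }
    double E, dE;
    nat_spline_eval(&yr[0], &mr[0], K, t0, h, x[p], kind_dist, rep_slope,
                    cap_width, &E, &dE);
    out(p, 0) = E; out(p, 1) = dE;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_eval_per_spline(NumericMatrix C, double t0, double h,
                                  NumericVector x) {
  int n = C.nrow(), K = C.ncol();
  if ((int)x.size() != n) stop("x length must match spline rows");
  NumericMatrix out(n, 2);
  std::vector<double> cr(K);
  for (int p = 0; p < n; p++) {
    for (int k = 0; k < K; k++) cr[k] = C(p, k);
    double E, dE;
    per_spline_eval(&cr[0], K, t0, h, x[p], &E, &dE);
    out(p, 0) = E; out(p, 1) = dE;
  }
  return out;
}

// ---------------------------------------------------------------------------
// energy terms
// ---------------------------------------------------------------------------

// cubic smoothstep on [0, 1]
static inline double sstep(double t, double* ds) {
  if (t <= 0) { *ds = 0; return 0; }
  if (t >= 1) { *ds = 0; return 1; }
  *ds = 6 * t * (1 - t);
  return t * t * (3 - 2 * t);
}

// gradient of dihedral(A,B,C,D) wrt the four atoms
static void dihedral_grad(const double* A, const double* B, const double* C,
                          const double* D, double* gA, double* gB,
                          double* gC, double* gD) {
  double b1[3], b2[3], b3[3], n1[3], n2[3];
  vsub(B, A, b1); vsub(C, B, b2); vsub(D, C, b3);
  vcross(b1, b2, n1); vcross(b2, b3, n2);
  double nb2 = vnorm(b2);
  double n1sq = vdot(n1, n1), n2sq = vdot(n2, n2);
  if (n1sq < 1e-18 || n2sq < 1e-18 || nb2 < 1e-12) {
    for (int k = 0; k < 3; k++) { gA[k] = gB[k] = gC[k] = gD[k] = 0; }
    return;
  }
  double F[3], G[3];
  for (int k = 0; k < 3; k++) {
    F[k] = -nb2 / n1sq * n1[k];
    G[k] = nb2 / n2sq * n2[k];
  }
  double c1 = vdot(b1, b2) / (nb2 * nb2);
  double c3 = vdot(b3, b2) / (nb2 * nb2);
  for (int k = 0; k < 3; k++) {
    gA[k] = F[k];
    gB[k] = -(1.0 + c1) * F[k] + c3 * G[k];
    gC[k] = c1 * F[k] - (1.0 + c3) * G[k];
    gD[k] = G[k];
  }
}

// planar angle at vertex B for atoms A-B-C, radians, plus gradients
static double angle_grad(const double* A, const double* B, const double* C,
                         double* gA, double* gB, double* gC) {
  double u[3], v[3];
  vsub(A, B, u); vsub(C, B, v);
  double nu = vnorm(u), nv = vnorm(v);
  double c = vdot(u, v) / (nu * nv);
  if (c > 1) c = 1; if (c < -1) c = -1;
  double th = std::acos(c);
  double s = std::sqrt(1 - c * c);
  if (s < 1e-8) s = 1e-8;
  for (int k = 0; k < 3; k++) {
    gA[k] = -(v[k] / (nu * nv) - c * u[k] / (nu * nu)) / s;
    gC[k] = -(u[k] / (nu * nv) - c * v[k] / (nv * nv)) / s;
    gB[k] = -gA[k] - gC[k];
  }
  return th;
}

// vdW exclusion: bonded path of length <= 2.  Slots as in the header.
static bool vdw_excluded(int ri, int si, int rj, int sj) {
  if (ri > rj) { int t = ri; ri = rj; rj = t; t = si; si = sj; sj = t; }
  if (ri == rj) {
    int a = si < sj ? si : sj, b = si < sj ? sj : si;
    // 1-2: N-H, N-CA, CA-CB, CA-C, CB-SC, C-O
    if ((a == 0 && b == 1) || (a == 0 && b == 2) || (a == 2 && b == 3) ||
        (a == 2 && b == 5) || (a == 3 && b == 4) || (a == 5 && b == 6))
      return true;
    // 1-3: H-CA, N-CB, N-C, CB-C, CA-SC, CA-O
    if ((a == 1 && b == 2) || (a == 0 && b == 3) || (a == 0 && b == 5) ||
        (a == 3 && b == 5) || (a == 2 && b == 4) || (a == 2 && b == 6))
      return true;
    return false;
  }
  if (rj == ri + 1) {
    // (slot in ri, slot in rj): C-N (1-2 bonds), CA-N, O-N, C-H, C-CA
    if (si == 5 && (sj == 0 || sj == 1 || sj == 2)) return true;
    if ((si == 2 || si == 6) && sj == 0) return true;
    return false;
  }
  return false;
}


// ---------------------------------------------------------------------------
// evaluation context
// ---------------------------------------------------------------------------
// All restraint payloads are flattened into plain C++ storage once per
// fold (cpp_make_context) so the per-step evaluator avoids R object
// traversal.

enum ChanType { CH_DIST_CB, CH_DIST_CA, CH_OMEGA, CH_THETA, CH_PHI_ANG,
                CH_CONT_CB, CH_CONT_CA };

struct Channel {
  int type;
  int n;
  std::vector<int> pi, pj, slot;
  std::vector<double> Y, M, C;   // row-major n x K
  int K;
  double t0, h, rep_slope, cap_width;
  std::vector<double> p;         // contact probabilities
  double d_b, w_sw;
};

struct Ctx {
  int L;
  std::vector<int> is_gly;
  std::vector<double> sc_dist;
  std::vector<Channel> chans;
  std::vector<double> weights;   // 24
  // generic terms
  bool vdw_on, hb_on, tor_on;
  std::vector<double> radii;
  double vdw_sigma;
  std::vector<double> torC[3];   // 24 x 24 row-major coefficient grids
  std::vector<int> tor_table;
  double tor_t0, tor_h;
};

static int chan_type_code(const std::string& type) {
  if (type == "cb_distance") return CH_DIST_CB;
  if (type == "ca_distance") return CH_DIST_CA;
  if (type == "omega") return CH_OMEGA;
  if (type == "theta") return CH_THETA;
  if (type == "phi_angle") return CH_PHI_ANG;
  if (type == "cb_contact") return CH_CONT_CB;
  if (type == "ca_contact") return CH_CONT_CA;
  stop("unknown channel type: " + type);
  return -1;
}

static void flatten_mat(const NumericMatrix& A, std::vector<double>& out) {
  int n = A.nrow(), K = A.ncol();
  out.resize((size_t)n * K);
  for (int i = 0; i < n; i++)
    for (int k = 0; k < K; k++) out[(size_t)i * K + k] = A(i, k);
}

static Ctx* build_ctx(IntegerVector is_gly,
                      NumericVector sc_dist, List channels,
                      NumericVector weights, List generic) {
  Ctx* ctx = new Ctx();
  int L = is_gly.size();
  ctx->L = L;
  ctx->is_gly.assign(is_gly.begin(), is_gly.end());
  ctx->sc_dist.assign(sc_dist.begin(), sc_dist.end());
  ctx->weights.assign(weights.begin(), weights.end());
  if ((int)ctx->weights.size() != 24) stop("expected 24 weights");
  for (int ci = 0; ci < channels.size(); ci++) {
    if (Rf_isNull(channels[ci])) continue;
    List ch(channels[ci]);
    Channel c;
    c.type = chan_type_code(as<std::string>(ch["type"]));
    IntegerMatrix pairs = ch["pairs"];
    IntegerVector slot = ch["slot"];
    c.n = pairs.nrow();
    if (c.n == 0) continue;
    c.pi.resize(c.n); c.pj.resize(c.n); c.slot.resize(c.n);
    for (int p = 0; p < c.n; p++) {
      c.pi[p] = pairs(p, 0); c.pj[p] = pairs(p, 1); c.slot[p] = slot[p];
      if (c.pi[p] < 0 || c.pi[p] >= L || c.pj[p] < 0 || c.pj[p] >= L)
        { delete ctx; stop("pair index out of range"); }
    }
    if (c.type == CH_DIST_CB || c.type == CH_DIST_CA ||
        c.type == CH_PHI_ANG) {
      NumericMatrix Y = ch["Y"], M = ch["M"];
      flatten_mat(Y, c.Y); flatten_mat(M, c.M);
      c.K = Y.ncol();
      c.t0 = ch["t0"]; c.h = ch["h"];
      c.rep_slope = as<double>(ch["rep_slope"]);
      c.cap_width = as<double>(ch["cap_width"]);
    } else if (c.type == CH_OMEGA || c.type == CH_THETA) {
      NumericMatrix C = ch["C"];
      flatten_mat(C, c.C);
      c.K = C.ncol();
      c.t0 = ch["t0"]; c.h = ch["h"];
    } else {
      NumericVector pr = ch["p"];
      c.p.assign(pr.begin(), pr.end());
      c.d_b = ch["d_b"]; c.w_sw = ch["w_sw"];
    }
    ctx->chans.push_back(c);
  }
  ctx->vdw_on = as<bool>(generic["vdw_on"]);
  ctx->hb_on = as<bool>(generic["hb_on"]);
  ctx->tor_on = as<bool>(generic["tor_on"]);
  NumericVector radii = generic["radii"];
  ctx->radii.assign(radii.begin(), radii.end());
  ctx->vdw_sigma = as<double>(generic["vdw_sigma"]);
  List torC(generic["tor_coef"]);
  for (int t = 0; t < 3; t++) {
    NumericMatrix Cm = torC[t];
    flatten_mat(Cm, ctx->torC[t]);
  }
  IntegerVector tab = generic["tor_table"];
  ctx->tor_table.assign(tab.begin(), tab.end());
  ctx->tor_t0 = as<double>(generic["tor_t0"]);
  ctx->tor_h = as<double>(generic["tor_h"]);
  return ctx;
}

// uniform cubic B-spline basis and derivative at local parameter t
static inline void bspline_basis(double t, double* b, double* db) {
  double omt = 1 - t;
  b[0] = omt * omt * omt / 6;
  b[1] = (3 * t * t * t - 6 * t * t + 4) / 6;
  b[2] = (-3 * t * t * t + 3 * t * t + 3 * t + 1) / 6;
  b[3] = t * t * t / 6;
  db[0] = -3 * omt * omt / 6;
  db[1] = (9 * t * t - 12 * t) / 6;
  db[2] = (-9 * t * t + 6 * t + 3) / 6;
  db[3] = 3 * t * t / 6;
}

static List eval_core(const Ctx& ctx, const double* phi, const double* psi,
                      bool want_grad, const double* coords_in) {
  int L = ctx.L;
  int natoms = 7 * L;
  std::vector<double> X(3 * natoms);
  if (coords_in) {
    std::copy(coords_in, coords_in + 3 * natoms, X.begin());
  } else {
    build_coords_impl(L, &ctx.is_gly[0], &ctx.sc_dist[0], phi, psi, &X[0]);
  }
  #define POS(i, s) (&X[3 * (7 * (i) + (s))])

  NumericVector terms(24);
  std::vector<double> g;
  if (want_grad) g.assign(3 * natoms, 0.0);
  std::vector<double> dphi(L, 0.0), dpsi(L, 0.0);
  const std::vector<double>& W = ctx.weights;

  auto addf = [&](int res, int slot, const double* f, double w) {
    if (ctx.is_gly[res] && (slot == 3 || slot == 4)) slot = 2;
    double* gp = &g[3 * (7 * res + slot)];
    gp[0] += w * f[0]; gp[1] += w * f[1]; gp[2] += w * f[2];
  };

  for (size_t ci = 0; ci < ctx.chans.size(); ci++) {
    const Channel& c = ctx.chans[ci];
    bool is_cb = (c.type != CH_DIST_CA && c.type != CH_CONT_CA);
    if (c.type == CH_DIST_CB || c.type == CH_DIST_CA) {
      for (int p = 0; p < c.n; p++) {
        int i = c.pi[p], j = c.pj[p];
        int si = is_cb ? (ctx.is_gly[i] ? 2 : 3) : 2;
        int sj = is_cb ? (ctx.is_gly[j] ? 2 : 3) : 2;
        const double *xi = POS(i, si), *xj = POS(j, sj);
        double dv[3]; vsub(xi, xj, dv);
        double d = vnorm(dv);
        double E, dE;
        nat_spline_eval(&c.Y[(size_t)p * c.K], &c.M[(size_t)p * c.K], c.K,
                        c.t0, c.h, d, true, c.rep_slope, c.cap_width,
                        &E, &dE);
        int sl = c.slot[p];
        terms[sl] += E;
        if (want_grad && d > 1e-9) {
          double w = W[sl] * dE / d;
          double f[3] = { w * dv[0], w * dv[1], w * dv[2] };
          addf(i, si, f, 1.0);
          double fneg[3] = { -f[0], -f[1], -f[2] };
          addf(j, sj, fneg, 1.0);
        }
      }
    } else if (c.type == CH_OMEGA || c.type == CH_THETA) {
      for (int p = 0; p < c.n; p++) {
        int i = c.pi[p], j = c.pj[p];
        if (ctx.is_gly[i] || ctx.is_gly[j]) continue;
        int rA, sA, rB, sB, rC, sC, rD, sD;
        if (c.type == CH_OMEGA) {
          rA = i; sA = 2; rB = i; sB = 3; rC = j; sC = 3; rD = j; sD = 2;
        } else {
          rA = i; sA = 0; rB = i; sB = 2; rC = i; sC = 3; rD = j; sD = 3;
        }
        const double *A = POS(rA, sA), *B = POS(rB, sB),
                     *Cc = POS(rC, sC), *D = POS(rD, sD);
        double ang = dihedral4(A, B, Cc, D);
        double E, dE;
        per_spline_eval(&c.C[(size_t)p * c.K], c.K, c.t0, c.h, ang, &E, &dE);
        int sl = c.slot[p];
        terms[sl] += E;
        if (want_grad) {
          double gA[3], gB[3], gC[3], gD[3];
          dihedral_grad(A, B, Cc, D, gA, gB, gC, gD);
          double w = W[sl] * dE;
          addf(rA, sA, gA, w); addf(rB, sB, gB, w);
          addf(rC, sC, gC, w); addf(rD, sD, gD, w);
        }
      }
    } else if (c.type == CH_PHI_ANG) {
      for (int p = 0; p < c.n; p++) {
        int i = c.pi[p], j = c.pj[p];
        if (ctx.is_gly[i] || ctx.is_gly[j]) continue;
        const double *A = POS(i, 2), *B = POS(i, 3), *Cc = POS(j, 3);
        double gA[3], gB[3], gC[3];
        double ang = angle_grad(A, B, Cc, gA, gB, gC);
        double E, dE;
        nat_spline_eval(&c.Y[(size_t)p * c.K], &c.M[(size_t)p * c.K], c.K,
                        c.t0, c.h, ang, false, 0, 0, &E, &dE);
        int sl = c.slot[p];
        terms[sl] += E;
        if (want_grad) {
          double w = W[sl] * dE;
          addf(i, 2, gA, w); addf(i, 3, gB, w); addf(j, 3, gC, w);
        }
      }
    } else {  // contacts
      for (int p = 0; p < c.n; p++) {
        int i = c.pi[p], j = c.pj[p];
        int si = is_cb ? (ctx.is_gly[i] ? 2 : 3) : 2;
        int sj = is_cb ? (ctx.is_gly[j] ? 2 : 3) : 2;
        const double *xi = POS(i, si), *xj = POS(j, sj);
        double dv[3]; vsub(xi, xj, dv);
        double d = vnorm(dv);
        if (d >= c.d_b + c.w_sw) continue;
        double sw = 0.0, dsw = 0.0;
        if (d > c.d_b) {
          double ds;
          sw = sstep((d - c.d_b) / c.w_sw, &ds);
          dsw = ds / c.w_sw;
        }
        int sl = c.slot[p];
        terms[sl] += -c.p[p] * (1.0 - sw);
        if (want_grad && d > 1e-9 && dsw != 0) {
          double w = W[sl] * c.p[p] * dsw / d;
          double f[3] = { w * dv[0], w * dv[1], w * dv[2] };
          addf(i, si, f, 1.0);
          double fneg[3] = { -f[0], -f[1], -f[2] };
          addf(j, sj, fneg, 1.0);
        }
      }
    }
  }

  // ---- generic terms ------------------------------------------------------
  if (ctx.vdw_on) {
    const std::vector<double>& radii = ctx.radii;
    double sigma = ctx.vdw_sigma;
    double wv = W[22];
    double rmax = 0;
    for (int a = 0; a < natoms; a++) rmax = std::max(rmax, radii[a]);
    double lim2 = sigma * 2 * rmax; lim2 *= lim2;
    for (int a = 0; a < natoms; a++) {
      if (radii[a] <= 0) continue;
      int ra = a / 7, sa = a % 7;
      for (int b = a + 1; b < natoms; b++) {
        if (radii[b] <= 0) continue;
        double dv[3]; vsub(&X[3 * a], &X[3 * b], dv);
        double d2 = vdot(dv, dv);
        if (d2 >= lim2) continue;
        int rb = b / 7, sb = b % 7;
        if (rb - ra <= 1 && vdw_excluded(ra, sa, rb, sb)) continue;
        double rc = sigma * (radii[a] + radii[b]);
        if (d2 >= rc * rc) continue;
        double d = std::sqrt(d2);
        double ov = rc - d;
        terms[22] += ov * ov;
        if (want_grad && d > 1e-9) {
          double w = wv * (-2.0 * ov) / d;
          for (int k = 0; k < 3; k++) {
            g[3 * a + k] += w * dv[k];
            g[3 * b + k] -= w * dv[k];
          }
        }
      }
    }
  }

  if (ctx.hb_on) {
    double wh = W[21];
    for (int i = 1; i < L; i++) {
      const double *H = POS(i, 1), *N = POS(i, 0);
      for (int j = 0; j < L; j++) {
        if (i - j < 2 && j - i < 2) continue;
        const double* O = POS(j, 6);
        double dv[3]; vsub(H, O, dv);
        double r2 = vdot(dv, dv);
        if (r2 > 9.0) continue;
        double r = std::sqrt(r2);
        double dsu, dsd;
        double Su = sstep((r - 1.2) / 0.3, &dsu);
        double Sd = 1.0 - sstep((r - 2.6) / 0.4, &dsd);
        double S_r = Su * Sd;
        double dS_r = dsu / 0.3 * Sd - Su * dsd / 0.4;
        if (S_r <= 0 && dS_r == 0) continue;
        double u[3], v[3];
        vsub(N, H, u); vsub(O, H, v);
        double nu = vnorm(u), nv = vnorm(v);
        double cc = vdot(u, v) / (nu * nv);
        double dsa;
        double S_a = sstep((-cc - 0.5) / 0.366, &dsa);
        double dS_a = dsa / 0.366;
        if (S_a <= 0 && dS_a == 0) continue;
        terms[21] += -S_r * S_a;
        if (want_grad) {
          double wr = wh * (-dS_r * S_a) / (r > 1e-9 ? r : 1e-9);
          for (int k = 0; k < 3; k++) {
            double f = wr * dv[k];
            g[3 * (7 * i + 1) + k] += f;
            g[3 * (7 * j + 6) + k] -= f;
          }
          double wc = wh * (S_r * dS_a);   // dE/dcos = +S_r * dsa/0.366
          for (int k = 0; k < 3; k++) {
            double dcdN = (v[k] / (nu * nv) - cc * u[k] / (nu * nu));
            double dcdO = (u[k] / (nu * nv) - cc * v[k] / (nv * nv));
            double dcdH = -dcdN - dcdO;
            g[3 * (7 * i + 0) + k] += wc * dcdN;
            g[3 * (7 * i + 1) + k] += wc * dcdH;
            g[3 * (7 * j + 6) + k] += wc * dcdO;
          }
        }
      }
    }
  }

  if (ctx.tor_on && !coords_in) {
    double wt = W[23];
    int n = 24;
    double t0 = ctx.tor_t0, h = ctx.tor_h;
    for (int i = 1; i < L - 1; i++) {
      const std::vector<double>& C = ctx.torC[ctx.tor_table[i]];
      double uf = wrap_pos((phi[i] - t0) / h, (double)n);
      double us = wrap_pos((psi[i] - t0) / h, (double)n);
      int kf = (int)std::floor(uf); if (kf >= n) kf = n - 1;
      int ks = (int)std::floor(us); if (ks >= n) ks = n - 1;
      double bf[4], dbf[4], bs[4], dbs[4];
      bspline_basis(uf - kf, bf, dbf);
      bspline_basis(us - ks, bs, dbs);
      double E = 0, dEf = 0, dEs = 0;
      for (int a = 0; a < 4; a++) {
        int ia = (kf - 1 + a + n) % n;
        for (int b = 0; b < 4; b++) {
          int ib = (ks - 1 + b + n) % n;
          double cc = C[(size_t)ia * n + ib];
          E += cc * bf[a] * bs[b];
          dEf += cc * dbf[a] * bs[b];
          dEs += cc * bf[a] * dbs[b];
        }
      }
      terms[23] += E;
      if (want_grad) {
        dphi[i] += wt * dEf / h;
        dpsi[i] += wt * dEs / h;
      }
    }
  }

  double total = 0;
  for (int s = 0; s < 24; s++) total += W[s] * terms[s];

  List out = List::create(_["total"] = total, _["terms"] = terms);
  if (want_grad) {
    std::vector<double> Sg(3 * (natoms + 1), 0.0), Sxg(3 * (natoms + 1), 0.0);
    for (int a = natoms - 1; a >= 0; a--) {
      double xg[3];
      vcross(&X[3 * a], &g[3 * a], xg);
      for (int k = 0; k < 3; k++) {
        Sg[3 * a + k] = Sg[3 * (a + 1) + k] + g[3 * a + k];
        Sxg[3 * a + k] = Sxg[3 * (a + 1) + k] + xg[k];
      }
    }
    for (int i = 0; i < L; i++) {
      if (i >= 1) {
        double u[3]; vsub(POS(i, 2), POS(i, 0), u); vunit(u);
        const double* pvt = POS(i, 2);
        int s = 7 * i + 3;
        double pxS[3];
        vcross(pvt, &Sg[3 * s], pxS);
        double tq = 0;
        for (int k = 0; k < 3; k++) tq += u[k] * (Sxg[3 * s + k] - pxS[k]);
        dphi[i] += tq;
      }
      if (i <= L - 2) {
        double u[3]; vsub(POS(i, 5), POS(i, 2), u); vunit(u);
        const double* pvt = POS(i, 5);
        int s = 7 * i + 6;
        double pxS[3];
        vcross(pvt, &Sg[3 * s], pxS);
        double tq = 0;
        for (int k = 0; k < 3; k++) tq += u[k] * (Sxg[3 * s + k] - pxS[k]);
        dpsi[i] += tq;
      }
    }
    NumericVector gphi(L), gpsi(L);
    for (int i = 0; i < L; i++) { gphi[i] = dphi[i]; gpsi[i] = dpsi[i]; }
    out["dphi"] = gphi;
    out["dpsi"] = gpsi;
  }
  #undef POS
  return out;
}

// [[Rcpp::export]]
List cpp_energy(NumericVector phi, NumericVector psi, IntegerVector is_gly,
                NumericVector sc_dist, List channels, NumericVector weights,
                List generic, bool want_grad,
                Nullable<NumericMatrix> coords_in) {
  Ctx* ctx = build_ctx(is_gly, sc_dist, channels, weights,
                       generic);
  std::vector<double> Xin;
  const double* cin = NULL;
  if (coords_in.isNotNull()) {
    if (want_grad) { delete ctx; stop("gradient requires torsion-built coordinates"); }
    NumericMatrix Ci(coords_in);
    if (Ci.nrow() != 7 * ctx->L) { delete ctx; stop("coords size mismatch"); }
    Xin.resize(3 * 7 * ctx->L);
    for (int a = 0; a < 7 * ctx->L; a++)
      for (int k = 0; k < 3; k++) Xin[3 * a + k] = Ci(a, k);
    cin = &Xin[0];
  }
  List out;
  try {
    out = eval_core(*ctx, &phi[0], &psi[0], want_grad, cin);
  } catch (...) {
    delete ctx;
    throw;
  }
  delete ctx;
  return out;
}

static void ctx_finalizer(Ctx* ctx) { delete ctx; }

// [[Rcpp::export]]
SEXP cpp_make_context(IntegerVector is_gly, NumericVector sc_dist,
                      List channels, NumericVector weights, List generic) {
  Ctx* ctx = build_ctx(is_gly, sc_dist, channels, weights,
                       generic);
  XPtr<Ctx> p(ctx, true);
  return p;
}

// [[Rcpp::export]]
List cpp_energy_ctx(SEXP ctx_sexp, NumericVector phi, NumericVector psi,
                    bool want_grad) {
  XPtr<Ctx> ctx(ctx_sexp);
  return eval_core(*ctx, &phi[0], &psi[0], want_grad, NULL);
}

// Two-loop recursion; S, Y are d x m buffers, ord gives the 0-based
// column indices in oldest-to-newest order.
// [[Rcpp::export]]
NumericVector cpp_lbfgs_direction(NumericVector g, NumericMatrix S,
                                  NumericMatrix Y, NumericVector rho,
                                  IntegerVector ord) {
  int d = g.size(), k = ord.size();
  NumericVector q = clone(g);
  std::vector<double> alpha(k);
  const double* Sp = &S(0, 0);
  const double* Yp = &Y(0, 0);
  for (int i = k - 1; i >= 0; i--) {
    const double* sc = Sp + (size_t)ord[i] * d;
    const double* yc = Yp + (size_t)ord[i] * d;
    double a = 0;
    for (int t = 0; t < d; t++) a += sc[t] * q[t];
    a *= rho[ord[i]];
    alpha[i] = a;
    for (int t = 0; t < d; t++) q[t] -= a * yc[t];
  }
  double gamma = 1.0;
  if (k > 0) {
    const double* sc = Sp + (size_t)ord[k - 1] * d;
    const double* yc = Yp + (size_t)ord[k - 1] * d;
    double sy = 0, yy = 0;
    for (int t = 0; t < d; t++) { sy += sc[t] * yc[t]; yy += yc[t] * yc[t]; }
    if (yy > 0) gamma = sy / yy;
  }
  for (int t = 0; t < d; t++) q[t] *= gamma;
  for (int i = 0; i < k; i++) {
    const double* sc = Sp + (size_t)ord[i] * d;
    const double* yc = Yp + (size_t)ord[i] * d;
    double b = 0;
    for (int t = 0; t < d; t++) b += yc[t] * q[t];
    b *= rho[ord[i]];
    double ab = alpha[i] - b;
    for (int t = 0; t < d; t++) q[t] += sc[t] * ab;
  }
  for (int t = 0; t < d; t++) q[t] = -q[t];
  return q;
}
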