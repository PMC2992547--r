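// Compiled core: torsion driving under fixed bond lengths/angles, empirical
// force-field evaluation, Kabsch superposition, bounded conjugate-gradient
// refinement, and a steady-state epsilon-dominance MOEA loop.
//
// The MOEA loop here is a performance twin of the pure-R reference in
// R/emoea.R: both draw from R's RNG in exactly the same order, so a run with
// the same seed is bitwise identical between the two (tested).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const double PI_C = 3.14159265358979323846;
static const double VDW_CAP = 1e6;   // keeps MOEA comparisons well-defined on clashes
static const double R_FLOOR = 0.05;  // distance floor, avoids division blowup

// floor-mod written exactly like R's `%%` on doubles, so that wrapped angles
// agree bitwise with the R reference implementation
static inline double rmod(double x1, double x2) {
  double q = x1 / x2;
  double tmp = x1 - std::floor(q) * x2;
  return tmp - std::floor(tmp / x2) * x2;
}

static inline double wrap_deg(double x) {
  return rmod(x + 180.0, 360.0) - 180.0;
}

struct FFSystem {
  int n;
  arma::mat X0;                        // reference coordinates, n x 3
  arma::imat bond_idx; arma::vec bond_r0, bond_k;
  arma::imat ang_idx;  arma::vec ang_th0, ang_k;   // th0 in radians
  arma::imat tor_idx;  arma::mat tor_v;            // V1 V2 V3 per quad
  arma::imat vdw_idx;  arma::vec vdw_eps, vdw_rstar, vdw_scale;
  int vdw_form;                        // 0 = LJ 12-6, 1 = buffered 14-7
  arma::imat rot_quad;                 // nr x 4 dihedral quads
  std::vector< std::vector<int> > rot_moving;
  std::vector<int> heavy;
  arma::mat ref_heavy;                 // input-conformation heavy coords (GD reference)
};

static inline arma::vec row3(const arma::mat& X, int i) {
  return arma::vec({X(i, 0), X(i, 1), X(i, 2)});
}

static inline void cross3(const double* a, const double* b, double* o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

static inline void diff3(const arma::mat& X, int i, int j, double* o) {
  o[0] = X(i, 0) - X(j, 0);
  o[1] = X(i, 1) - X(j, 1);
  o[2] = X(i, 2) - X(j, 2);
}

// Signed dihedral, atan2 convention; returns false if a quad is collinear.
static bool dihedral_rad(const arma::mat& X, int i, int j, int k, int l,
                         double& phi) {
  double b1[3], b2[3], b3[3], n1[3], n2[3], nx[3];
  diff3(X, j, i, b1);
  diff3(X, k, j, b2);
  diff3(X, l, k, b3);
  cross3(b1, b2, n1);
  cross3(b2, b3, n2);
  double l1 = norm3(n1), l2 = norm3(n2), lb = norm3(b2);
  if (l1 < 1e-10 || l2 < 1e-10 || lb < 1e-10) return false;
  cross3(n1, n2, nx);
  phi = std::atan2(dot3(nx, b2) / lb, dot3(n1, n2));
  return true;
}

static arma::mat apply_torsions_internal(const FFSystem& S,
                                         const arma::vec& ang_deg) {
  arma::mat X = S.X0;
  int nr = S.rot_quad.n_rows;
  for (int r = 0; r < nr; ++r) {
    int qi = S.rot_quad(r, 0), qj = S.rot_quad(r, 1),
        qk = S.rot_quad(r, 2), ql = S.rot_quad(r, 3);
    double cur;
    if (!dihedral_rad(X, qi, qj, qk, ql, cur))
      stop("undefined dihedral (collinear atoms) at rotatable bond %d", r + 1);
    double delta = ang_deg[r] * PI_C / 180.0 - cur;
    double a[3] = {X(qj, 0), X(qj, 1), X(qj, 2)};
    double u[3];
    diff3(X, qk, qj, u);
    double un = norm3(u);
    u[0] /= un; u[1] /= un; u[2] /= un;
    double c = std::cos(delta), s = std::sin(delta);
    const std::vector<int>& mov = S.rot_moving[r];
    for (size_t t = 0; t < mov.size(); ++t) {
      int idx = mov[t];
      double v[3] = {X(idx, 0) - a[0], X(idx, 1) - a[1], X(idx, 2) - a[2]};
      double uxv[3];
      cross3(u, v, uxv);
      double uv = dot3(u, v) * (1.0 - c);
      X(idx, 0) = a[0] + v[0] * c + uxv[0] * s + u[0] * uv;
      X(idx, 1) = a[1] + v[1] * c + uxv[1] * s + u[1] * uv;
      X(idx, 2) = a[2] + v[2] * c + uxv[2] * s + u[2] * uv;
    }
  }
  return X;
}

// out: vdw, torsion, bond, angle, total_no_elec
static void energy_terms_internal(const FFSystem& S, const arma::mat& X,
                                  double* out, bool vdw_torsion_only = false) {
  double eb = 0, ea = 0, et = 0, ev = 0;
  if (!vdw_torsion_only) {
    for (arma::uword b = 0; b < S.bond_idx.n_rows; ++b) {
      double v[3];
      diff3(X, S.bond_idx(b, 0), S.bond_idx(b, 1), v);
      double d = norm3(v) - S.bond_r0[b];
      eb += S.bond_k[b] * d * d;
    }
    for (arma::uword a = 0; a < S.ang_idx.n_rows; ++a) {
      double u[3], w[3];
      diff3(X, S.ang_idx(a, 0), S.ang_idx(a, 1), u);
      diff3(X, S.ang_idx(a, 2), S.ang_idx(a, 1), w);
      double ct = dot3(u, w) / (norm3(u) * norm3(w));
      ct = std::max(-1.0, std::min(1.0, ct));
      double d = std::acos(ct) - S.ang_th0[a];
      ea += S.ang_k[a] * d * d;
    }
  }
  for (arma::uword t = 0; t < S.tor_idx.n_rows; ++t) {
    double phi;
    if (!dihedral_rad(X, S.tor_idx(t, 0), S.tor_idx(t, 1),
                      S.tor_idx(t, 2), S.tor_idx(t, 3), phi))
      continue;  // collinear quad contributes nothing
    et += 0.5 * (S.tor_v(t, 0) * (1.0 + std::cos(phi)) +
                 S.tor_v(t, 1) * (1.0 - std::cos(2.0 * phi)) +
                 S.tor_v(t, 2) * (1.0 + std::cos(3.0 * phi)));
  }
  for (arma::uword p = 0; p < S.vdw_idx.n_rows; ++p) {
    double v[3];
    diff3(X, S.vdw_idx(p, 0), S.vdw_idx(p, 1), v);
    double r = norm3(v);
    if (r < R_FLOOR) r = R_FLOOR;
    double rs = S.vdw_rstar[p], e;
    if (S.vdw_form == 0) {
      double q = rs / r, q3 = q * q * q, q6 = q3 * q3;
      e = S.vdw_eps[p] * (q6 * q6 - 2.0 * q6);
    } else {
      double a1 = 1.07 * rs / (r + 0.07 * rs);
      double a3 = a1 * a1 * a1, a7 = a3 * a3 * a1;
      double r3 = r * r * r, r7 = r3 * r3 * r;
      double s3 = rs * rs * rs, rs7 = s3 * s3 * rs;
      e = S.vdw_eps[p] * a7 * (1.12 * rs7 / (r7 + 0.12 * rs7) - 2.0);
    }
    ev += S.vdw_scale[p] * e;
  }
  if (ev > VDW_CAP) ev = VDW_CAP;
  out[0] = ev; out[1] = et; out[2] = eb; out[3] = ea;
  out[4] = ev + et + eb + ea;
}

static double total_energy(const FFSystem& S, const arma::mat& X) {
  double o[5];
  energy_terms_internal(S, X, o);
  return o[4];
}

static arma::mat num_grad(const FFSystem& S, arma::mat X, double h = 1e-5) {
  arma::mat G(S.n, 3);
  for (int i = 0; i < S.n; ++i) {
    for (int d = 0; d < 3; ++d) {
      double x0 = X(i, d);
      X(i, d) = x0 + h;
      double ep = total_energy(S, X);
      X(i, d) = x0 - h;
      double em = total_energy(S, X);
      X(i, d) = x0;
      G(i, d) = (ep - em) / (2.0 * h);
    }
  }
  return G;
}

static double kabsch_internal(const arma::mat& A0, const arma::mat& B0) {
  arma::mat A = A0, B = B0;
  A.each_row() -= arma::mean(A, 0);
  B.each_row() -= arma::mean(B, 0);
  arma::mat H = A.t() * B;
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) stop("SVD failed in superposition");
  double d = arma::det(V * U.t()) < 0 ? -1.0 : 1.0;
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = d;
  arma::mat R = V * D * U.t();
  arma::mat E = A * R.t() - B;
  return std::sqrt(arma::accu(E % E) / A.n_rows);
}

static double rg_internal(const arma::mat& X, const std::vector<int>& idx) {
  arma::mat H(idx.size(), 3);
  for (size_t i = 0; i < idx.size(); ++i) H.row(i) = X.row(idx[i]);
  arma::rowvec c = arma::mean(H, 0);
  H.each_row() -= c;
  return std::sqrt(arma::accu(H % H) / H.n_rows);
}

static arma::imat to_imat0(SEXP x) {          // 1-based R matrix -> 0-based
  IntegerMatrix m(x);
  arma::imat out(m.nrow(), m.ncol());
  for (int i = 0; i < m.nrow(); ++i)
    for (int j = 0; j < m.ncol(); ++j) out(i, j) = m(i, j) - 1;
  return out;
}

// [[Rcpp::export]]
SEXP cpp_build_system(List spec) {
  FFSystem* S = new FFSystem;
  NumericMatrix X0(spec["X0"]);
  S->n = X0.nrow();
  S->X0 = as<arma::mat>(wrap(X0));
  S->bond_idx = to_imat0(spec["bond_idx"]);
  S->bond_r0 = as<arma::vec>(spec["bond_r0"]);
  S->bond_k = as<arma::vec>(spec["bond_k"]);
  S->ang_idx = to_imat0(spec["ang_idx"]);
  S->ang_th0 = as<arma::vec>(spec["ang_th0"]);
  S->ang_k = as<arma::vec>(spec["ang_k"]);
  S->tor_idx = to_imat0(spec["tor_idx"]);
  S->tor_v = as<arma::mat>(spec["tor_v"]);
  S->vdw_idx = to_imat0(spec["vdw_idx"]);
  S->vdw_eps = as<arma::vec>(spec["vdw_eps"]);
  S->vdw_rstar = as<arma::vec>(spec["vdw_rstar"]);
  S->vdw_scale = as<arma::vec>(spec["vdw_scale"]);
  S->vdw_form = as<int>(spec["vdw_form"]);
  S->rot_quad = to_imat0(spec["rot_quad"]);
  List mov(spec["rot_moving"]);
  for (int r = 0; r < mov.size(); ++r) {
    IntegerVector v(mov[r]);
    std::vector<int> mv(v.size());
    for (int i = 0; i < v.size(); ++i) mv[i] = v[i] - 1;
    S->rot_moving.push_back(mv);
  }
  IntegerVector hv(spec["heavy"]);
  for (int i = 0; i < hv.size(); ++i) S->heavy.push_back(hv[i] - 1);
  S->ref_heavy = as<arma::mat>(spec["ref_heavy"]);
  XPtr<FFSystem> p(S, true);
  return p;
}

// [[Rcpp::export]]
NumericMatrix cpp_sys_coords(SEXP sysp, NumericVector angles) {
  XPtr<FFSystem> S(sysp);
  arma::mat X = apply_torsions_internal(*S, as<arma::vec>(angles));
  return wrap(X);
}

// [[Rcpp::export]]
NumericVector cpp_sys_energy(SEXP sysp, NumericMatrix X_) {
  XPtr<FFSystem> S(sysp);
  arma::mat X = as<arma::mat>(wrap(X_));
  double o[5];
  energy_terms_internal(*S, X, o);
  return NumericVector::create(_["vdw"] = o[0], _["torsion"] = o[1],
                               _["bond"] = o[2], _["angle"] = o[3],
                               _["total_no_elec"] = o[4]);
}

// [[Rcpp::export]]
NumericMatrix cpp_sys_gradient(SEXP sysp, NumericMatrix X_) {
  XPtr<FFSystem> S(sysp);
  arma::mat X = as<arma::mat>(wrap(X_));
  return wrap(num_grad(*S, X));
}

// Objective vector for one genotype: (vdw, torsion[, GD, Rg]).
// [[Rcpp::export]]
NumericVector cpp_sys_evaluate(SEXP sysp, NumericVector angles, bool mecbm) {
  XPtr<FFSystem> S(sysp);
  arma::mat X = apply_torsions_internal(*S, as<arma::vec>(angles));
  double o[5];
  energy_terms_internal(*S, X, o, true);
  if (!mecbm) return NumericVector::create(o[0], o[1]);
  arma::mat H(S->heavy.size(), 3);
  for (size_t i = 0; i < S->heavy.size(); ++i) H.row(i) = X.row(S->heavy[i]);
  double gd = kabsch_internal(H, S->ref_heavy);
  double rg = rg_internal(X, S->heavy);
  return NumericVector::create(o[0], o[1], gd, rg);
}

// [[Rcpp::export]]
double cpp_kabsch_rmsd(NumericMatrix A_, NumericMatrix B_) {
  arma::mat A = as<arma::mat>(wrap(A_)), B = as<arma::mat>(wrap(B_));
  if (A.n_rows != B.n_rows) stop("paired coordinate sets differ in size");
  return kabsch_internal(A, B);
}

// [[Rcpp::export]]
NumericVector cpp_dihedrals(NumericMatrix X_, IntegerMatrix quads) {
  arma::mat X = as<arma::mat>(wrap(X_));
  NumericVector out(quads.nrow());
  for (int r = 0; r < quads.nrow(); ++r) {
    double phi;
    if (!dihedral_rad(X, quads(r, 0) - 1, quads(r, 1) - 1,
                      quads(r, 2) - 1, quads(r, 3) - 1, phi))
      stop("undefined dihedral (collinear atoms) in quad %d", r + 1);
    out[r] = wrap_deg(phi * 180.0 / PI_C);
  }
  return out;
}

// Polak-Ribiere conjugate gradient with Armijo backtracking.
// Stops on max-norm gradient <= grad_tol or after max_steps accepted steps.
// [[Rcpp::export]]
List cpp_minimize(SEXP sysp, NumericMatrix X_, int max_steps, double grad_tol) {
  XPtr<FFSystem> S(sysp);
  arma::mat X = as<arma::mat>(wrap(X_));
  double E = total_energy(*S, X);
  if (!std::isfinite(E)) stop("non-finite energy at minimization input");
  arma::mat G = num_grad(*S, X);
  int steps = 0;
  bool converged = arma::abs(G).max() <= grad_tol;
  arma::mat d = -G;
  while (!converged && steps < max_steps) {
    double gd = arma::accu(G % d);
    if (gd >= 0) { d = -G; gd = arma::accu(G % d); }
    double dmax = arma::abs(d).max();
    if (dmax <= 0) break;
    double alpha = std::min(1.0, 0.2 / dmax);  // cap initial displacement at 0.2 A
    bool ok = false;
    double Enew = E;
    for (int t = 0; t < 40; ++t) {
      arma::mat Xn = X + alpha * d;
      Enew = total_energy(*S, Xn);
      if (Enew <= E + 1e-4 * alpha * gd) { X = Xn; ok = true; break; }
      alpha *= 0.5;
    }
    if (!ok) break;  // no descent possible along d at machine scale
    ++steps;
    E = Enew;
    arma::mat Gn = num_grad(*S, X);
    if (arma::abs(Gn).max() <= grad_tol) { converged = true; G = Gn; break; }
    double beta = std::max(0.0, arma::accu(Gn % (Gn - G)) /
                                std::max(1e-12, arma::accu(G % G)));
    d = -Gn + beta * d;
    G = Gn;
  }
  double o[5];
  energy_terms_internal(*S, X, o);
  return List::create(_["coords"] = wrap(X), _["steps"] = steps,
                      _["converged"] = converged,
                      _["energy"] = NumericVector::create(
                          _["vdw"] = o[0], _["torsion"] = o[1], _["bond"] = o[2],
                          _["angle"] = o[3], _["total_no_elec"] = o[4]));
}

// ---------------------------------------------------------------------------
// epsilon-dominance archive + steady-state MOEA loop (RNG-mirrors R/emoea.R)
// ---------------------------------------------------------------------------

typedef std::vector<double> dvec;

static bool dom(const dvec& a, const dvec& b) {
  bool strict = false;
  for (size_t i = 0; i < a.size(); ++i) {
    if (a[i] > b[i]) return false;
    if (a[i] < b[i]) strict = true;
  }
  return strict;
}

struct CArchive {
  std::vector<dvec> geno, canon, raw, box;
};

static void arch_accept(CArchive& A, const dvec& g, const dvec& c,
                        const dvec& r, const dvec& eps) {
  size_t m = c.size();
  dvec b(m);
  for (size_t i = 0; i < m; ++i) b[i] = std::floor(c[i] / eps[i]);
  // same-box member?
  int same = -1;
  for (size_t k = 0; k < A.box.size(); ++k)
    if (A.box[k] == b) { same = (int)k; break; }
  if (same >= 0) {
    const dvec& mc = A.canon[same];
    bool take;
    if (dom(c, mc)) take = true;
    else if (dom(mc, c)) take = false;
    else {
      double dc = 0, dm = 0;
      for (size_t i = 0; i < m; ++i) {
        double corner = b[i] * eps[i];
        double uc = (c[i] - corner) / eps[i], um = (mc[i] - corner) / eps[i];
        dc += uc * uc; dm += um * um;
      }
      take = dc < dm;  // incumbent wins ties
    }
    if (take) { A.geno[same] = g; A.canon[same] = c; A.raw[same] = r; }
    return;
  }
  for (size_t k = 0; k < A.box.size(); ++k)
    if (dom(A.box[k], b)) return;  // candidate's box dominated -> reject
  // evict members whose boxes the candidate's box dominates (order preserved)
  size_t w = 0;
  for (size_t k = 0; k < A.box.size(); ++k) {
    if (!dom(b, A.box[k])) {
      if (w != k) {
        A.geno[w] = A.geno[k]; A.canon[w] = A.canon[k];
        A.raw[w] = A.raw[k]; A.box[w] = A.box[k];
      }
      ++w;
    }
  }
  A.geno.resize(w); A.canon.resize(w); A.raw.resize(w); A.box.resize(w);
  A.geno.push_back(g); A.canon.push_back(c); A.raw.push_back(r);
  A.box.push_back(b);
}

static inline int rnd_idx(int n) {           // mirrors floor(runif(1)*n)+1 - 1
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static dvec vary_cpp(const dvec& p1, const dvec& p2, double cx_rate,
                     double mut_rate) {
  size_t ng = p1.size();
  dvec child = p1;
  if (cx_rate > 0 && unif_rand() < cx_rate) {
    for (size_t g = 0; g < ng; ++g) {
      double u = unif_rand();
      child[g] = wrap_deg(p1[g] + u * wrap_deg(p2[g] - p1[g]));
    }
  }
  if (mut_rate > 0) {
    std::vector<bool> mut(ng);
    for (size_t g = 0; g < ng; ++g) mut[g] = unif_rand() < mut_rate;
    for (size_t g = 0; g < ng; ++g)
      if (mut[g]) child[g] = -180.0 + unif_rand() * 360.0;
  }
  return child;
}

// [[Rcpp::export]]
List cpp_run_emoea(SEXP sysp, bool mecbm, NumericVector eps_, NumericVector sgn_,
                   int n_pop, int n_gen, Nullable<NumericVector> init_,
                   double cx_rate, double mut_rate, double energy_window) {
  XPtr<FFSystem> S(sysp);
  int ng = S->rot_quad.n_rows;
  int m = eps_.size();
  dvec eps(eps_.begin(), eps_.end()), sgn(sgn_.begin(), sgn_.end());

  std::vector<dvec> pop_g(n_pop, dvec(ng)), pop_c(n_pop, dvec(m));
  for (int p = 0; p < n_pop; ++p)
    for (int g = 0; g < ng; ++g) pop_g[p][g] = -180.0 + unif_rand() * 360.0;
  if (init_.isNotNull()) {
    NumericVector init(init_);
    for (int g = 0; g < ng; ++g) pop_g[0][g] = wrap_deg(init[g]);
  }

  NumericVector angv(ng);
  std::vector<dvec> pop_r(n_pop, dvec(m));
  long n_eval = 0;
  for (int p = 0; p < n_pop; ++p) {
    for (int g = 0; g < ng; ++g) angv[g] = pop_g[p][g];
    NumericVector o = cpp_sys_evaluate(sysp, angv, mecbm);
    for (int i = 0; i < m; ++i) { pop_r[p][i] = o[i]; pop_c[p][i] = sgn[i] * o[i]; }
    ++n_eval;
  }
  // in-run energy window on the force-field objectives (canonical 0 and 1):
  // structures above the running minimum + window are discarded on sight
  double fe_min = R_PosInf;
  for (int p = 0; p < n_pop; ++p)
    fe_min = std::min(fe_min, pop_c[p][0] + pop_c[p][1]);
  CArchive A;
  for (int p = 0; p < n_pop; ++p)
    if (pop_c[p][0] + pop_c[p][1] <= fe_min + energy_window)
      arch_accept(A, pop_g[p], pop_c[p], pop_r[p], eps);

  long n_iter = (long)n_pop * n_gen;
  for (long it = 0; it < n_iter; ++it) {
    int i1 = rnd_idx(n_pop), i2 = rnd_idx(n_pop);
    int p1;
    if (dom(pop_c[i1], pop_c[i2])) p1 = i1;
    else if (dom(pop_c[i2], pop_c[i1])) p1 = i2;
    else p1 = (unif_rand() < 0.5) ? i1 : i2;
    int ai = rnd_idx((int)A.geno.size());
    dvec child = vary_cpp(pop_g[p1], A.geno[ai], cx_rate, mut_rate);
    for (int g = 0; g < ng; ++g) angv[g] = child[g];
    NumericVector o = cpp_sys_evaluate(sysp, angv, mecbm);
    dvec cr(m), cc(m);
    for (int i = 0; i < m; ++i) { cr[i] = o[i]; cc[i] = sgn[i] * o[i]; }
    ++n_eval;
    double fe = cc[0] + cc[1];
    if (fe < fe_min) fe_min = fe;
    if (fe > fe_min + energy_window) continue;  // discard as soon as identified
    arch_accept(A, child, cc, cr, eps);
    // population update: reject if dominated; else replace a dominated member,
    // else a random member
    bool rejected = false;
    for (int p = 0; p < n_pop; ++p)
      if (dom(pop_c[p], cc)) { rejected = true; break; }
    if (!rejected) {
      std::vector<int> dominated;
      for (int p = 0; p < n_pop; ++p)
        if (dom(cc, pop_c[p])) dominated.push_back(p);
      int repl;
      if (!dominated.empty()) repl = dominated[rnd_idx((int)dominated.size())];
      else repl = rnd_idx(n_pop);
      pop_g[repl] = child;
      pop_c[repl] = cc;
    }
  }

  int k = (int)A.geno.size();
  NumericMatrix geno(k, ng), canon(k, m), raw(k, m), box(k, m);
  for (int i = 0; i < k; ++i) {
    for (int g = 0; g < ng; ++g) geno(i, g) = A.geno[i][g];
    for (int j = 0; j < m; ++j) {
      canon(i, j) = A.canon[i][j];
      raw(i, j) = A.raw[i][j];
      box(i, j) = A.box[i][j];
    }
  }
  return List::create(_["genotypes"] = geno, _["canonical"] = canon,
                      _["objectives"] = raw, _["boxes"] = box,
                      _["n_evaluations"] = (double)n_eval);
}
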