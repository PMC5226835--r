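// Compiled engine: flow-law evaluation, analytic Jacobians, bottom-up
// steady-state sampling, eigenvalue screening, and adaptive ODE integration
// (Dormand-Prince RK45 and a Kaps-Rentrop Rosenbrock 4(3) stiff method)
// with extremum
// tracking for oscillation detection. All randomness is drawn from R's RNG
// so results are reproducible via set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Packed model description
//
// pack = [m, M, ntheta, eta (m*M col-major), per flow: nfac, nfac*7 doubles]
// factor record: [type, s1, s2, i1, i2, c1, c2]   (indices 0-based, -1 unused)
//   type 1 POW       : S[s1]^c1
//   type 2 MM        : S[s1]/(S[s1] + theta[i1])
//   type 3 HILL_ACT  : x^c1/(1+x^c1),  x = S[s1]/theta[i1]
//   type 4 HILL_INH  : 1/(1+x^c1)
//   type 5 SWITCH    : (S[s1]+c1) / (theta[i1]*(1+(S[s2]/theta[i2])^c2)
//                                    + S[s1] + c1)
//   type 6 HILL_BASAL: 1 + x^c1 (basal rate plus Hill activation)
// ---------------------------------------------------------------------------

struct Factor {
  int type, s1, s2, i1, i2;
  double c1, c2;
};

// hard caps that keep hot-path buffers on the stack
#define OSC_MAX_SPECIES 32
#define OSC_MAX_FLOWS 96

static bool luFactor(double* A, int* piv, int m);
static void luSolve(const double* A, const int* piv, double* b, int m);

struct Model {
  int m, M, ntheta;
  arma::mat eta;                         // m x M
  std::vector< std::vector<Factor> > fac;
};

static Model parsePack(const NumericVector& pack) {
  Model mod;
  int pos = 0;
  mod.m = (int) pack[pos++];
  mod.M = (int) pack[pos++];
  mod.ntheta = (int) pack[pos++];
  if (mod.m > OSC_MAX_SPECIES || mod.M > OSC_MAX_FLOWS)
    stop("model exceeds the compiled species/flow limits");
  mod.eta.set_size(mod.m, mod.M);
  for (int j = 0; j < mod.M; ++j)
    for (int i = 0; i < mod.m; ++i)
      mod.eta(i, j) = pack[pos++];
  mod.fac.resize(mod.M);
  for (int j = 0; j < mod.M; ++j) {
    int nf = (int) pack[pos++];
    mod.fac[j].resize(nf);
    for (int a = 0; a < nf; ++a) {
      Factor f;
      f.type = (int) pack[pos++];
      f.s1 = (int) pack[pos++];
      f.s2 = (int) pack[pos++];
      f.i1 = (int) pack[pos++];
      f.i2 = (int) pack[pos++];
      f.c1 = pack[pos++];
      f.c2 = pack[pos++];
      mod.fac[j][a] = f;
    }
  }
  return mod;
}

// x^e with a fast path for small positive integral exponents (the common
// Hill/cooperativity case)
static inline double powFast(double x, double e) {
  if (e == 1.0) return x;
  if (e == 2.0) return x * x;
  int n = (int) e;
  if ((double) n == e && n > 0 && n <= 64) {
    double r = 1.0, b = x;
    while (n) {
      if (n & 1) r *= b;
      b *= b;
      n >>= 1;
    }
    return r;
  }
  return std::pow(x, e);
}

static inline double facVal(const Factor& f, const double* S, const double* th) {
  switch (f.type) {
  case 1:
    return (f.c1 == 1.0) ? S[f.s1] : powFast(S[f.s1], f.c1);
  case 2:
    return S[f.s1] / (S[f.s1] + th[f.i1]);
  case 3: {
    double xn = powFast(S[f.s1] / th[f.i1], f.c1);
    if (!std::isfinite(xn)) return 1.0;
    return xn / (1.0 + xn);
  }
  case 4: {
    double xn = powFast(S[f.s1] / th[f.i1], f.c1);
    if (!std::isfinite(xn)) return 0.0;
    return 1.0 / (1.0 + xn);
  }
  case 5: {
    double u = powFast(S[f.s2] / th[f.i2], f.c2);
    double num = S[f.s1] + f.c1;
    return num / (th[f.i1] * (1.0 + u) + num);
  }
  case 6: {
    double xn = powFast(S[f.s1] / th[f.i1], f.c1);
    return 1.0 + xn;
  }
  default:
    return NA_REAL;
  }
}

// d log(factor) / d S_i, accumulated into row of length m
static inline void facLogDeriv(const Factor& f, const double* S,
                               const double* th, double* dlogdS) {
  switch (f.type) {
  case 1:
    dlogdS[f.s1] += f.c1 / S[f.s1];
    break;
  case 2:
    dlogdS[f.s1] += th[f.i1] / (S[f.s1] * (S[f.s1] + th[f.i1]));
    break;
  case 3: {
    double xn = powFast(S[f.s1] / th[f.i1], f.c1);
    if (std::isfinite(xn))
      dlogdS[f.s1] += (f.c1 / S[f.s1]) / (1.0 + xn);
    break;
  }
  case 4: {
    double xn = powFast(S[f.s1] / th[f.i1], f.c1);
    if (std::isfinite(xn))
      dlogdS[f.s1] += -(f.c1 / S[f.s1]) * xn / (1.0 + xn);
    break;
  }
  case 5: {
    double u = powFast(S[f.s2] / th[f.i2], f.c2);
    double num = S[f.s1] + f.c1;
    double D = th[f.i1] * (1.0 + u) + num;
    dlogdS[f.s1] += 1.0 / num - 1.0 / D;
    dlogdS[f.s2] += -(th[f.i1] * f.c2 * u / S[f.s2]) / D;
    break;
  }
  case 6: {
    double xn = powFast(S[f.s1] / th[f.i1], f.c1);
    if (std::isfinite(xn))
      dlogdS[f.s1] += (f.c1 / S[f.s1]) * xn / (1.0 + xn);
    break;
  }
  }
}

static void evalG(const Model& mod, const double* S, const double* th,
                  double* g) {
  for (int j = 0; j < mod.M; ++j) {
    double v = 1.0;
    for (size_t a = 0; a < mod.fac[j].size(); ++a)
      v *= facVal(mod.fac[j][a], S, th);
    g[j] = v;
  }
}

static void evalFlows(const Model& mod, const double* S, const double* k,
                      const double* th, double* nu) {
  evalG(mod, S, th, nu);
  for (int j = 0; j < mod.M; ++j) nu[j] *= k[j];
}

static void evalRHS(const Model& mod, const double* S, const double* k,
                    const double* th, double* dS) {
  double nu[OSC_MAX_FLOWS];
  evalFlows(mod, S, k, th, nu);
  for (int i = 0; i < mod.m; ++i) {
    double acc = 0.0;
    for (int j = 0; j < mod.M; ++j) acc += mod.eta(i, j) * nu[j];
    dS[i] = acc;
  }
}

static void evalJacInto(const Model& mod, const double* S, const double* k,
                        const double* th, arma::mat& J) {
  double dlog[OSC_MAX_SPECIES];
  J.zeros(mod.m, mod.m);
  for (int j = 0; j < mod.M; ++j) {
    double nu = 1.0;
    for (size_t a = 0; a < mod.fac[j].size(); ++a)
      nu *= facVal(mod.fac[j][a], S, th);
    nu *= k[j];
    for (int i = 0; i < mod.m; ++i) dlog[i] = 0.0;
    for (size_t a = 0; a < mod.fac[j].size(); ++a)
      facLogDeriv(mod.fac[j][a], S, th, dlog);
    for (int c = 0; c < mod.m; ++c) {
      double dv = nu * dlog[c];
      if (dv != 0.0)
        for (int i = 0; i < mod.m; ++i) J(i, c) += mod.eta(i, j) * dv;
    }
  }
}

static arma::mat evalJac(const Model& mod, const double* S, const double* k,
                         const double* th) {
  arma::mat J(mod.m, mod.m);
  evalJacInto(mod, S, k, th, J);
  return J;
}

// [[Rcpp::export]]
NumericVector cppFlows(NumericVector pack, NumericVector S, NumericVector k,
                       NumericVector theta) {
  Model mod = parsePack(pack);
  NumericVector nu(mod.M);
  evalFlows(mod, S.begin(), k.begin(), theta.begin(), nu.begin());
  return nu;
}

// [[Rcpp::export]]
NumericVector cppGFactors(NumericVector pack, NumericVector S,
                          NumericVector theta) {
  Model mod = parsePack(pack);
  NumericVector g(mod.M);
  evalG(mod, S.begin(), theta.begin(), g.begin());
  return g;
}

// [[Rcpp::export]]
NumericVector cppRHS(NumericVector pack, NumericVector S, NumericVector k,
                     NumericVector theta) {
  Model mod = parsePack(pack);
  NumericVector dS(mod.m);
  evalRHS(mod, S.begin(), k.begin(), theta.begin(), dS.begin());
  return dS;
}

// [[Rcpp::export]]
NumericMatrix cppJacobian(NumericVector pack, NumericVector S, NumericVector k,
                          NumericVector theta) {
  Model mod = parsePack(pack);
  arma::mat J = evalJac(mod, S.begin(), k.begin(), theta.begin());
  return wrap(J);
}

// [[Rcpp::export]]
ComplexVector cppEigvals(NumericVector pack, NumericVector S, NumericVector k,
                         NumericVector theta) {
  Model mod = parsePack(pack);
  arma::mat J = evalJac(mod, S.begin(), k.begin(), theta.begin());
  arma::cx_vec ev;
  arma::eig_gen(ev, J);
  return wrap(ev);
}

// Max real part of the Jacobian spectrum for each sampled state; the
// nExclude eigenvalues of smallest modulus (conservation-induced zeros)
// are ignored.
// [[Rcpp::export]]
NumericVector cppMaxReEig(NumericVector pack, NumericMatrix S, NumericMatrix k,
                          NumericMatrix theta, int nExclude) {
  Model mod = parsePack(pack);
  int n = S.ncol();
  NumericVector out(n);
  arma::cx_vec ev;
  const double* thdummy = NULL;
  for (int c = 0; c < n; ++c) {
    const double* th = (theta.nrow() > 0) ? &theta(0, c) : thdummy;
    arma::mat J = evalJac(mod, &S(0, c), &k(0, c), th);
    bool ok = arma::eig_gen(ev, J);
    if (!ok) { out[c] = NA_REAL; continue; }
    if (nExclude > 0) {
      arma::uvec idx = arma::sort_index(arma::abs(ev));
      double best = -std::numeric_limits<double>::infinity();
      for (int q = nExclude; q < (int) ev.n_elem; ++q)
        best = std::max(best, ev(idx(q)).real());
      out[c] = best;
    } else {
      out[c] = arma::real(ev).max();
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Bottom-up sampler
// ---------------------------------------------------------------------------

// Gaussian-elimination rank of a small matrix (columns given by idx);
// row-major stack buffer, no allocations
static int geRank(const arma::mat& A, const std::vector<int>& cols) {
  int m = A.n_rows, n = (int) cols.size();
  double B[OSC_MAX_SPECIES * OSC_MAX_FLOWS];
  double amax = 1.0;
  for (int r = 0; r < m; ++r)
    for (int j = 0; j < n; ++j) {
      double v = A(r, cols[j]);
      B[r * n + j] = v;
      if (std::abs(v) > amax) amax = std::abs(v);
    }
  double tol = 1e-9 * amax;
  int rank = 0;
  for (int col = 0; col < n && rank < m; ++col) {
    int piv = -1;
    double best = tol;
    for (int r = rank; r < m; ++r)
      if (std::abs(B[r * n + col]) > best) {
        best = std::abs(B[r * n + col]);
        piv = r;
      }
    if (piv < 0) continue;
    if (piv != rank)
      for (int c2 = 0; c2 < n; ++c2)
        std::swap(B[rank * n + c2], B[piv * n + c2]);
    for (int r = rank + 1; r < m; ++r) {
      double f = B[r * n + col] / B[rank * n + col];
      if (f != 0.0)
        for (int c2 = col; c2 < n; ++c2) B[r * n + c2] -= f * B[rank * n + c2];
    }
    ++rank;
  }
  return rank;
}

// [[Rcpp::export]]
List cppSampleStates(NumericVector pack, int n,
                     NumericVector sLo, NumericVector sHi,   // log10, per species
                     double flowLo, double flowHi,           // log10
                     double thetaLo, double thetaHi,         // log10
                     int maxAttempts,
                     NumericMatrix Sfix, NumericMatrix thetaFix) {
  Model mod = parsePack(pack);
  const int m = mod.m, M = mod.M, nt = mod.ntheta;

  // rank and independent-row selection of eta (for rank-deficient models)
  std::vector<int> allCols(M);
  for (int j = 0; j < M; ++j) allCols[j] = j;
  int r = geRank(mod.eta, allCols);
  // row basis via rank of transposed submatrices
  arma::mat etaT = mod.eta.t();
  std::vector<int> rowSel;
  {
    std::vector<int> cur;
    for (int i = 0; i < m && (int) rowSel.size() < r; ++i) {
      cur.push_back(i);
      if (geRank(etaT, cur) == (int) cur.size()) rowSel.push_back(i);
      else cur.pop_back();
    }
  }
  arma::mat etaR(r, M);
  for (int q = 0; q < r; ++q) etaR.row(q) = mod.eta.row(rowSel[q]);

  NumericMatrix S0(m, n), nu0(M, n), theta(std::max(nt, 1), n), kout(M, n);
  IntegerVector attempts(n);
  LogicalVector ok(n);
  bool haveSfix = (Sfix.nrow() == m && Sfix.ncol() == n);
  bool haveTfix = (nt > 0 && thetaFix.nrow() == nt && thetaFix.ncol() == n);
  double flowLoLin = std::pow(10.0, flowLo), flowHiLin = std::pow(10.0, flowHi);

  std::vector<int> perm(M), freeF, depF;
  std::vector<double> Sv(m), thv(std::max(nt, 1)), nuv(M), gv(M);

  for (int c = 0; c < n; ++c) {
    ok[c] = false;
    // concentrations (log10-uniform; per-species interval)
    for (int i = 0; i < m; ++i) {
      if (haveSfix && R_finite(Sfix(i, c))) Sv[i] = Sfix(i, c);
      else Sv[i] = std::pow(10.0, sLo[i] + unif_rand() * (sHi[i] - sLo[i]));
    }
    // nl-parameters
    for (int i = 0; i < nt; ++i) {
      if (haveTfix && R_finite(thetaFix(i, c))) thv[i] = thetaFix(i, c);
      else thv[i] = std::pow(10.0, thetaLo + unif_rand() * (thetaHi - thetaLo));
    }
    // flows: random-order greedy selection of M-r free flows, dependents solved
    int att = 0;
    bool accepted = false;
    while (att < maxAttempts && !accepted) {
      ++att;
      for (int j = 0; j < M; ++j) perm[j] = j;
      for (int j = M - 1; j > 0; --j) {
        int q = (int) std::floor(unif_rand() * (j + 1));
        if (q > j) q = j;
        std::swap(perm[j], perm[q]);
      }
      freeF.clear();
      for (int pi = 0; pi < M && (int) freeF.size() < M - r; ++pi) {
        int j = perm[pi];
        // complement of freeF + {j} must retain rank r
        std::vector<int> rest;
        rest.reserve(M);
        for (int q = 0; q < M; ++q) {
          if (q == j) continue;
          bool isFree = false;
          for (size_t f = 0; f < freeF.size(); ++f)
            if (freeF[f] == q) { isFree = true; break; }
          if (!isFree) rest.push_back(q);
        }
        if (geRank(mod.eta, rest) == r) freeF.push_back(j);
      }
      if ((int) freeF.size() != M - r) break; // structurally impossible
      depF.clear();
      for (int q = 0; q < M; ++q) {
        bool isFree = false;
        for (size_t f = 0; f < freeF.size(); ++f)
          if (freeF[f] == q) { isFree = true; break; }
        if (!isFree) depF.push_back(q);
      }
      for (int j = 0; j < M; ++j) nuv[j] = 0.0;
      for (size_t f = 0; f < freeF.size(); ++f)
        nuv[freeF[f]] = std::pow(10.0, flowLo + unif_rand() * (flowHi - flowLo));
      // solve etaR[,dep] x = -etaR[,free] nu_free  (square r x r, full rank)
      double A[OSC_MAX_SPECIES * OSC_MAX_SPECIES], b[OSC_MAX_SPECIES];
      int piv[OSC_MAX_SPECIES];
      for (int q = 0; q < r; ++q) {
        for (int d = 0; d < r; ++d) A[q * r + d] = etaR(q, depF[d]);
        double acc = 0.0;
        for (size_t f = 0; f < freeF.size(); ++f)
          acc += etaR(q, freeF[f]) * nuv[freeF[f]];
        b[q] = -acc;
      }
      if (!luFactor(A, piv, r)) continue;
      luSolve(A, piv, b, r);
      bool inRange = true;
      for (int d = 0; d < r; ++d) {
        nuv[depF[d]] = b[d];
        if (!(b[d] > flowLoLin && b[d] < flowHiLin)) inRange = false;
      }
      if (inRange) accepted = true;
    }
    attempts[c] = att;
    if (!accepted) continue;
    evalG(mod, Sv.data(), thv.data(), gv.data());
    bool gok = true;
    for (int j = 0; j < M; ++j)
      if (!(gv[j] > 0.0) || !std::isfinite(gv[j])) gok = false;
    if (!gok) continue;
    for (int i = 0; i < m; ++i) S0(i, c) = Sv[i];
    for (int i = 0; i < nt; ++i) theta(i, c) = thv[i];
    for (int j = 0; j < M; ++j) {
      nu0(j, c) = nuv[j];
      kout(j, c) = nuv[j] / gv[j];
    }
    ok[c] = true;
  }

  return List::create(_["S0"] = S0, _["nu0"] = nu0, _["theta"] = theta,
                      _["k"] = kout, _["attempts"] = attempts, _["ok"] = ok,
                      _["rank"] = r);
}

// ---------------------------------------------------------------------------
// Integrators with extremum tracking
// ---------------------------------------------------------------------------

// Extremum events are kept in per-(species, kind) ring buffers: fast
// oscillators can produce millions of extrema over a long window, but
// detection and amplitude extraction only ever look at the most recent
// ones, so only the newest ringCap per stream are retained.
struct Recorder {
  int m;
  int ringCap;
  std::vector<double> evT, evV;     // m*2 streams, each ringCap wide
  std::vector<int> evHead, evCount; // per stream
  std::vector<double> ymin, ymax;
  // ring buffer of accepted steps
  int bufSize, bufCount, bufHead;
  std::vector<double> bufT, bufY;

  Recorder(int m_, int ringCap_, int bufSize_)
    : m(m_), ringCap(ringCap_),
      evT((size_t) m_ * 2 * ringCap_), evV((size_t) m_ * 2 * ringCap_),
      evHead(m_ * 2, 0), evCount(m_ * 2, 0),
      ymin(m_, std::numeric_limits<double>::infinity()),
      ymax(m_, -std::numeric_limits<double>::infinity()),
      bufSize(bufSize_), bufCount(0), bufHead(0),
      bufT(bufSize_), bufY((size_t) bufSize_ * m_) {}

  void pushStep(double t, const double* y) {
    for (int i = 0; i < m; ++i) {
      ymin[i] = std::min(ymin[i], y[i]);
      ymax[i] = std::max(ymax[i], y[i]);
    }
    bufT[bufHead] = t;
    for (int i = 0; i < m; ++i) bufY[(size_t) bufHead * m + i] = y[i];
    bufHead = (bufHead + 1) % bufSize;
    if (bufCount < bufSize) ++bufCount;
  }

  void pushEvent(int sp, double t, double v, bool isMax) {
    int s = sp * 2 + (isMax ? 0 : 1);
    size_t base = (size_t) s * ringCap;
    evT[base + evHead[s]] = t;
    evV[base + evHead[s]] = v;
    evHead[s] = (evHead[s] + 1) % ringCap;
    if (evCount[s] < ringCap) ++evCount[s];
    ymin[sp] = std::min(ymin[sp], v);
    ymax[sp] = std::max(ymax[sp], v);
  }
};

// cubic Hermite extremum location on [0,1]; returns theta in (0,1) or -1
static double hermiteExtremum(double y0, double y1, double f0h, double f1h) {
  // dy/dtheta = a th^2 + b th + c, with f*h = derivative scaled to theta
  double d = y1 - y0;
  double a = -6.0 * d + 3.0 * (f0h + f1h);
  double b = 6.0 * d - 4.0 * f0h - 2.0 * f1h;
  double c = f0h;
  double th = -1.0;
  if (std::abs(a) < 1e-14 * (std::abs(b) + 1e-300)) {
    if (std::abs(b) > 0) th = -c / b;
  } else {
    double disc = b * b - 4.0 * a * c;
    if (disc >= 0) {
      double sq = std::sqrt(disc);
      double r1 = (-b + sq) / (2.0 * a), r2 = (-b - sq) / (2.0 * a);
      if (r1 > 0.0 && r1 < 1.0) th = r1;
      if (r2 > 0.0 && r2 < 1.0 && (th < 0.0 || std::abs(r2 - 0.5) < std::abs(th - 0.5)))
        th = r2;
    }
  }
  if (!(th > 0.0 && th < 1.0)) {
    // derivative changes sign across the step; fall back to linear zero
    if (f0h != f1h) th = f0h / (f0h - f1h);
    if (!(th > 0.0 && th < 1.0)) th = 0.5;
  }
  return th;
}

static double hermiteValue(double y0, double y1, double f0h, double f1h,
                           double th) {
  double th2 = th * th, th3 = th2 * th;
  return (2 * th3 - 3 * th2 + 1) * y0 + (th3 - 2 * th2 + th) * f0h +
         (-2 * th3 + 3 * th2) * y1 + (th3 - th2) * f1h;
}

// classical RK4 with nsub fixed substeps, for precise extremum values
static void rk4To(const Model& mod, const double* k, const double* th,
                  const double* y0, double t0, double t1, int nsub,
                  double* yout, int m) {
  double y[OSC_MAX_SPECIES], k1[OSC_MAX_SPECIES], k2[OSC_MAX_SPECIES],
         k3[OSC_MAX_SPECIES], k4[OSC_MAX_SPECIES], tmp[OSC_MAX_SPECIES];
  for (int i = 0; i < m; ++i) y[i] = y0[i];
  double h = (t1 - t0) / nsub;
  for (int s = 0; s < nsub; ++s) {
    evalRHS(mod, y, k, th, k1);
    for (int i = 0; i < m; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
    evalRHS(mod, tmp, k, th, k2);
    for (int i = 0; i < m; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
    evalRHS(mod, tmp, k, th, k3);
    for (int i = 0; i < m; ++i) tmp[i] = y[i] + h * k3[i];
    evalRHS(mod, tmp, k, th, k4);
    for (int i = 0; i < m; ++i)
      y[i] += h / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);
  }
  for (int i = 0; i < m; ++i) yout[i] = y[i];
}

// Process extrema on an accepted step [t, t+h]. Maxima enter the
// regular-oscillation test (equality within 1e-6 relative), so with
// preciseRefine their value is recomputed by re-stepping from the step start
// with fixed RK4 substeps; the interpolation error then matches the
// solution's own accuracy and cancels between consecutive maxima. Minima
// only feed the amplitude (max - min over one period), where the cubic
// Hermite interpolant is precise enough.
static void recordExtrema(const Model& mod, const double* k, const double* th,
                          Recorder& rec, double t, double h, const double* y,
                          const double* ynew, const double* f0,
                          const double* f1, bool preciseRefine) {
  int m = mod.m;
  double yref[OSC_MAX_SPECIES];
  for (int i = 0; i < m; ++i) {
    bool isMax = (f0[i] > 0.0 && f1[i] <= 0.0);
    bool isMin = (f0[i] < 0.0 && f1[i] >= 0.0);
    if (!isMax && !isMin) continue;
    double thx = hermiteExtremum(y[i], ynew[i], f0[i] * h, f1[i] * h);
    double tstar = t + thx * h;
    double val;
    if (preciseRefine && isMax) {
      rk4To(mod, k, th, y, t, tstar, 4, yref, m);
      val = yref[i];
    } else {
      val = hermiteValue(y[i], ynew[i], f0[i] * h, f1[i] * h, thx);
    }
    rec.pushEvent(i, tstar, val, isMax);
  }
}

// in-place LU factorisation with partial pivoting (row-major, m x m)
static bool luFactor(double* A, int* piv, int m) {
  for (int c = 0; c < m; ++c) {
    int p = c;
    double best = std::abs(A[c * m + c]);
    for (int r = c + 1; r < m; ++r)
      if (std::abs(A[r * m + c]) > best) { best = std::abs(A[r * m + c]); p = r; }
    if (!(best > 0.0) || !std::isfinite(best)) return false;
    piv[c] = p;
    if (p != c)
      for (int q = 0; q < m; ++q) std::swap(A[c * m + q], A[p * m + q]);
    double d = A[c * m + c];
    for (int r = c + 1; r < m; ++r) {
      double f = A[r * m + c] / d;
      A[r * m + c] = f;
      if (f != 0.0)
        for (int q = c + 1; q < m; ++q) A[r * m + q] -= f * A[c * m + q];
    }
  }
  return true;
}

static void luSolve(const double* A, const int* piv, double* b, int m) {
  for (int c = 0; c < m; ++c) {
    if (piv[c] != c) std::swap(b[c], b[piv[c]]);
    for (int r = c + 1; r < m; ++r) b[r] -= A[r * m + c] * b[c];
  }
  for (int c = m - 1; c >= 0; --c) {
    b[c] /= A[c * m + c];
    for (int r = 0; r < c; ++r) b[r] -= A[r * m + c] * b[c];
  }
}

// Dormand-Prince RK45 coefficients
static const double DP_c2 = 1.0 / 5, DP_c3 = 3.0 / 10, DP_c4 = 4.0 / 5,
                    DP_c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

// shared output assembly
static List finishSim(int status, double t, const std::vector<double>& y,
                      long steps, long fevals, const Recorder& rec,
                      const NumericMatrix& dense, bool haveDense) {
  int m = (int) y.size();
  NumericVector yout(m);
  for (int i = 0; i < m; ++i) yout[i] = y[i];
  int nb = rec.bufCount;
  NumericVector bt(nb);
  NumericMatrix by(m, nb);
  int start = (rec.bufHead - rec.bufCount + rec.bufSize * 2) % rec.bufSize;
  for (int q = 0; q < nb; ++q) {
    int idx = (start + q) % rec.bufSize;
    bt[q] = rec.bufT[idx];
    for (int i = 0; i < m; ++i) by(i, q) = rec.bufY[(size_t) idx * m + i];
  }
  // unpack the per-stream extremum rings in chronological order
  int nev = 0;
  for (int s = 0; s < 2 * m; ++s) nev += rec.evCount[s];
  IntegerVector exSp(nev), exMax(nev);
  NumericVector exT(nev), exV(nev);
  int pos = 0;
  for (int s = 0; s < 2 * m; ++s) {
    int cnt = rec.evCount[s];
    size_t base = (size_t) s * rec.ringCap;
    int start2 = (rec.evHead[s] - cnt + 2 * rec.ringCap) % rec.ringCap;
    for (int q = 0; q < cnt; ++q) {
      int idx = (start2 + q) % rec.ringCap;
      exSp[pos] = s / 2;
      exMax[pos] = (s % 2 == 0) ? 1 : 0;
      exT[pos] = rec.evT[base + idx];
      exV[pos] = rec.evV[base + idx];
      ++pos;
    }
  }
  List out = List::create(
    _["status"] = status, _["t"] = t, _["y"] = yout,
    _["steps"] = (double) steps, _["fevals"] = (double) fevals,
    _["extSpecies"] = exSp, _["extTime"] = exT,
    _["extValue"] = exV, _["extIsMax"] = exMax,
    _["ymin"] = wrap(rec.ymin), _["ymax"] = wrap(rec.ymax),
    _["bufT"] = bt, _["bufY"] = by);
  if (haveDense) out["dense"] = dense;
  return out;
}

// method: 0 = RK45 (Dormand-Prince), 1 = Rosenbrock 2(3)
// status: 0 reached tend, 1 max steps, 2 step failure
// [[Rcpp::export]]
List cppSimulate(NumericVector pack, NumericVector kpar, NumericVector theta,
                 NumericVector y0, double t0, double tend, double rtol,
                 double atol, int method, double maxSteps, double hInit,
                 int bufSize, int maxEvents, NumericVector tout) {
  Model mod = parsePack(pack);
  const int m = mod.m;
  const double* kp = kpar.begin();
  const double* th = (theta.size() > 0) ? theta.begin() : NULL;

  int ringCap = std::max(64, maxEvents / (2 * m));
  if (ringCap > 8192) ringCap = 8192;
  Recorder rec(m, ringCap, bufSize);
  std::vector<double> y(y0.begin(), y0.end());
  double t = t0;
  long steps = 0, fevals = 0;

  bool haveDense = tout.size() > 0;
  NumericMatrix dense(haveDense ? m : 0, haveDense ? tout.size() : 0);
  int denseIdx = 0;

  std::vector<double> f0(m), f1(m), ynew(m), err(m);
  std::vector<double> k2(m), k3(m), k4(m), k5(m), k6(m), tmp(m);

  evalRHS(mod, y.data(), kp, th, f0.data());
  ++fevals;
  rec.pushStep(t, y.data());

  double span = tend - t0;
  double h = hInit;
  if (!(h > 0)) {
    double ynorm = 0, fnorm = 0;
    for (int i = 0; i < m; ++i) {
      ynorm = std::max(ynorm, std::abs(y[i]));
      fnorm = std::max(fnorm, std::abs(f0[i]));
    }
    h = (fnorm > 0) ? 0.01 * std::max(ynorm, atol) / fnorm : span / 100.0;
    h = std::min(h, span / 10.0);
    if (!(h > 0) || !std::isfinite(h)) h = span / 1000.0;
  }
  double hmin = span * 1e-14;

  int status = 0;
  arma::mat Jw(m, m);

  while (t < tend) {
    if (steps >= (long) maxSteps) { status = 1; break; }
    if (h > tend - t) h = tend - t;
    bool accept = false;
    double errNorm = 1e10;   // failed evaluations count as large error

    if (method == 0) {
      // --- Dormand-Prince 5(4) ---
      for (int i = 0; i < m; ++i) tmp[i] = y[i] + h * a21 * f0[i];
      evalRHS(mod, tmp.data(), kp, th, k2.data());
      for (int i = 0; i < m; ++i)
        tmp[i] = y[i] + h * (a31 * f0[i] + a32 * k2[i]);
      evalRHS(mod, tmp.data(), kp, th, k3.data());
      for (int i = 0; i < m; ++i)
        tmp[i] = y[i] + h * (a41 * f0[i] + a42 * k2[i] + a43 * k3[i]);
      evalRHS(mod, tmp.data(), kp, th, k4.data());
      for (int i = 0; i < m; ++i)
        tmp[i] = y[i] + h * (a51 * f0[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
      evalRHS(mod, tmp.data(), kp, th, k5.data());
      for (int i = 0; i < m; ++i)
        tmp[i] = y[i] + h * (a61 * f0[i] + a62 * k2[i] + a63 * k3[i] +
                             a64 * k4[i] + a65 * k5[i]);
      evalRHS(mod, tmp.data(), kp, th, k6.data());
      for (int i = 0; i < m; ++i)
        ynew[i] = y[i] + h * (b1 * f0[i] + b3 * k3[i] + b4 * k4[i] +
                              b5 * k5[i] + b6 * k6[i]);
      evalRHS(mod, ynew.data(), kp, th, f1.data()); // FSAL
      fevals += 6;
      bool bad = false;
      for (int i = 0; i < m; ++i)
        if (!std::isfinite(ynew[i])) bad = true;
      if (!bad) {
        errNorm = 0.0;
        for (int i = 0; i < m; ++i) {
          double e = h * (e1 * f0[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                          e6 * k6[i] + e7 * f1[i]);
          double sc = atol + rtol * std::max(std::abs(y[i]), std::abs(ynew[i]));
          errNorm += (e / sc) * (e / sc);
        }
        errNorm = std::sqrt(errNorm / m);
        accept = (errNorm <= 1.0);
      }
      if (accept) {
        // extremum values come from the dense-output interpolant: this is
        // the same accuracy class as the solver's own continuous extension,
        // so the regular-oscillation test implicitly requires maxima smooth
        // enough for the interpolant to reproduce them (sub-step re-stepping
        // would be more precise but admits razor-sharp relaxation maxima the
        // detection rule is meant to treat conservatively)
        recordExtrema(mod, kp, th, rec, t, h, y.data(), ynew.data(), f0.data(),
                      f1.data(), false);
      }
      double fac = bad ? 0.2
                       : std::max(0.2, std::min(5.0, 0.9 * std::pow(
                             1.0 / std::max(errNorm, 1e-10), 0.2)));
      if (accept) {
        // dense output on the accepted step
        if (haveDense) {
          while (denseIdx < tout.size() && tout[denseIdx] <= t + h + 1e-14 * span) {
            double thx = (tout[denseIdx] - t) / h;
            if (thx < 0) thx = 0;
            if (thx > 1) thx = 1;
            for (int i = 0; i < m; ++i)
              dense(i, denseIdx) = hermiteValue(y[i], ynew[i], f0[i] * h,
                                                f1[i] * h, thx);
            ++denseIdx;
          }
        }
        t += h;
        y = ynew;
        f0 = f1;
        rec.pushStep(t, y.data());
        ++steps;
      }
      h *= fac;
    } else {
      // --- Rosenbrock 4(3), Kaps-Rentrop with Shampine's parameters,
      //     analytic Jacobian (L-stable; 3 RHS evaluations + 1 Jacobian
      //     factorisation + 4 back-solves per step) ---
      static const double GAM = 0.5, A21 = 2.0, A31 = 48.0 / 25,
                          A32 = 6.0 / 25, C21 = -8.0, C31 = 372.0 / 25,
                          C32 = 12.0 / 5, C41 = -112.0 / 125,
                          C42 = -54.0 / 125, C43 = -2.0 / 5, B1 = 19.0 / 9,
                          B2 = 0.5, B3 = 25.0 / 108, B4 = 125.0 / 108,
                          E1 = 17.0 / 54, E2 = 7.0 / 36, E3 = 0.0,
                          E4 = 125.0 / 108;
      evalJacInto(mod, y.data(), kp, th, Jw);
      // W = I/(gamma h) - J, factorised once per step (shared by all four
      // stage solves)
      double W[OSC_MAX_SPECIES * OSC_MAX_SPECIES];
      int piv[OSC_MAX_SPECIES];
      double dinv = 1.0 / (GAM * h);
      for (int c = 0; c < m; ++c)
        for (int r = 0; r < m; ++r)
          W[r * m + c] = (r == c ? dinv : 0.0) - Jw(r, c);
      bool finiteStages = luFactor(W, piv, m);
      double g1[OSC_MAX_SPECIES], g2[OSC_MAX_SPECIES], g3[OSC_MAX_SPECIES],
             g4[OSC_MAX_SPECIES], fs[OSC_MAX_SPECIES], rhsv[OSC_MAX_SPECIES];
      if (finiteStages) {
        for (int i = 0; i < m; ++i) g1[i] = f0[i];
        luSolve(W, piv, g1, m);
        for (int i = 0; i < m; ++i) {
          if (!std::isfinite(g1[i])) finiteStages = false;
          tmp[i] = y[i] + A21 * g1[i];
        }
      }
      if (finiteStages) {
        evalRHS(mod, tmp.data(), kp, th, fs);
        for (int i = 0; i < m; ++i) g2[i] = fs[i] + (C21 / h) * g1[i];
        luSolve(W, piv, g2, m);
        for (int i = 0; i < m; ++i) {
          if (!std::isfinite(g2[i])) finiteStages = false;
          tmp[i] = y[i] + A31 * g1[i] + A32 * g2[i];
        }
      }
      if (finiteStages) {
        evalRHS(mod, tmp.data(), kp, th, fs);
        for (int i = 0; i < m; ++i)
          rhsv[i] = fs[i] + (C31 * g1[i] + C32 * g2[i]) / h;
        for (int i = 0; i < m; ++i) g3[i] = rhsv[i];
        luSolve(W, piv, g3, m);
        for (int i = 0; i < m; ++i) {
          if (!std::isfinite(g3[i])) finiteStages = false;
          g4[i] = fs[i] + (C41 * g1[i] + C42 * g2[i] + C43 * g3[i]) / h;
        }
      }
      if (finiteStages) {
        luSolve(W, piv, g4, m);
        for (int i = 0; i < m; ++i)
          if (!std::isfinite(g4[i])) finiteStages = false;
        fevals += 2;
      }
      if (finiteStages) {
        bool bad = false;
        for (int i = 0; i < m; ++i) {
          ynew[i] = y[i] + B1 * g1[i] + B2 * g2[i] + B3 * g3[i] + B4 * g4[i];
          if (!std::isfinite(ynew[i])) bad = true;
        }
        if (!bad) {
          errNorm = 0.0;
          for (int i = 0; i < m; ++i) {
            double e = E1 * g1[i] + E2 * g2[i] + E3 * g3[i] + E4 * g4[i];
            double sc = atol + rtol * std::max(std::abs(y[i]),
                                               std::abs(ynew[i]));
            errNorm += (e / sc) * (e / sc);
          }
          errNorm = std::sqrt(errNorm / m);
          accept = (errNorm <= 1.0);
        }
      }
      if (accept) {
        evalRHS(mod, ynew.data(), kp, th, f1.data());
        ++fevals;
        recordExtrema(mod, kp, th, rec, t, h, y.data(), ynew.data(), f0.data(),
                      f1.data(), false);
        if (haveDense) {
          while (denseIdx < tout.size() && tout[denseIdx] <= t + h + 1e-14 * span) {
            double thx = (tout[denseIdx] - t) / h;
            if (thx < 0) thx = 0;
            if (thx > 1) thx = 1;
            for (int i = 0; i < m; ++i)
              dense(i, denseIdx) = hermiteValue(y[i], ynew[i], f0[i] * h,
                                                f1[i] * h, thx);
            ++denseIdx;
          }
        }
        t += h;
        y = ynew;
        f0 = f1;
        rec.pushStep(t, y.data());
        ++steps;
        h *= std::max(0.2, std::min(5.0, 0.9 * std::pow(
                 1.0 / std::max(errNorm, 1e-10), 0.25)));
      } else {
        double fac = finiteStages
                         ? std::max(0.1, 0.9 * std::pow(
                               1.0 / std::max(errNorm, 1e-10), 1.0 / 3.0))
                         : 0.2;
        h *= std::min(fac, 0.9);
        if (!std::isfinite(h)) break;
      }
    }

    if (h < hmin || !std::isfinite(h)) { status = 2; break; }
  }

  return finishSim(status, t, y, steps, fevals, rec, dense, haveDense);
}
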