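#include <Rcpp.h>
using namespace Rcpp;

// Multiplicative-regulation steady states.
//
// Node i satisfies  C_i = s_i * A_i(C)  with
//   A_i(C) = prod_{e:(j->i,+)} (1 + w_e h(u_j)) * prod_{e:(j->i,-)} 1/(1 + w_e h(u_j)),
//   h(u) = u / (K + u),
// where u_j is the effective upstream signal of source j: zero if j is
// (ligand- or receptor-)blocked, otherwise its concentration (zero for
// exogenous sources) plus any exogenous dose.  s_i is the unregulated
// steady level beta_i / delta_i for the active stimulus state.
//
// Solved by a safeguarded Newton iteration on F(C) = s*A(C) - C (the
// Jacobian is small and dense); any step that worsens the residual falls
// back to a damped fixed-point update, which is a contraction for the
// saturating regulation used here.  Nodes with a clamp value are held
// fixed (mediation analysis).

struct Problem {
  const NumericVector &s;
  const IntegerVector &esrc, &edst, &esign;
  const NumericVector &w;
  double K;
  const NumericVector &dose;
  const IntegerVector &blocked;
  const NumericVector &clamp;
  int n;
};

// target T(C) = s * A(C) (clamped nodes: T = clamp value);
// optionally exposes log A_i for the gradient kernel.
static void eval_target_logA(const Problem &pb, const std::vector<double> &C,
                             std::vector<double> &T,
                             std::vector<double> &logA) {
  int n = pb.n, E = pb.esrc.size();
  std::fill(logA.begin(), logA.end(), 0.0);
  for (int e = 0; e < E; ++e) {
    int j = pb.esrc[e] - 1, i = pb.edst[e] - 1;
    double u = 0.0;
    if (!pb.blocked[j]) {
      u = pb.dose[j];
      if (j < n) u += C[j];
    }
    double h = u / (pb.K + u);
    double t = log1p(pb.w[e] * h);
    logA[i] += (pb.esign[e] > 0) ? t : -t;
  }
  for (int i = 0; i < n; ++i)
    T[i] = R_IsNA(pb.clamp[i]) ? pb.s[i] * exp(logA[i]) : pb.clamp[i];
}

static void eval_target(const Problem &pb, const std::vector<double> &C,
                        std::vector<double> &T) {
  std::vector<double> logA(pb.n);
  eval_target_logA(pb, C, T, logA);
}

// Jacobian of T at C: J[i][j] = dT_i/dC_j
static void eval_jacobian(const Problem &pb, const std::vector<double> &C,
                          const std::vector<double> &T,
                          std::vector<double> &J) {
  int n = pb.n, E = pb.esrc.size();
  std::fill(J.begin(), J.end(), 0.0);
  for (int e = 0; e < E; ++e) {
    int j = pb.esrc[e] - 1, i = pb.edst[e] - 1;
    if (j >= n || pb.blocked[j] || !R_IsNA(pb.clamp[i])) continue;
    double u = pb.dose[j] + C[j];
    double h = u / (pb.K + u);
    double hp = pb.K / ((pb.K + u) * (pb.K + u));
    double g = pb.w[e] * hp / (1.0 + pb.w[e] * h);
    J[i * n + j] += (pb.esign[e] > 0) ? g : -g;
  }
  // chain rule: dT_i/dC_j = T_i * dlogA_i/dC_j
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) J[i * n + j] *= T[i];
}

static double residual_of(const Problem &pb, const std::vector<double> &C,
                          const std::vector<double> &T) {
  double res = 0.0;
  for (int i = 0; i < pb.n; ++i) {
    double d = fabs(T[i] - C[i]) / (1.0 + fabs(C[i]));
    if (d > res) res = d;
  }
  return res;
}

// Solve (I - J) x = b in place by Gaussian elimination with partial
// pivoting; returns false when singular.
static bool solve_linear(std::vector<double> A, std::vector<double> &x,
                         const std::vector<double> &b, int n) {
  std::vector<double> rhs(b);
  std::vector<int> piv(n);
  for (int i = 0; i < n; ++i) piv[i] = i;
  for (int col = 0; col < n; ++col) {
    int best = col;
    double bv = fabs(A[piv[col] * n + col]);
    for (int r = col + 1; r < n; ++r) {
      double v = fabs(A[piv[r] * n + col]);
      if (v > bv) { bv = v; best = r; }
    }
    if (bv < 1e-14) return false;
    std::swap(piv[col], piv[best]);
    double d = A[piv[col] * n + col];
    for (int r = col + 1; r < n; ++r) {
      double f = A[piv[r] * n + col] / d;
      if (f == 0.0) continue;
      for (int c2 = col; c2 < n; ++c2) A[piv[r] * n + c2] -= f * A[piv[col] * n + c2];
      rhs[piv[r]] -= f * rhs[piv[col]];
    }
  }
  x.assign(n, 0.0);
  for (int row = n - 1; row >= 0; --row) {
    double acc = rhs[piv[row]];
    for (int c2 = row + 1; c2 < n; ++c2) acc -= A[piv[row] * n + c2] * x[c2];
    x[row] = acc / A[piv[row] * n + row];
  }
  return true;
}

// Solve one condition; returns achieved residual.
static double solve_condition(std::vector<double> &C, const Problem &pb,
                              int maxit, double tol) {
  int n = pb.n;
  std::vector<double> T(n), J(n * n), A(n * n), step(n), rhs(n);
  for (int i = 0; i < n; ++i)
    C[i] = R_IsNA(pb.clamp[i]) ? pb.s[i] : pb.clamp[i];
  eval_target(pb, C, T);
  double res = residual_of(pb, C, T);
  double lam = 0.7, prev = R_PosInf;
  for (int it = 0; it < maxit && res >= tol; ++it) {
    bool stepped = false;
    if (it >= 1) {           // one damped warm-up step, then Newton
      eval_jacobian(pb, C, T, J);
      for (int i = 0; i < n; ++i) {
        for (int j = 0; j < n; ++j) A[i * n + j] = -J[i * n + j];
        A[i * n + i] += 1.0;
        rhs[i] = T[i] - C[i];
      }
      if (solve_linear(A, step, rhs, n)) {
        std::vector<double> Cn(n), Tn(n);
        double sc = 1.0;
        for (int tries = 0; tries < 4; ++tries, sc *= 0.5) {
          bool ok = true;
          for (int i = 0; i < n; ++i) {
            Cn[i] = C[i] + sc * step[i];
            if (Cn[i] < 0.0) Cn[i] = C[i] * 0.1;
            if (!R_finite(Cn[i])) { ok = false; break; }
          }
          if (!ok) continue;
          eval_target(pb, Cn, Tn);
          double rn = residual_of(pb, Cn, Tn);
          if (rn < res) {
            C.swap(Cn); T.swap(Tn); res = rn; stepped = true;
            break;
          }
        }
      }
    }
    if (!stepped) {          // damped fixed-point fallback
      if (res > prev) lam = std::max(lam * 0.5, 0.05);
      else lam = std::min(lam * 1.05, 0.9);
      prev = res;
      for (int i = 0; i < n; ++i)
        if (R_IsNA(pb.clamp[i])) C[i] = (1.0 - lam) * C[i] + lam * T[i];
      eval_target(pb, C, T);
      res = residual_of(pb, C, T);
    }
  }
  return res;
}

// [[Rcpp::export(name = ".ss_solve_cpp")]]
List ss_solve_cpp(NumericMatrix s,          // n x ncond basal steady levels
                  IntegerVector esrc,       // E, 1-based source (over sources)
                  IntegerVector edst,       // E, 1-based target (over nodes)
                  IntegerVector esign,      // E, +1 / -1
                  NumericVector w,          // E
                  double K,
                  NumericMatrix dose,       // m x ncond (sources)
                  IntegerMatrix blocked,    // m x ncond
                  NumericMatrix clamp,      // n x ncond, NA = free
                  int maxit = 2000, double tol = 1e-10) {
  int n = s.nrow(), nc = s.ncol();
  NumericMatrix C(n, nc);
  NumericVector resid(nc);
  LogicalVector conv(nc);
  std::vector<double> Cc(n);
  for (int c = 0; c < nc; ++c) {
    NumericVector sc = s(_, c), dc = dose(_, c), cc = clamp(_, c);
    IntegerVector bc = blocked(_, c);
    Problem pb{sc, esrc, edst, esign, w, K, dc, bc, cc, n};
    double r = solve_condition(Cc, pb, maxit, tol);
    resid[c] = r;
    conv[c] = (r < tol);
    for (int i = 0; i < n; ++i) C(i, c) = Cc[i];
  }
  return List::create(_["C"] = C, _["converged"] = conv, _["residual"] = resid);
}

// Objective kernel: RSS of log10(C + eps) against observed log10 values.
// Non-converged conditions add a large penalty so the optimizer retreats.
// [[Rcpp::export(name = ".ss_rss_cpp")]]
double ss_rss_cpp(NumericMatrix s,
                  IntegerVector esrc, IntegerVector edst, IntegerVector esign,
                  NumericVector w, double K,
                  NumericMatrix dose, IntegerMatrix blocked, NumericMatrix clamp,
                  NumericMatrix obslog,   // n x ncond, NA skipped
                  double eps,
                  int maxit = 2000, double tol = 1e-10) {
  int n = s.nrow(), nc = s.ncol();
  double rss = 0.0;
  std::vector<double> Cc(n);
  for (int c = 0; c < nc; ++c) {
    NumericVector sc = s(_, c), dc = dose(_, c), cl = clamp(_, c);
    IntegerVector bc = blocked(_, c);
    Problem pb{sc, esrc, edst, esign, w, K, dc, bc, cl, n};
    double r = solve_condition(Cc, pb, maxit, tol);
    if (!(r < tol)) rss += 1e6 * (1.0 + r);
    for (int i = 0; i < n; ++i) {
      double o = obslog(i, c);
      if (R_IsNA(o)) continue;
      double d = log10(Cc[i] + eps) - o;
      rss += d * d;
    }
  }
  return rss;
}

// Fixed-step RK4 endpoint integration of the production ODE, used by the
// timecourse fitting objective (the user-facing simulator integrates with
// adaptive stepping; at the step sizes used here the discretisation error
// is far below the fit tolerance).  beta is the production rate matrix
// (n x ncond), C0 the initial state (added doses on their nodes).
static void tc_rhs(const Problem &pb, const NumericVector &delta,
                   const std::vector<double> &C, std::vector<double> &dC) {
  int n = pb.n;
  std::vector<double> T(n), logA(n);
  eval_target_logA(pb, C, T, logA);
  for (int i = 0; i < n; ++i) {
    if (!R_IsNA(pb.clamp[i])) { dC[i] = 0.0; continue; }
    // pb.s carries beta here, so the "target" already is beta * A
    dC[i] = T[i] - delta[i] * C[i];
  }
}

// [[Rcpp::export(name = ".tc_rss_cpp")]]
double tc_rss_cpp(NumericMatrix beta,        // n x ncond production rates
                  NumericVector delta,       // n decay rates
                  IntegerVector esrc, IntegerVector edst, IntegerVector esign,
                  NumericVector w, double K,
                  NumericMatrix dose, IntegerMatrix blocked, NumericMatrix clamp,
                  NumericMatrix C0,          // n x ncond initial state
                  double Tend, double h,
                  NumericMatrix obslog, double eps) {
  int n = beta.nrow(), nc = beta.ncol();
  int nstep = (int) ceil(Tend / h);
  double dt = Tend / nstep;
  double rss = 0.0;
  std::vector<double> C(n), k1(n), k2(n), k3(n), k4(n), tmp(n);
  for (int c = 0; c < nc; ++c) {
    NumericVector bc_ = beta(_, c), dc = dose(_, c), cl = clamp(_, c);
    IntegerVector bl = blocked(_, c);
    Problem pb{bc_, esrc, edst, esign, w, K, dc, bl, cl, n};
    for (int i = 0; i < n; ++i)
      C[i] = R_IsNA(cl[i]) ? C0(i, c) : cl[i];
    for (int s = 0; s < nstep; ++s) {
      tc_rhs(pb, delta, C, k1);
      for (int i = 0; i < n; ++i) tmp[i] = C[i] + 0.5 * dt * k1[i];
      tc_rhs(pb, delta, tmp, k2);
      for (int i = 0; i < n; ++i) tmp[i] = C[i] + 0.5 * dt * k2[i];
      tc_rhs(pb, delta, tmp, k3);
      for (int i = 0; i < n; ++i) tmp[i] = C[i] + dt * k3[i];
      tc_rhs(pb, delta, tmp, k4);
      for (int i = 0; i < n; ++i) {
        C[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
        if (C[i] < 0.0) C[i] = 0.0;
      }
    }
    for (int i = 0; i < n; ++i) {
      double o = obslog(i, c);
      if (R_IsNA(o)) continue;
      double d = log10(C[i] + eps) - o;
      rss += d * d;
    }
  }
  return rss;
}

// RSS plus its analytic gradient by the adjoint (implicit-function)
// method: at the fixed point C = T(C, p),  dC/dp = (I - J)^{-1} dT/dp,
// so with lambda solving (I - J)^T lambda = dRSS/dC the parameter
// gradients are lambda^T dT/dp.  Returns gradients with respect to the
// natural-scale basal levels s (per node and condition), edge strengths
// w and half-saturation K.  Unconverged conditions contribute only the
// value penalty (zero gradient), pushing the optimizer elsewhere.
// [[Rcpp::export(name = ".ss_rss_grad_cpp")]]
List ss_rss_grad_cpp(NumericMatrix s,
                     IntegerVector esrc, IntegerVector edst, IntegerVector esign,
                     NumericVector w, double K,
                     NumericMatrix dose, IntegerMatrix blocked, NumericMatrix clamp,
                     NumericMatrix obslog, double eps,
                     int maxit = 2000, double tol = 1e-10) {
  const double LN10 = 2.302585092994045684;
  int n = s.nrow(), nc = s.ncol(), E = esrc.size();
  double rss = 0.0;
  NumericMatrix g_s(n, nc);
  NumericVector g_w(E);
  double g_K = 0.0;
  std::vector<double> Cc(n), T(n), logA(n), J(n * n), A(n * n),
      b(n), lam(n);
  for (int c = 0; c < nc; ++c) {
    NumericVector sc = s(_, c), dc = dose(_, c), cl = clamp(_, c);
    IntegerVector bc = blocked(_, c);
    Problem pb{sc, esrc, edst, esign, w, K, dc, bc, cl, n};
    double r = solve_condition(Cc, pb, maxit, tol);
    if (!(r < tol)) { rss += 1e6 * (1.0 + r); continue; }
    eval_target_logA(pb, Cc, T, logA);
    bool any_obs = false;
    for (int i = 0; i < n; ++i) {
      double o = obslog(i, c);
      if (R_IsNA(o)) { b[i] = 0.0; continue; }
      double d = log10(Cc[i] + eps) - o;
      rss += d * d;
      b[i] = 2.0 * d / ((Cc[i] + eps) * LN10);
      any_obs = true;
    }
    if (!any_obs) continue;
    eval_jacobian(pb, Cc, T, J);
    // (I - J)^T lambda = b
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        A[i * n + j] = (i == j ? 1.0 : 0.0) - J[j * n + i];
    if (!solve_linear(A, lam, b, n)) continue;
    for (int i = 0; i < n; ++i)
      if (R_IsNA(pb.clamp[i])) g_s(i, c) += lam[i] * exp(logA[i]);
    for (int e = 0; e < E; ++e) {
      int j = esrc[e] - 1, i = edst[e] - 1;
      if (!R_IsNA(pb.clamp[i])) continue;
      double u = 0.0;
      if (!bc[j]) {
        u = dc[j];
        if (j < n) u += Cc[j];
      }
      double h = u / (K + u);
      double denom = 1.0 + w[e] * h;
      double sgn = (esign[e] > 0) ? 1.0 : -1.0;
      g_w[e] += lam[i] * T[i] * sgn * h / denom;
      // dh/dK = -u / (K + u)^2
      g_K += lam[i] * T[i] * sgn * w[e] * (-u / ((K + u) * (K + u))) / denom;
    }
  }
  return List::create(_["value"] = rss, _["g_s"] = g_s, _["g_w"] = g_w,
                      _["g_K"] = g_K);
}
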