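#include <Rcpp.h>
using namespace Rcpp;

// Bilinear neural model with balloon-type hemodynamics, integrated by RK4 on a
// fixed microtime grid. States per region: x (neural), s (vasodilatory signal),
// f (inflow), v (blood volume), q (deoxyhemoglobin). The leading diagonals of A
// and of each B slice are log-scale self-connection parameters: the effective
// self-coupling under input u is -0.5 * exp(a_ii + sum_j u_j * b_jii).

struct HemoPars {
  double kappa, gamma, tau, alpha, rho, V0;
};

static inline void derivs(const double *st, double *d, int n,
                          const double *J, const double *drive,
                          const HemoPars &hp) {
  // st layout: [x(n), s(n), f(n), v(n), q(n)]
  const double *x = st, *s = st + n, *f = st + 2 * n, *v = st + 3 * n,
               *q = st + 4 * n;
  double ooa = 1.0 / hp.alpha;
  for (int i = 0; i < n; ++i) {
    double xi = 0.0;
    for (int j = 0; j < n; ++j) xi += J[i + n * j] * x[j];
    d[i] = xi + drive[i];
    d[n + i] = x[i] - hp.kappa * s[i] - hp.gamma * (f[i] - 1.0);
    d[2 * n + i] = s[i];
    double fv = std::pow(v[i], ooa);
    d[3 * n + i] = (f[i] - fv) / hp.tau;
    double E = 1.0 - std::pow(1.0 - hp.rho, 1.0 / f[i]);
    d[4 * n + i] = (f[i] * E / hp.rho - fv * q[i] / v[i]) / hp.tau;
  }
}

// [[Rcpp::export]]
List cpp_dcm_simulate(NumericMatrix A, NumericVector Bcube, NumericMatrix C,
                      NumericMatrix U, double dt, NumericVector hemo,
                      IntegerVector sample_idx, bool return_states,
                      int stages = 4, int substeps = 1) {
  int n = A.nrow();
  int m = U.nrow();
  int T = U.ncol();
  if (C.nrow() != n || C.ncol() != m)
    stop("C must be regions x inputs");
  IntegerVector bd = Bcube.attr("dim");
  if (bd.size() != 3 || bd[0] != n || bd[1] != n || bd[2] != m)
    stop("B must be an n x n x m array");
  HemoPars hp = {hemo[0], hemo[1], hemo[2], hemo[3], hemo[4], hemo[5]};

  int ns = 5 * n;
  std::vector<double> st(ns, 0.0), k1(ns), k2(ns), k3(ns), k4(ns), tmp(ns);
  for (int i = 0; i < n; ++i) {
    st[2 * n + i] = 1.0; // f
    st[3 * n + i] = 1.0; // v
    st[4 * n + i] = 1.0; // q
  }

  std::vector<double> J(n * n), drive(n);
  int nvol = sample_idx.size();
  NumericMatrix Y(nvol, n);
  NumericMatrix X; // neural states at sampled volumes
  if (return_states) X = NumericMatrix(nvol, n);

  double k1c = 7.0 * hp.rho, k2c = 2.0, k3c = 2.0 * hp.rho - 0.2;
  int isamp = 0;

  // record state at time 0 if requested (sample index 1)
  for (int t = 0; t < T; ++t) {
    if (isamp < nvol && sample_idx[isamp] == t + 1) {
      for (int i = 0; i < n; ++i) {
        double v = st[3 * n + i], q = st[4 * n + i];
        Y(isamp, i) = 100.0 * hp.V0 *
          (k1c * (1.0 - q) + k2c * (1.0 - q / v) + k3c * (1.0 - v));
        if (return_states) X(isamp, i) = st[i];
      }
      ++isamp;
    }
    if (t == T - 1) break;
    // inputs held constant over bin t
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) {
        if (i == j) continue;
        double a = A(i, j);
        for (int u = 0; u < m; ++u)
          a += U(u, t) * Bcube[i + n * j + n * n * u];
        J[i + n * j] = a;
      }
      double ad = A(i, i);
      for (int u = 0; u < m; ++u) ad += U(u, t) * Bcube[i + n * i + n * n * u];
      J[i + n * i] = -0.5 * std::exp(ad);
      double dr = 0.0;
      for (int u = 0; u < m; ++u) dr += C(i, u) * U(u, t);
      drive[i] = dr;
    }
    double h = dt / substeps;
    for (int sub = 0; sub < substeps; ++sub) {
      if (stages == 4) {
        derivs(st.data(), k1.data(), n, J.data(), drive.data(), hp);
        for (int i = 0; i < ns; ++i) tmp[i] = st[i] + 0.5 * h * k1[i];
        derivs(tmp.data(), k2.data(), n, J.data(), drive.data(), hp);
        for (int i = 0; i < ns; ++i) tmp[i] = st[i] + 0.5 * h * k2[i];
        derivs(tmp.data(), k3.data(), n, J.data(), drive.data(), hp);
        for (int i = 0; i < ns; ++i) tmp[i] = st[i] + h * k3[i];
        derivs(tmp.data(), k4.data(), n, J.data(), drive.data(), hp);
        for (int i = 0; i < ns; ++i)
          st[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      } else { // Heun's method
        derivs(st.data(), k1.data(), n, J.data(), drive.data(), hp);
        for (int i = 0; i < ns; ++i) tmp[i] = st[i] + h * k1[i];
        derivs(tmp.data(), k2.data(), n, J.data(), drive.data(), hp);
        for (int i = 0; i < ns; ++i)
          st[i] += 0.5 * h * (k1[i] + k2[i]);
      }
    }
    for (int i = 0; i < ns; ++i) {
      if (!std::isfinite(st[i]))
        stop("dcm simulation diverged (non-finite states); "
             "check stability of the connectivity parameters");
    }
    for (int i = 0; i < n; ++i) {
      if (std::fabs(st[i]) > 1e6 || st[3 * n + i] <= 0.0 ||
          st[4 * n + i] <= 0.0)
        stop("dcm simulation diverged (non-physical states); "
             "check stability of the connectivity parameters");
    }
  }
  if (return_states) return List::create(_["bold"] = Y, _["neural"] = X);
  return List::create(_["bold"] = Y);
}
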