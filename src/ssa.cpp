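#include <Rcpp.h>
using namespace Rcpp;

// Gillespie direct method over the package's parametric propensity forms.
// kind: 0 const, 1 linear (coef*y[i1]), 2 bilinear (coef*y[i1]*y[i2]),
//       3 hill (b0 + b*y[i1]^n/(y[i1]^n + K^n)).
// Input dependence is folded into coef / hill constants by the R wrapper
// (the step amplitude is constant for t >= 0).

static inline double pow_fast(double y, double n) {
  if (n == 1.0) return y;
  if (n == 1.5) return y * std::sqrt(y);
  if (n == 2.0) return y * y;
  if (n == 3.0) return y * y * y;
  return std::pow(y, n);
}

static inline double prop(int kind, double coef, int i1, int i2,
                          double b0, double b, double n, double Kn,
                          const std::vector<double>& y) {
  switch (kind) {
  case 0: return coef;
  case 1: return coef * y[i1];
  case 2: return coef * y[i1] * y[i2];
  case 3: {
    double yv = y[i1];
    if (yv <= 0.0) return b0;
    double yn = pow_fast(yv, n);
    return b0 + b * yn / (yn + Kn);
  }
  }
  return 0.0;
}

// [[Rcpp::export]]
List ssa_run_cpp(IntegerMatrix nu, IntegerVector kind, NumericVector coef,
                 IntegerVector i1, IntegerVector i2, NumericVector hb0,
                 NumericVector hb, NumericVector hn, NumericVector hK,
                 IntegerVector init, NumericVector rec_times, int n_runs) {
  const int M = nu.nrow(), N = nu.ncol(), T = rec_times.size();
  NumericVector out(static_cast<R_xlen_t>(n_runs) * T * N);
  out.attr("dim") = IntegerVector::create(n_runs, T, N);
  NumericVector jumps(n_runs);
  std::vector<double> a(M), hKn(M);
  for (int j = 0; j < M; ++j) {
    hKn[j] = (kind[j] == 3) ? std::pow(hK[j], hn[j]) : 0.0;
  }

  for (int run = 0; run < n_runs; ++run) {
    std::vector<double> y(N);
    for (int k = 0; k < N; ++k) y[k] = init[k];
    double t = 0.0;
    long long njump = 0;
    int ti = 0;

    while (ti < T) {
      double a0 = 0.0;
      for (int j = 0; j < M; ++j) {
        a[j] = prop(kind[j], coef[j], i1[j], i2[j], hb0[j], hb[j], hn[j],
                    hKn[j], y);
        if (!(a[j] >= 0.0) || !R_finite(a[j]))
          stop("invalid propensity encountered in reaction %d", j + 1);
        a0 += a[j];
      }
      double tnext;
      if (a0 <= 0.0) {
        tnext = R_PosInf;
      } else {
        tnext = t + ::Rf_rexp(1.0 / a0);
      }
      // record every passed output time before taking the jump
      while (ti < T && rec_times[ti] <= tnext) {
        for (int k = 0; k < N; ++k)
          out[run + static_cast<R_xlen_t>(n_runs) * (ti + T * k)] = y[k];
        ++ti;
      }
      if (ti >= T) break;
      if (!R_finite(tnext)) break;
      t = tnext;
      double u = ::unif_rand() * a0;
      double cum = 0.0;
      int j = 0;
      for (; j < M; ++j) {
        cum += a[j];
        if (u <= cum) break;
      }
      if (j >= M) j = M - 1;
      for (int k = 0; k < N; ++k) {
        y[k] += nu(j, k);
        if (y[k] < 0) stop("negative copy number reached; invalid network");
      }
      ++njump;
    }
    jumps[run] = static_cast<double>(njump);
  }
  return List::create(_["states"] = out, _["jumps"] = jumps);
}

// Affine-closure moment equations: state = (z, vech(C)) with vech the
// column-major lower triangle including the diagonal. Propensities and
// their exact gradients are evaluated at the (clipped non-negative) mean.

// [[Rcpp::export]]
NumericVector moment_rhs_cpp(NumericVector state, IntegerMatrix nu,
                             IntegerVector kind, NumericVector coef,
                             IntegerVector i1, IntegerVector i2,
                             NumericVector hb0, NumericVector hb,
                             NumericVector hn, NumericVector hK) {
  const int M = nu.nrow(), N = nu.ncol();
  std::vector<double> z(N), C(N * N, 0.0);
  for (int k = 0; k < N; ++k) {
    z[k] = state[k];
    if (z[k] < 0.0) z[k] = 0.0;
  }
  {
    int idx = N;
    for (int j = 0; j < N; ++j)
      for (int i = j; i < N; ++i) {
        C[i + N * j] = state[idx];
        C[j + N * i] = state[idx];
        ++idx;
      }
  }
  // expected propensities under a normal closure: E[a(y)] is evaluated
  // as a(z) + 0.5 * tr(H C), which is exact for constant, linear and
  // bilinear forms and a curvature correction for the Hill term
  std::vector<double> a(M), J(M * N, 0.0);
  for (int j = 0; j < M; ++j) {
    switch (kind[j]) {
    case 0:
      a[j] = coef[j];
      break;
    case 1:
      a[j] = coef[j] * z[i1[j]];
      J[j + M * i1[j]] = coef[j];
      break;
    case 2:
      a[j] = coef[j] * (z[i1[j]] * z[i2[j]] + C[i1[j] + N * i2[j]]);
      J[j + M * i1[j]] += coef[j] * z[i2[j]];
      J[j + M * i2[j]] += coef[j] * z[i1[j]];
      break;
    case 3: {
      double yv = z[i1[j]];
      if (yv <= 0.0) {
        a[j] = hb0[j];
        J[j + M * i1[j]] = (hn[j] == 1.0) ? hb[j] / hK[j] : 0.0;
      } else {
        double n = hn[j];
        double yn = std::pow(yv, n);
        double Kn = std::pow(hK[j], n);
        double den = yn + Kn;
        a[j] = hb0[j] + hb[j] * yn / den;
        J[j + M * i1[j]] =
          hb[j] * n * Kn * std::pow(yv, n - 1.0) / (den * den);
        double d2 = hb[j] * n * Kn * std::pow(yv, n - 2.0) *
          ((n - 1.0) * den - 2.0 * n * yn) / (den * den * den);
        a[j] += 0.5 * d2 * C[i1[j] + N * i1[j]];
      }
      break;
    }
    }
    if (a[j] < 0.0) a[j] = 0.0;
  }
  // A = nu' J, B = nu' diag(a) nu, dz = nu' a
  std::vector<double> A(N * N, 0.0), B(N * N, 0.0), dz(N, 0.0);
  for (int j = 0; j < M; ++j) {
    for (int p = 0; p < N; ++p) {
      double nujp = nu(j, p);
      if (nujp == 0.0) continue;
      dz[p] += nujp * a[j];
      for (int k = 0; k < N; ++k) A[p + N * k] += nujp * J[j + M * k];
      for (int q = 0; q < N; ++q) B[p + N * q] += nujp * a[j] * nu(j, q);
    }
  }
  // dC = A C + C A' + B
  std::vector<double> AC(N * N, 0.0);
  for (int p = 0; p < N; ++p)
    for (int r = 0; r < N; ++r) {
      double apr = A[p + N * r];
      if (apr == 0.0) continue;
      for (int q = 0; q < N; ++q) AC[p + N * q] += apr * C[r + N * q];
    }
  NumericVector out(state.size());
  for (int k = 0; k < N; ++k) out[k] = dz[k];
  int idx = N;
  for (int j = 0; j < N; ++j)
    for (int i = j; i < N; ++i) {
      out[idx++] = AC[i + N * j] + AC[j + N * i] + B[i + N * j];
    }
  return out;
}
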