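#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for L1-penalized linear and logistic
// regression with covariance (Gram-matrix) updating, so each coordinate
// update costs O(p) after an O(n p^2) precomputation.
// Objective (gaussian): (1/2n) * ||y - b0 - X beta||^2 + lambda * ||beta||_1
// Objective (logistic): -(1/n) * loglik + lambda * ||beta||_1
// Predictors arrive pre-standardized (continuous) or 0/1 (binary); the
// intercept is never penalized. Paths are solved from the largest lambda
// down with warm starts.

inline double soft_threshold(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// [[Rcpp::export]]
List cd_gaussian_path(NumericMatrix X, NumericVector y, NumericVector lambdas,
                      double tol, int max_iter) {
  int n = X.nrow(), p = X.ncol(), nlam = lambdas.size();
  NumericMatrix beta_path(p, nlam);
  NumericVector b0_path(nlam);
  IntegerVector iters(nlam);
  LogicalVector converged(nlam);

  // center predictors and response; the intercept is recovered afterwards
  std::vector<double> xm(p, 0.0);
  double ym = 0.0;
  for (int i = 0; i < n; ++i) ym += y[i];
  ym /= n;
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j);
    xm[j] = s / n;
  }
  // Gram matrix G = Xc'Xc / n and c = Xc'yc / n
  std::vector<double> G(p * p, 0.0), c(p, 0.0);
  for (int j = 0; j < p; ++j) {
    for (int k = j; k < p; ++k) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += (X(i, j) - xm[j]) * (X(i, k) - xm[k]);
      G[j * p + k] = G[k * p + j] = s / n;
    }
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += (X(i, j) - xm[j]) * (y[i] - ym);
    c[j] = s / n;
  }

  std::vector<double> beta(p, 0.0);
  for (int l = 0; l < nlam; ++l) {
    double lam = lambdas[l];
    int it = 0;
    bool ok = false;
    for (it = 0; it < max_iter; ++it) {
      double max_delta = 0.0;
      for (int j = 0; j < p; ++j) {
        double gjj = G[j * p + j];
        if (gjj <= 0) { beta[j] = 0.0; continue; }
        double z = c[j];
        const double *Gj = &G[j * p];
        for (int k = 0; k < p; ++k) if (k != j && beta[k] != 0.0) z -= Gj[k] * beta[k];
        double bnew = soft_threshold(z, lam) / gjj;
        double d = std::fabs(bnew - beta[j]);
        beta[j] = bnew;
        if (d > max_delta) max_delta = d;
      }
      if (max_delta < tol) { ok = true; ++it; break; }
    }
    double b0 = ym;
    for (int j = 0; j < p; ++j) {
      beta_path(j, l) = beta[j];
      b0 -= beta[j] * xm[j];
    }
    b0_path[l] = b0;
    iters[l] = it;
    converged[l] = ok;
  }
  return List::create(_["beta"] = beta_path, _["b0"] = b0_path,
                      _["iterations"] = iters, _["converged"] = converged);
}

// [[Rcpp::export]]
List cd_logistic_path(NumericMatrix X, NumericVector y, NumericVector lambdas,
                      double tol, int max_iter) {
  int n = X.nrow(), p = X.ncol(), nlam = lambdas.size();
  NumericMatrix beta_path(p, nlam);
  NumericVector b0_path(nlam);
  IntegerVector iters(nlam);
  LogicalVector converged(nlam);

  std::vector<double> beta(p, 0.0);
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  // guard against perfectly separated / constant responses
  double pb = std::min(std::max(ybar, 1e-8), 1.0 - 1e-8);
  double b0 = std::log(pb / (1.0 - pb));

  std::vector<double> eta(n, b0), w(n), u(n);
  // weighted Gram over (intercept, X): (p+1) x (p+1)
  int q = p + 1;
  std::vector<double> Gw(q * q), cw(q);

  for (int l = 0; l < nlam; ++l) {
    double lam = lambdas[l];
    int outer = 0;
    bool ok = false;
    for (outer = 0; outer < max_iter; ++outer) {
      // IRLS working weights and residuals at the current estimate
      for (int i = 0; i < n; ++i) {
        double m = 1.0 / (1.0 + std::exp(-eta[i]));
        double wi = m * (1.0 - m);
        if (wi < 1e-6) wi = 1e-6;
        w[i] = wi;
        u[i] = y[i] - m;
      }
      // weighted Gram: Gw[a][b] = sum w * xa * xb / n (x0 = 1),
      // cw[a] = sum xa * (w * eta + u) / n
      for (int a = 0; a < q; ++a) {
        for (int b = a; b < q; ++b) {
          double s = 0.0;
          if (a == 0 && b == 0) {
            for (int i = 0; i < n; ++i) s += w[i];
          } else if (a == 0) {
            for (int i = 0; i < n; ++i) s += w[i] * X(i, b - 1);
          } else {
            for (int i = 0; i < n; ++i) s += w[i] * X(i, a - 1) * X(i, b - 1);
          }
          Gw[a * q + b] = Gw[b * q + a] = s / n;
        }
        double s = 0.0;
        if (a == 0) {
          for (int i = 0; i < n; ++i) s += w[i] * eta[i] + u[i];
        } else {
          for (int i = 0; i < n; ++i) s += X(i, a - 1) * (w[i] * eta[i] + u[i]);
        }
        cw[a] = s / n;
      }
      // inner penalized weighted least squares by coordinate descent
      std::vector<double> bold(p);
      double b0_old = b0;
      for (int j = 0; j < p; ++j) bold[j] = beta[j];
      for (int inner = 0; inner < max_iter; ++inner) {
        double max_delta = 0.0;
        // intercept (unpenalized)
        {
          double z = cw[0];
          for (int k = 0; k < p; ++k) if (beta[k] != 0.0) z -= Gw[k + 1] * beta[k];
          double bnew = z / Gw[0];
          double d = std::fabs(bnew - b0);
          b0 = bnew;
          if (d > max_delta) max_delta = d;
        }
        for (int j = 0; j < p; ++j) {
          int a = j + 1;
          double gjj = Gw[a * q + a];
          if (gjj <= 0) { beta[j] = 0.0; continue; }
          double z = cw[a] - Gw[a * q] * b0;
          const double *Ga = &Gw[a * q];
          for (int k = 0; k < p; ++k)
            if (k != j && beta[k] != 0.0) z -= Ga[k + 1] * beta[k];
          double bnew = soft_threshold(z, lam) / gjj;
          double d = std::fabs(bnew - beta[j]);
          beta[j] = bnew;
          if (d > max_delta) max_delta = d;
        }
        if (max_delta < tol) break;
      }
      // refresh the linear predictor and check outer convergence
      double outer_delta = std::fabs(b0 - b0_old);
      for (int j = 0; j < p; ++j) {
        double d = std::fabs(beta[j] - bold[j]);
        if (d > outer_delta) outer_delta = d;
      }
      for (int i = 0; i < n; ++i) {
        double e = b0;
        for (int j = 0; j < p; ++j) if (beta[j] != 0.0) e += X(i, j) * beta[j];
        eta[i] = e;
      }
      if (outer_delta < tol) { ok = true; ++outer; break; }
    }
    for (int j = 0; j < p; ++j) beta_path(j, l) = beta[j];
    b0_path[l] = b0;
    iters[l] = outer;
    converged[l] = ok;
  }
  return List::create(_["beta"] = beta_path, _["b0"] = b0_path,
                      _["iterations"] = iters, _["converged"] = converged);
}
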