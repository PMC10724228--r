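#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L2-regularized L1-hinge SVM without
// intercept:  min_w 0.5*||w||^2 + C * sum_i max(0, 1 - y_i * w.z_i).
// Standard dual CD with per-sweep shuffling and active-set shrinking; the
// shuffle uses an internal fixed-seed xorshift generator, so the solver is
// fully deterministic for given inputs. Stops when the projected-gradient
// spread over a full (unshrunk) sweep drops below tol.

static inline uint32_t xorshift32(uint32_t &s) {
  s ^= s << 13;
  s ^= s >> 17;
  s ^= s << 5;
  return s;
}

// [[Rcpp::export]]
List svm_dual_cd(NumericMatrix Z, NumericVector y, double C,
                 double tol = 1e-4, int max_sweeps = 100000) {
  const int m = Z.nrow();
  const int d = Z.ncol();
  std::vector<double> w(d, 0.0), alpha(m, 0.0), qii(m);
  std::vector<int> idx(m);
  uint32_t rng = 88172645u;

  for (int i = 0; i < m; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += Z(i, j) * Z(i, j);
    qii[i] = s;
    idx[i] = i;
  }

  int active = m;
  double pg_max_old = R_PosInf, pg_min_old = R_NegInf;
  bool converged = false;
  double spread = R_PosInf;
  int sweep = 0;

  while (sweep < max_sweeps) {
    ++sweep;
    double pg_max = R_NegInf, pg_min = R_PosInf;
    for (int s = 0; s < active; ++s) {
      int r = s + (int)(xorshift32(rng) % (uint32_t)(active - s));
      std::swap(idx[s], idx[r]);
      int i = idx[s];
      if (qii[i] <= 0.0) continue;  // zero difference vector: no signal
      double g = 0.0;
      for (int j = 0; j < d; ++j) g += w[j] * Z(i, j);
      g = y[i] * g - 1.0;
      double pg = g;
      if (alpha[i] == 0.0) {
        if (g > pg_max_old) {  // shrink: move out of the active range
          std::swap(idx[s], idx[--active]);
          --s;
          continue;
        }
        if (g > 0.0) pg = 0.0;
      } else if (alpha[i] == C) {
        if (g < pg_min_old) {
          std::swap(idx[s], idx[--active]);
          --s;
          continue;
        }
        if (g < 0.0) pg = 0.0;
      }
      if (pg > pg_max) pg_max = pg;
      if (pg < pg_min) pg_min = pg;
      if (pg != 0.0) {
        double old = alpha[i];
        double a = old - g / qii[i];
        if (a < 0.0) a = 0.0;
        if (a > C) a = C;
        alpha[i] = a;
        double delta = (a - old) * y[i];
        if (delta != 0.0) {
          for (int j = 0; j < d; ++j) w[j] += delta * Z(i, j);
        }
      }
    }
    if (pg_max == R_NegInf) { pg_max = 0.0; pg_min = 0.0; }
    spread = pg_max - pg_min;
    if (spread < tol) {
      if (active == m) {
        converged = true;
        break;
      }
      active = m;  // re-examine shrunk coordinates before declaring victory
      pg_max_old = R_PosInf;
      pg_min_old = R_NegInf;
      continue;
    }
    pg_max_old = pg_max <= 0.0 ? R_PosInf : pg_max;
    pg_min_old = pg_min >= 0.0 ? R_NegInf : pg_min;
  }

  double obj = 0.0;
  for (int j = 0; j < d; ++j) obj += 0.5 * w[j] * w[j];
  for (int i = 0; i < m; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += w[j] * Z(i, j);
    double xi = 1.0 - y[i] * s;
    if (xi > 0.0) obj += C * xi;
  }

  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["objective"] = obj,
                      _["sweeps"] = sweep,
                      _["converged"] = converged,
                      _["max_violation"] = spread);
}
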