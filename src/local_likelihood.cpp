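#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Weighted local log posterior in s for one focal cell:
//   sum_i w_i [ y_i log(a_i s) + (1 - y_i) log(1 - a_i s) ]
//   - (s - prior_mean)^2 / (2 prior_sd^2)
// with a_i = m_i * d_i fixed. Truncation constants of the prior drop out.
// The detection terms contribute (sum w_i y_i) * (1/s) to the derivative
// (d/ds log(a s) = 1/s regardless of a), so only non-detection records
// need to be visited per Newton step.

struct FocalTerms {
  std::vector<double> w0, a0;  // non-detection records in reach
  double wy = 0.0;             // sum of weights over detections
};

static double dlogpost(double s, const FocalTerms& t, double pm, double psd) {
  double d = t.wy / s - (s - pm) / (psd * psd);
  for (std::size_t i = 0; i < t.a0.size(); ++i) {
    d -= t.w0[i] * t.a0[i] / (1.0 - t.a0[i] * s);
  }
  return d;
}

static double d2logpost(double s, const FocalTerms& t, double pm, double psd) {
  double d = -t.wy / (s * s) - 1.0 / (psd * psd);
  for (std::size_t i = 0; i < t.a0.size(); ++i) {
    double q = t.a0[i] / (1.0 - t.a0[i] * s);
    d -= t.w0[i] * q * q;
  }
  return d;
}

// Safeguarded Newton maximisation of the strictly concave log posterior
// over [lo, hi]; falls back to bisection when a step leaves the bracket.
static double newton_max(const FocalTerms& t, double pm, double psd,
                         double lo, double hi) {
  double glo = dlogpost(lo, t, pm, psd);
  if (glo <= 0.0) return lo;  // decreasing at the left edge
  double ghi = dlogpost(hi, t, pm, psd);
  if (ghi >= 0.0) return hi;  // still increasing at the right edge
  double s = 0.5 * (lo + hi);
  for (int it = 0; it < 100; ++it) {
    double g = dlogpost(s, t, pm, psd);
    if (g > 0.0) lo = s; else hi = s;
    double h = d2logpost(s, t, pm, psd);
    double step = -g / h;
    double s_new = s + step;
    if (!(s_new > lo && s_new < hi)) s_new = 0.5 * (lo + hi);
    if (std::fabs(s_new - s) < 1e-12) { s = s_new; break; }
    s = s_new;
  }
  return s;
}

// Per-cell MAP update over a whole coarse raster.
// rec_row/rec_col are 0-based coarse indices; a = m * d per record.
// prior_mean/prior_sd are n_rows x n_cols matrices (NA = nodata).
// [[Rcpp::export]]
List cpp_update_map(IntegerVector rec_row, IntegerVector rec_col,
                    IntegerVector y, NumericVector a,
                    NumericMatrix prior_mean, NumericMatrix prior_sd,
                    double tau, double trunc_km, double cell_km,
                    double lower, double upper) {
  int n_rows = prior_mean.nrow(), n_cols = prior_mean.ncol();
  int n_rec = rec_row.size();

  // bucket records by coarse cell
  std::vector<std::vector<int> > bucket((std::size_t)n_rows * n_cols);
  for (int i = 0; i < n_rec; ++i) {
    bucket[(std::size_t)rec_row[i] * n_cols + rec_col[i]].push_back(i);
  }

  int reach = (tau > 0.0) ? (int)std::ceil(trunc_km / cell_km)
                          : std::max(n_rows, n_cols);
  double trunc2 = trunc_km * trunc_km;

  NumericMatrix s_hat(n_rows, n_cols), post_sd(n_rows, n_cols);
  FocalTerms t;

  for (int r0 = 0; r0 < n_rows; ++r0) {
    for (int c0 = 0; c0 < n_cols; ++c0) {
      double pm = prior_mean(r0, c0), psd = prior_sd(r0, c0);
      if (!std::isfinite(pm) || !std::isfinite(psd)) {
        s_hat(r0, c0) = NA_REAL; post_sd(r0, c0) = NA_REAL;
        continue;
      }
      t.w0.clear(); t.a0.clear(); t.wy = 0.0;
      for (int dr = -reach; dr <= reach; ++dr) {
        int r = r0 + dr;
        if (r < 0 || r >= n_rows) continue;
        for (int dc = -reach; dc <= reach; ++dc) {
          int c = c0 + dc;
          if (c < 0 || c >= n_cols) continue;
          const std::vector<int>& b = bucket[(std::size_t)r * n_cols + c];
          if (b.empty()) continue;
          double wt = 1.0;
          if (tau > 0.0) {
            double d2 = cell_km * cell_km * (dr * dr + dc * dc);
            if (d2 > trunc2) continue;
            wt = std::exp(-0.5 * tau * d2);
          }
          for (std::size_t k = 0; k < b.size(); ++k) {
            int i = b[k];
            if (y[i]) t.wy += wt;
            else { t.w0.push_back(wt); t.a0.push_back(a[i]); }
          }
        }
      }
      double s = newton_max(t, pm, psd, lower, upper);
      s_hat(r0, c0) = s;
      double curv = d2logpost(s, t, pm, psd);
      post_sd(r0, c0) = (curv < 0.0) ? 1.0 / std::sqrt(-curv) : psd;
    }
  }
  return List::create(_["mean"] = s_hat, _["sd"] = post_sd);
}

// Scalar weighted log posterior (exported for the single-cell R path and
// oracle tests).
// [[Rcpp::export]]
double cpp_log_post(double s, NumericVector w, NumericVector a,
                    IntegerVector y, double prior_mean, double prior_sd) {
  double ll = 0.0;
  const double eps = 1e-12;
  for (int i = 0; i < a.size(); ++i) {
    double p = a[i] * s;
    if (p < eps) p = eps;
    if (p > 1.0 - eps) p = 1.0 - eps;
    ll += w[i] * (y[i] ? std::log(p) : std::log1p(-p));
  }
  double z = (s - prior_mean) / prior_sd;
  return ll - 0.5 * z * z;
}
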