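#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Negative log-likelihood of reproduction trials under the three-stage
// observer, computed with the same quadrature scheme as the R reference
// path (response_pdf with direct BLS evaluation), but with the dense loops
// in C++. The BLS mapping is evaluated exactly at each measurement node;
// no interpolation is involved.
//
// tr_by_ts:  list of numeric vectors of responses, one per sample interval
// ts_vals:   the distinct sample intervals, same order as tr_by_ts
// px, pw:    Gauss-Legendre nodes/weights on the prior support
// mx, mw:    Gauss-Legendre reference nodes/weights on [-1, 1], mapped per
//            interval to t_s +/- 6 w_m t_s (floored at tm_floor)
// [[Rcpp::export]]
List nll_observer_cpp(List tr_by_ts, NumericVector ts_vals,
                      double wm, double wr,
                      NumericVector px, NumericVector pw,
                      NumericVector mx, NumericVector mw,
                      double prior_lo, double prior_hi,
                      double tm_floor, double log_floor) {
  const int n_ts = ts_vals.size();
  const int n_p = px.size();
  const int n_m = mx.size();
  const double inv_sqrt_2pi = 0.3989422804014327;
  double total = 0.0;
  int n_clamped = 0;

  for (int g = 0; g < n_ts; ++g) {
    const double ts = ts_vals[g];
    NumericVector tr = tr_by_ts[g];
    const int n_tr = tr.size();
    double lo = ts * (1.0 - 6.0 * wm);
    if (lo < tm_floor) lo = tm_floor;
    const double hi = ts * (1.0 + 6.0 * wm);
    const double mid = 0.5 * (lo + hi), half = 0.5 * (hi - lo);
    const double sd_meas = wm * ts;

    std::vector<double> dens(n_tr, 0.0);
    for (int i = 0; i < n_m; ++i) {
      const double m = mid + half * mx[i];
      // BLS estimate at this measurement node
      double num = 0.0, den = 0.0;
      for (int j = 0; j < n_p; ++j) {
        const double s = wm * px[j];
        const double z = (m - px[j]) / s;
        const double lik = std::exp(-0.5 * z * z) / s;
        num += pw[j] * px[j] * lik;
        den += pw[j] * lik;
      }
      double te;
      if (den > 0.0 && std::isfinite(num / den)) {
        te = num / den;
      } else {
        te = m < prior_lo ? prior_lo : (m > prior_hi ? prior_hi : m);
      }
      const double zm = (m - ts) / sd_meas;
      const double w_meas = half * mw[i] * inv_sqrt_2pi *
        std::exp(-0.5 * zm * zm) / sd_meas;
      const double sd_mot = wr * te;
      for (int k = 0; k < n_tr; ++k) {
        const double zr = (tr[k] - te) / sd_mot;
        dens[k] += w_meas * inv_sqrt_2pi * std::exp(-0.5 * zr * zr) / sd_mot;
      }
    }
    // measurements are clamped at tm_floor in the generative process; the
    // clamped mass is an atom at the floor's BLS estimate
    const double p_clamp = R::pnorm(tm_floor, ts, sd_meas, 1, 0);
    if (p_clamp > 0.0) {
      double num = 0.0, den = 0.0;
      for (int j = 0; j < n_p; ++j) {
        const double s = wm * px[j];
        const double z = (tm_floor - px[j]) / s;
        const double lik = std::exp(-0.5 * z * z) / s;
        num += pw[j] * px[j] * lik;
        den += pw[j] * lik;
      }
      const double te0 =
        (den > 0.0 && std::isfinite(num / den)) ? num / den : prior_lo;
      const double sd0 = wr * te0;
      for (int k = 0; k < n_tr; ++k) {
        const double zr = (tr[k] - te0) / sd0;
        dens[k] += p_clamp * inv_sqrt_2pi * std::exp(-0.5 * zr * zr) / sd0;
      }
    }

    for (int k = 0; k < n_tr; ++k) {
      double ld = dens[k] > 0.0 ? std::log(dens[k]) : log_floor;
      if (!std::isfinite(ld) || ld < log_floor) {
        ld = log_floor;
        ++n_clamped;
      }
      total -= ld;
    }
  }
  return List::create(Named("nll") = total,
                      Named("n_clamped") = n_clamped);
}
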