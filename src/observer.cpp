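#include <Rcpp.h>
using namespace Rcpp;

// Deterministic response-probability kernel for the simulation-based
// multinomial likelihood.  Internal samples are supplied as standard-normal
// draws (common random numbers) and scaled by the current sigmas, so the
// likelihood surface is smooth in the parameters and simplex-optimisable.
//
// Causal-structure marginals are the usual Gaussian convolutions:
//   C = 1: (x_A, x_V) | s ~ N(s, v_A) x N(s, v_V), s ~ N(mu_P, v_P)
//   C = 2: x_A ~ N(mu_P, v_A + v_P), x_V ~ N(mu_P, v_V + v_P)
// evaluated in log space to survive large disparities / small sigmas.

static inline double seg_est(double x, double v, double mup, double vp) {
  return (x / v + mup / vp) / (1.0 / v + 1.0 / vp);
}

// [[Rcpp::export]]
NumericMatrix cell_response_probs_cpp(NumericMatrix za, NumericMatrix zv,
                                      NumericVector aloc, NumericVector vloc,
                                      NumericVector sa, NumericVector sv,
                                      LogicalVector report_a,
                                      double sp, double mup, double pc,
                                      bool forced_fusion,
                                      NumericVector buttons) {
  const int nsim = za.nrow();
  const int ncell = aloc.size();
  const int nb = buttons.size();

  std::vector<double> edges(nb - 1);
  for (int j = 0; j < nb - 1; ++j) edges[j] = 0.5 * (buttons[j] + buttons[j + 1]);
  double centre = 0.0;
  for (int j = 0; j < nb; ++j) centre += buttons[j] / nb;

  const double vp = sp * sp;
  const double log_pc = (pc > 0.0) ? std::log(pc) : R_NegInf;
  const double log_qc = (pc < 1.0) ? std::log1p(-pc) : R_NegInf;

  NumericMatrix probs(nb, ncell);

  for (int c = 0; c < ncell; ++c) {
    const double va = sa[c] * sa[c];
    const double vv = sv[c] * sv[c];
    const double wsum = 1.0 / va + 1.0 / vv + 1.0 / vp;
    const double d1 = va * vv + va * vp + vv * vp;  // det of C=1 covariance
    const double l1c = -std::log(2.0 * M_PI) - 0.5 * std::log(d1);
    const double l2c = -std::log(2.0 * M_PI) -
      0.5 * std::log((va + vp) * (vv + vp));
    const bool repA = report_a[c];

    std::vector<int> counts(nb, 0);

    for (int i = 0; i < nsim; ++i) {
      const double xa = aloc[c] + sa[c] * za(i, c);
      const double xv = vloc[c] + sv[c] * zv(i, c);
      const double fused = (xa / va + xv / vv + mup / vp) / wsum;
      double est;
      if (forced_fusion) {
        est = fused;
      } else {
        double p1;
        if (pc >= 1.0) {
          p1 = 1.0;
        } else if (pc <= 0.0) {
          p1 = 0.0;
        } else {
          const double ll1 = l1c - 0.5 *
            ((xa - xv) * (xa - xv) * vp + (xa - mup) * (xa - mup) * vv +
             (xv - mup) * (xv - mup) * va) / d1;
          const double ll2 = l2c - 0.5 *
            ((xa - mup) * (xa - mup) / (va + vp) +
             (xv - mup) * (xv - mup) / (vv + vp));
          p1 = 1.0 / (1.0 + std::exp(ll2 + log_qc - ll1 - log_pc));
        }
        const double seg = repA ? seg_est(xa, va, mup, vp)
                                : seg_est(xv, vv, mup, vp);
        est = p1 * fused + (1.0 - p1) * seg;
      }

      // nearest button; midpoint ties break toward the centre button
      int idx = 0;
      while (idx < nb - 1 && est > edges[idx]) ++idx;
      if (idx > 0 && est == edges[idx - 1] && edges[idx - 1] > centre) --idx;
      if (idx < nb - 1 && est == edges[idx] && edges[idx] < centre) ++idx;
      ++counts[idx];
    }

    for (int b = 0; b < nb; ++b) probs(b, c) = (double)counts[b] / nsim;
  }

  return probs;
}

// Multinomial log likelihood summed over cells, probabilities floored
// before the log to guard against zero simulated mass.
// [[Rcpp::export]]
double multinomial_loglik_cpp(NumericMatrix probs, NumericMatrix counts,
                              double floor_p) {
  double ll = 0.0;
  for (int c = 0; c < probs.ncol(); ++c)
    for (int b = 0; b < probs.nrow(); ++b)
      if (counts(b, c) > 0.0)
        ll += counts(b, c) * std::log(std::max(probs(b, c), floor_p));
  return ll;
}
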