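#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Simulated log-likelihood (and analytic gradient) of the exploded
// sequential best-worst model with normally mixed domain coefficients.
//
// Rows are (case, alternative) pairs sorted by case, cases sorted by
// respondent; case utilities are V = sign * (b_dom + b_lvl) where the
// domain coefficient is b_dom = mean[d] + sd[d] * eta for the respondent's
// current draw. Per respondent the likelihood is the average over draws of
// the product of logit choice probabilities of all the respondent's cases.
// With n_draws = 1 and eta = 0 this is the plain conditional logit.
//
// theta layout: [dom_mean (P), lvl (K), dom_sd (P)]
// eta: (n_resp * n_draws) x P, respondent j / draw d at row j * n_draws + d
// dom, lvl: 0-based parameter indices per row, -1 = no such covariate
// [[Rcpp::export(name = ".exploded_loglik_cpp")]]
List exploded_loglik_cpp(NumericVector theta,
                         IntegerVector dom, IntegerVector lvl,
                         IntegerVector sgn, IntegerVector case_id,
                         IntegerVector resp_id, IntegerVector chosen,
                         NumericMatrix eta,
                         int n_resp, int n_draws, int P, int K,
                         bool want_grad) {
  const int n = dom.size();
  const double *mean = REAL(theta);
  const double *lv = mean + P;
  const double *sd = lv + K;
  const int D = n_draws;

  // case boundaries (rows sorted by case)
  std::vector<int> cstart;
  cstart.reserve(1024);
  for (int r = 0; r < n; ++r)
    if (r == 0 || case_id[r] != case_id[r - 1]) cstart.push_back(r);
  cstart.push_back(n);
  const int C = (int)cstart.size() - 1;

  // pass 1: per-respondent per-draw log product of case probabilities
  std::vector<double> S((size_t)n_resp * D, 0.0);
  std::vector<double> V(64);
  for (int d = 0; d < D; ++d) {
    for (int c = 0; c < C; ++c) {
      const int r0 = cstart[c], r1 = cstart[c + 1];
      const int j = resp_id[r0];
      const double *et = &eta((size_t)j * D + d, 0);
      double vmax = -1e300, vch = 0.0;
      if ((int)V.size() < r1 - r0) V.resize(r1 - r0);
      for (int r = r0; r < r1; ++r) {
        double u = 0.0;
        const int dm = dom[r], lq = lvl[r];
        if (dm >= 0) u += mean[dm] + sd[dm] * et[(size_t)dm * eta.nrow()];
        if (lq >= 0) u += lv[lq];
        u *= sgn[r];
        V[r - r0] = u;
        if (u > vmax) vmax = u;
        if (chosen[r]) vch = u;
      }
      double se = 0.0;
      for (int r = r0; r < r1; ++r) se += std::exp(V[r - r0] - vmax);
      S[(size_t)j * D + d] += vch - vmax - std::log(se);
    }
  }

  // combine draws per respondent
  double ll = 0.0;
  std::vector<double> W((size_t)n_resp * D);
  for (int j = 0; j < n_resp; ++j) {
    double smax = -1e300;
    for (int d = 0; d < D; ++d)
      if (S[(size_t)j * D + d] > smax) smax = S[(size_t)j * D + d];
    double tot = 0.0;
    for (int d = 0; d < D; ++d) {
      double e = std::exp(S[(size_t)j * D + d] - smax);
      W[(size_t)j * D + d] = e;
      tot += e;
    }
    ll += smax + std::log(tot / D);
    if (want_grad)
      for (int d = 0; d < D; ++d) W[(size_t)j * D + d] /= tot;
  }

  NumericVector grad(want_grad ? (2 * P + K) : 0);
  if (want_grad) {
    double *gm = REAL(grad);
    double *gl = gm + P;
    double *gs = gl + K;
    for (int d = 0; d < D; ++d) {
      for (int c = 0; c < C; ++c) {
        const int r0 = cstart[c], r1 = cstart[c + 1];
        const int j = resp_id[r0];
        const double w = W[(size_t)j * D + d];
        if (w < 1e-300) continue;
        const double *et = &eta((size_t)j * D + d, 0);
        double vmax = -1e300;
        if ((int)V.size() < r1 - r0) V.resize(r1 - r0);
        for (int r = r0; r < r1; ++r) {
          double u = 0.0;
          const int dm = dom[r], lq = lvl[r];
          if (dm >= 0) u += mean[dm] + sd[dm] * et[(size_t)dm * eta.nrow()];
          if (lq >= 0) u += lv[lq];
          u *= sgn[r];
          V[r - r0] = u;
          if (u > vmax) vmax = u;
        }
        double se = 0.0;
        for (int r = r0; r < r1; ++r) {
          V[r - r0] = std::exp(V[r - r0] - vmax);
          se += V[r - r0];
        }
        for (int r = r0; r < r1; ++r) {
          const double resid = (chosen[r] ? 1.0 : 0.0) - V[r - r0] / se;
          const double g = w * resid * sgn[r];
          const int dm = dom[r], lq = lvl[r];
          if (dm >= 0) {
            gm[dm] += g;
            gs[dm] += g * et[(size_t)dm * eta.nrow()];
          }
          if (lq >= 0) gl[lq] += g;
        }
      }
    }
  }
  return List::create(_["loglik"] = ll, _["gradient"] = grad);
}
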