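#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Gaussian state-space likelihood for a sparse lagged linear recursion over k
// daily series on a complete calendar grid, with missing entries marginalized
// by the Kalman filter (missing observation rows are simply skipped).
//
// State at day t: for each series i, its values on days t, t-1, ..,
// t-depth[i]+1, stacked.  Each series' current value is itself a state
// element, so observations are exact (no measurement noise); all stochastic
// innovation lives in the transition.
//
// A per-subject intercept on one designated series is concentrated out of
// the likelihood exactly via filter augmentation: alongside the data column
// we propagate the sensitivity of the filtered state to the intercept, and
// profile the resulting quadratic in closed form (GLS for a regression
// effect in the observation process).
//
// The likelihood conditions on the first m0 days of each subject: their
// observed values initialise the state with zero variance, unobserved slots
// get a diffuse-ish prior variance; days <= m0 contribute nothing to the
// reported likelihood.

struct EqTerm {
  int tgt;  // 0-based target series
  int src;  // 0-based source series
  int lag;  // >= 1
  int idx;  // index into coefficient vector
};

// [[Rcpp::export]]
List ss_loglik_cpp(List subj_data,
                   IntegerMatrix eqs,     // columns: target, source, lag (1-based series)
                   NumericVector coefs,   // one per row of eqs
                   NumericVector sigma,   // innovation sd per series
                   IntegerVector depth,   // state depth per series
                   int m0,                // conditioning days (>= max depth)
                   int intercept_series,  // 1-based, 0 = no concentrated intercept
                   int outcome_series,    // 1-based, series whose loglik is reported
                   NumericVector prior_var) {
  const int k = depth.size();
  const int ne = eqs.nrow();
  std::vector<EqTerm> terms(ne);
  for (int e = 0; e < ne; ++e) {
    terms[e].tgt = eqs(e, 0) - 1;
    terms[e].src = eqs(e, 1) - 1;
    terms[e].lag = eqs(e, 2);
    terms[e].idx = e;
  }
  std::vector<int> off(k);
  int D = 0;
  for (int i = 0; i < k; ++i) { off[i] = D; D += depth[i]; }
  const int ic = intercept_series - 1;  // -1 if none
  const int oc = outcome_series - 1;

  std::vector<double> sig2(k);
  for (int i = 0; i < k; ++i) sig2[i] = sigma[i] * sigma[i];

  double tot_ll = 0.0, y_ll = 0.0;
  int n_y = 0, n_all = 0;
  const double LOG2PI = 1.8378770664093453;
  const int nsub = subj_data.size();
  NumericVector mu_hat(nsub);

  // work buffers sized on first use
  std::vector<double> a0(D), A(D), P(D * D), Pn(D * D), an0(D), An(D), K(D);
  std::vector<double> CP(k * D), newv0(k), newA(k), CPC(k * k);

  for (int s = 0; s < nsub; ++s) {
    NumericMatrix Y = subj_data[s];
    const int T = Y.nrow();
    if (Y.ncol() != k) stop("subject matrix has wrong number of series");
    if (T <= m0) continue;

    // init state from days 1..m0 (day m0 - j for state slot j)
    std::fill(P.begin(), P.end(), 0.0);
    std::fill(A.begin(), A.end(), 0.0);
    for (int i = 0; i < k; ++i) {
      for (int j = 0; j < depth[i]; ++j) {
        int pos = off[i] + j;
        double v = Y(m0 - 1 - j, i);
        if (ISNAN(v) || !std::isfinite(v)) {
          a0[pos] = 0.0;
          P[pos * D + pos] = prior_var[i];
        } else {
          a0[pos] = v;
        }
      }
    }

    // per-update records for this subject
    std::vector<double> rec_v0, rec_V, rec_F;
    std::vector<int> rec_is_y;
    rec_v0.reserve((T - m0) * k); rec_V.reserve((T - m0) * k);
    rec_F.reserve((T - m0) * k); rec_is_y.reserve((T - m0) * k);

    for (int t = m0; t < T; ++t) {  // 0-based row t = day t+1
      // ---- predict ----
      std::fill(newv0.begin(), newv0.end(), 0.0);
      std::fill(newA.begin(), newA.end(), 0.0);
      std::fill(CP.begin(), CP.end(), 0.0);
      for (int e = 0; e < ne; ++e) {
        const EqTerm &q = terms[e];
        const int pos = off[q.src] + q.lag - 1;  // value at day t - lag
        const double c = coefs[q.idx];
        newv0[q.tgt] += c * a0[pos];
        newA[q.tgt] += c * A[pos];
        const double *Prow = &P[pos * D];
        double *CProw = &CP[q.tgt * D];
        for (int d = 0; d < D; ++d) CProw[d] += c * Prow[d];
      }
      if (ic >= 0) newA[ic] += 1.0;
      std::fill(CPC.begin(), CPC.end(), 0.0);
      for (int e = 0; e < ne; ++e) {
        const EqTerm &q = terms[e];
        const int pos = off[q.src] + q.lag - 1;
        const double c = coefs[q.idx];
        for (int i = 0; i < k; ++i) CPC[i * k + q.tgt] += c * CP[i * D + pos];
      }
      // assemble shifted state
      for (int i = 0; i < k; ++i) {
        an0[off[i]] = newv0[i];
        An[off[i]] = newA[i];
        for (int j = depth[i] - 1; j >= 1; --j) {
          an0[off[i] + j] = a0[off[i] + j - 1];
          An[off[i] + j] = A[off[i] + j - 1];
        }
      }
      // assemble Pn
      for (int i = 0; i < k; ++i) {
        for (int i2 = 0; i2 < k; ++i2) {
          double v = CPC[i * k + i2];
          if (i == i2) v += sig2[i];
          Pn[off[i] * D + off[i2]] = v;
        }
        for (int i2 = 0; i2 < k; ++i2)
          for (int j2 = 1; j2 < depth[i2]; ++j2) {
            double v = CP[i * D + off[i2] + j2 - 1];
            Pn[off[i] * D + off[i2] + j2] = v;
            Pn[(off[i2] + j2) * D + off[i]] = v;
          }
      }
      for (int i = 0; i < k; ++i)
        for (int j = 1; j < depth[i]; ++j)
          for (int i2 = 0; i2 < k; ++i2)
            for (int j2 = 1; j2 < depth[i2]; ++j2)
              Pn[(off[i] + j) * D + off[i2] + j2] =
                  P[(off[i] + j - 1) * D + off[i2] + j2 - 1];
      std::swap(P, Pn);
      std::swap(a0, an0);
      std::swap(A, An);

      // ---- sequential updates, series order as given ----
      for (int i = 0; i < k; ++i) {
        double yv = Y(t, i);
        if (ISNAN(yv) || !std::isfinite(yv)) continue;
        const int pos = off[i];
        double F = P[pos * D + pos];
        if (F < 1e-12) F = 1e-12;
        const double v0 = yv - a0[pos];
        const double V = A[pos];
        rec_v0.push_back(v0); rec_V.push_back(V); rec_F.push_back(F);
        rec_is_y.push_back(i == oc ? 1 : 0);
        const double Finv = 1.0 / F;
        for (int d = 0; d < D; ++d) K[d] = P[d * D + pos] * Finv;
        for (int d = 0; d < D; ++d) {
          a0[d] += K[d] * v0;
          A[d] -= K[d] * V;
        }
        for (int d1 = 0; d1 < D; ++d1) {
          const double kd1F = K[d1] * F;
          double *Pr = &P[d1 * D];
          for (int d2 = 0; d2 < D; ++d2) Pr[d2] -= kd1F * K[d2];
        }
      }
    }

    // ---- concentrate intercept, accumulate logliks ----
    double Svv = 0.0, Svy = 0.0, slogF = 0.0, sq = 0.0;
    const int nr = (int)rec_v0.size();
    for (int r = 0; r < nr; ++r) {
      const double Fi = 1.0 / rec_F[r];
      Svv += rec_V[r] * rec_V[r] * Fi;
      Svy += rec_V[r] * rec_v0[r] * Fi;
      slogF += std::log(rec_F[r]);
      sq += rec_v0[r] * rec_v0[r] * Fi;
    }
    double mu = 0.0;
    if (ic >= 0 && Svv > 1e-12) mu = Svy / Svv;
    mu_hat[s] = mu;
    double ll_s = -0.5 * (nr * LOG2PI + slogF + sq);
    if (ic >= 0 && Svv > 1e-12) ll_s += 0.5 * Svy * Svy / Svv;
    tot_ll += ll_s;
    n_all += nr;
    for (int r = 0; r < nr; ++r) {
      if (!rec_is_y[r]) continue;
      const double e = rec_v0[r] - rec_V[r] * mu;
      y_ll += -0.5 * (LOG2PI + std::log(rec_F[r]) + e * e / rec_F[r]);
      ++n_y;
    }
  }

  return List::create(_["loglik"] = tot_ll, _["loglik_y"] = y_ll,
                      _["n_y"] = n_y, _["n_obs"] = n_all,
                      _["mu"] = mu_hat);
}
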