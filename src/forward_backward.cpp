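#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward recursions for an input-driven HMM.
//
// logB: T x K matrix of log emission likelihoods log p(y_t | z_t = k).
// A:    T*K*K array (R column-major, [t, i, j]) of per-trial transition
//       matrices; slice t governs the transition INTO trial t (slice 1 unused).
// pi:   initial state distribution.
//
// Messages are rescaled to sum to 1 at every trial; the accumulated log scale
// factors make logZ exact. Emissions are max-subtracted per trial so the
// recursion never touches raw exp() of large-magnitude logits.
// [[Rcpp::export(name = ".fb_core")]]
List fb_core(NumericMatrix logB, NumericVector A, NumericVector pi) {
  const int T = logB.nrow();
  const int K = logB.ncol();

  NumericMatrix ahat(T, K), bhat(T, K), phi(T, K), em(T, K);
  NumericVector cs(T);          // scaled normalizers
  NumericVector mx(T);          // per-trial emission log max
  double logZ = 0.0;

  auto Aat = [&](int t, int i, int j) -> double {
    return A[t + T * i + T * K * j];
  };

  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k) m = std::max(m, logB(t, k));
    mx[t] = m;
    for (int k = 0; k < K; ++k) em(t, k) = std::exp(logB(t, k) - m);
  }

  // forward
  for (int k = 0; k < K; ++k) ahat(0, k) = pi[k] * em(0, k);
  double c0 = 0.0;
  for (int k = 0; k < K; ++k) c0 += ahat(0, k);
  if (!(c0 > 0.0) || !std::isfinite(c0))
    stop("non-finite forward message at trial 1");
  for (int k = 0; k < K; ++k) ahat(0, k) /= c0;
  cs[0] = c0;
  logZ += std::log(c0) + mx[0];

  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += ahat(t - 1, j) * Aat(t, j, k);
      double v = s * em(t, k);
      ahat(t, k) = v;
      ct += v;
    }
    if (!(ct > 0.0) || !std::isfinite(ct))
      stop("non-finite forward message at trial %d", t + 1);
    for (int k = 0; k < K; ++k) ahat(t, k) /= ct;
    cs[t] = ct;
    logZ += std::log(ct) + mx[t];
  }

  // backward
  for (int k = 0; k < K; ++k) bhat(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int k = 0; k < K; ++k)
        s += Aat(t + 1, j, k) * em(t + 1, k) * bhat(t + 1, k);
      bhat(t, j) = s / cs[t + 1];
    }
  }

  // posteriors
  for (int t = 0; t < T; ++t) {
    double z = 0.0;
    for (int k = 0; k < K; ++k) z += ahat(t, k) * bhat(t, k);
    if (!(z > 0.0) || !std::isfinite(z))
      stop("non-finite posterior at trial %d", t + 1);
    for (int k = 0; k < K; ++k) phi(t, k) = ahat(t, k) * bhat(t, k) / z;
  }

  // joint posteriors mu[t, j, k] = P(z_t = j, z_{t+1} = k | Y)
  NumericVector mu;
  if (T > 1) {
    mu = NumericVector((T - 1) * K * K);
    for (int t = 0; t < T - 1; ++t) {
      double z = 0.0;
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k) {
          double v = ahat(t, j) * Aat(t + 1, j, k) * em(t + 1, k) *
                     bhat(t + 1, k) / cs[t + 1];
          mu[t + (T - 1) * j + (T - 1) * K * k] = v;
          z += v;
        }
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k)
          mu[t + (T - 1) * j + (T - 1) * K * k] /= z;
    }
  } else {
    mu = NumericVector(0);
  }

  return List::create(_["phi"] = phi, _["mu"] = mu, _["logZ"] = logZ,
                      _["alpha_hat"] = ahat, _["beta_hat"] = bhat,
                      _["log_scale"] = log(cs) + mx);
}
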