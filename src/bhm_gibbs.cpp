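#include <Rcpp.h>
using namespace Rcpp;

// Binomial hierarchical model on the log-odds scale:
//   Y_k ~ Bin(n_k, p_k),  theta_k = logit(p_k) ~ N(mu, sigma2),
//   mu ~ N(mu_mean, mu_sd^2),  sigma2 ~ IG(shape, scale) or fixed.
// Gibbs over (mu, sigma2) with conjugate conditionals; slice sampling for
// each theta_k; plus a joint translation move on (mu, theta) that keeps the
// chain mobile when sigma2 collapses toward zero (strong borrowing).
// Uses R's RNG so results are reproducible through set.seed().

static inline double softplus(double x) {
  return (x > 35.0) ? x : std::log1p(std::exp(x));
}

// unnormalised log full conditional of theta_k
static inline double theta_logpost(double th, double y, double n, double mu,
                                   double sig2) {
  return y * th - n * softplus(th) - 0.5 * (th - mu) * (th - mu) / sig2;
}

// unnormalised log conditional of mu in the pooled model (sigma2 = 0):
// all theta_k == mu, so the whole binomial likelihood acts on mu.
static inline double pooled_logpost(double mu, double sy, double sn,
                                    double mu_mean, double mu_prec) {
  return sy * mu - sn * softplus(mu) -
         0.5 * mu_prec * (mu - mu_mean) * (mu - mu_mean);
}

// Generic slice sampler step (stepping out + shrinkage), log-concave targets.
template <typename F>
static double slice_step(double x0, double w, F logf) {
  double f0 = logf(x0);
  double logy = f0 - R::rexp(1.0);
  double u = R::runif(0.0, 1.0);
  double L = x0 - w * u, U = L + w;
  int m = 100;
  while (m-- > 0 && logf(L) > logy) L -= w;
  m = 100;
  while (m-- > 0 && logf(U) > logy) U += w;
  for (int it = 0; it < 200; ++it) {
    double x1 = R::runif(L, U);
    if (logf(x1) >= logy) return x1;
    if (x1 < x0) L = x1; else U = x1;
  }
  return x0;
}

// [[Rcpp::export]]
List bhm_gibbs_cpp(NumericVector y, NumericVector n, double mu_mean,
                   double mu_sd, bool sigma2_fixed, double sigma2_value,
                   double ig_shape, double ig_scale, int iter, int burn,
                   int thin) {
  const int K = y.size();
  const double mu_prec = 1.0 / (mu_sd * mu_sd);
  const bool pooled = sigma2_fixed && sigma2_value <= 0.0;
  const int kept = (iter - burn + thin - 1) / thin;

  NumericMatrix theta_out(kept, K);
  NumericVector mu_out(kept), sig2_out(kept);

  // initialise at empirical logits
  std::vector<double> th(K);
  double sy = 0.0, sn = 0.0;
  for (int k = 0; k < K; ++k) {
    th[k] = std::log((y[k] + 0.5) / (n[k] - y[k] + 0.5));
    sy += y[k];
    sn += n[k];
  }
  double mu = 0.0;
  for (int k = 0; k < K; ++k) mu += th[k];
  mu /= K;
  double sig2;
  if (sigma2_fixed) {
    sig2 = sigma2_value;
  } else {
    double ss = 0.0;
    for (int k = 0; k < K; ++k) ss += (th[k] - mu) * (th[k] - mu);
    sig2 = std::max(ss / K, 0.01);
  }

  int row = 0;
  for (int it = 0; it < iter; ++it) {
    if (pooled) {
      mu = slice_step(mu, 1.0, [&](double m) {
        return pooled_logpost(m, sy, sn, mu_mean, mu_prec);
      });
      for (int k = 0; k < K; ++k) th[k] = mu;
    } else {
      // sigma2 | theta, mu  (inverse-gamma conjugate)
      if (!sigma2_fixed) {
        double ss = 0.0;
        for (int k = 0; k < K; ++k) ss += (th[k] - mu) * (th[k] - mu);
        double shape = ig_shape + 0.5 * K;
        double rate = ig_scale + 0.5 * ss;
        sig2 = rate / R::rgamma(shape, 1.0);
        if (sig2 < 1e-12) sig2 = 1e-12;
      }
      // mu | theta, sigma2  (normal conjugate)
      double prec = K / sig2 + mu_prec;
      double sum_th = 0.0;
      for (int k = 0; k < K; ++k) sum_th += th[k];
      double mean = (sum_th / sig2 + mu_mean * mu_prec) / prec;
      mu = R::rnorm(mean, std::sqrt(1.0 / prec));
      // theta_k | mu, sigma2, y_k  (slice)
      double w = std::min(1.0, 3.0 * std::sqrt(sig2) + 0.05);
      for (int k = 0; k < K; ++k) {
        double yk = y[k], nk = n[k];
        th[k] = slice_step(th[k], w, [&](double t) {
          return theta_logpost(t, yk, nk, mu, sig2);
        });
      }
      // joint translation of (mu, theta): helps mixing when sig2 ~ 0
      double d = R::rnorm(0.0, 0.25);
      double lr = 0.0;
      for (int k = 0; k < K; ++k)
        lr += y[k] * d - n[k] * (softplus(th[k] + d) - softplus(th[k]));
      lr += -0.5 * mu_prec *
            ((mu + d - mu_mean) * (mu + d - mu_mean) -
             (mu - mu_mean) * (mu - mu_mean));
      if (std::log(R::runif(0.0, 1.0)) < lr) {
        mu += d;
        for (int k = 0; k < K; ++k) th[k] += d;
      }
    }

    if (it >= burn && (it - burn) % thin == 0) {
      for (int k = 0; k < K; ++k) theta_out(row, k) = th[k];
      mu_out[row] = mu;
      sig2_out[row] = pooled ? 0.0 : sig2;
      ++row;
    }
  }

  return List::create(_["theta"] = theta_out, _["mu"] = mu_out,
                      _["sigma2"] = sig2_out);
}

// Posterior means of p_k for a batch of trials sharing one (prior, settings)
// configuration: the inner loop of design-stage Monte Carlo. y is a
// reps x K matrix of responder counts. Returns a reps x K matrix of
// posterior means.
// [[Rcpp::export]]
NumericMatrix bhm_postmean_batch_cpp(IntegerMatrix y, NumericVector n,
                                     double mu_mean, double mu_sd,
                                     bool sigma2_fixed, NumericVector sigma2_value,
                                     double ig_shape, double ig_scale,
                                     int iter, int burn, int thin) {
  const int reps = y.nrow(), K = y.ncol();
  NumericMatrix out(reps, K);
  NumericVector yr(K);
  for (int r = 0; r < reps; ++r) {
    for (int k = 0; k < K; ++k) yr[k] = y(r, k);
    double s2 = sigma2_value.size() == 1 ? sigma2_value[0] : sigma2_value[r];
    List fit = bhm_gibbs_cpp(yr, n, mu_mean, mu_sd, sigma2_fixed, s2,
                             ig_shape, ig_scale, iter, burn, thin);
    NumericMatrix th = fit["theta"];
    for (int k = 0; k < K; ++k) {
      double acc = 0.0;
      for (int i = 0; i < th.nrow(); ++i) acc += 1.0 / (1.0 + std::exp(-th(i, k)));
      out(r, k) = acc / th.nrow();
    }
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Same batch driver but also returns per-replication posterior
// tail probabilities Pr(p_k > threshold | data), used for rejection rules.
// [[Rcpp::export]]
List bhm_batch_cpp(IntegerMatrix y, NumericVector n, double mu_mean,
                   double mu_sd, bool sigma2_fixed, NumericVector sigma2_value,
                   double ig_shape, double ig_scale, int iter, int burn,
                   int thin, double threshold) {
  const int reps = y.nrow(), K = y.ncol();
  NumericMatrix pm(reps, K), tail(reps, K);
  NumericVector yr(K);
  const double th_logit = std::log(threshold / (1.0 - threshold));
  for (int r = 0; r < reps; ++r) {
    for (int k = 0; k < K; ++k) yr[k] = y(r, k);
    double s2 = sigma2_value.size() == 1 ? sigma2_value[0] : sigma2_value[r];
    List fit = bhm_gibbs_cpp(yr, n, mu_mean, mu_sd, sigma2_fixed, s2,
                             ig_shape, ig_scale, iter, burn, thin);
    NumericMatrix th = fit["theta"];
    const int m = th.nrow();
    for (int k = 0; k < K; ++k) {
      double acc = 0.0, cnt = 0.0;
      for (int i = 0; i < m; ++i) {
        acc += 1.0 / (1.0 + std::exp(-th(i, k)));
        if (th(i, k) > th_logit) cnt += 1.0;
      }
      pm(r, k) = acc / m;
      tail(r, k) = cnt / m;
    }
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["post_mean"] = pm, _["tail_prob"] = tail);
}
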