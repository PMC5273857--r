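#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the three-component normal mixture on weighted
// z-scores.  `x` are the (sorted) statistic values, `w` integer
// weights (all 1 in raw mode; bin counts in binned mode).  Label
// sampling loops over the weight of each value so that a run on
// weight-1 values and a run on losslessly binned values consume the
// RNG stream identically.  Uses R's RNG throughout, so set.seed()
// makes the trace bit-reproducible.
//
// Conditional updates (conjugate normal/inverse-gamma/Dirichlet):
//   eps        ~ Dirichlet(gamma_j + n_j)
//   mu_j|s2_j  ~ N((tau_j*lambda_j + s_j)/(tau_j + n_j),
//                  s2_j/(tau_j + n_j))           [s_j = sum of members]
//   1/s2_j     ~ Gamma(alpha + (n_j+1)/2,
//                  rate = beta + tau_j*(mu_j-lambda_j)^2/2 + SS_j/2)
// with SS_j the within-component sum of squares about the component
// sample mean.  Empty components (n_j = 0) reduce to the prior.
// [[Rcpp::export]]
List gibbs_core(NumericVector x, IntegerVector w,
                NumericVector eps0, NumericVector mu0, NumericVector sd0,
                NumericVector lambda, NumericVector tau,
                double alpha, double beta, NumericVector gamma,
                int n_burnin, int n_keep) {
  const int m = x.size();
  const int n_iter = n_burnin + n_keep;
  NumericMatrix trace(n_keep, 9);
  double eps[3] = {eps0[0], eps0[1], eps0[2]};
  double mu[3]  = {mu0[0],  mu0[1],  mu0[2]};
  double sd[3]  = {sd0[0],  sd0[1],  sd0[2]};
  long underflow = 0;

  RNGScope scope;
  for (int t = 0; t < n_iter; ++t) {
    // --- sample component labels, accumulate sufficient statistics ---
    // long-double accumulators mirror R's sum()/rowSums(), so the
    // pure-R reference loop reproduces this sampler bit for bit
    double n[3] = {0, 0, 0};
    long double s_acc[3] = {0, 0, 0}, ss_acc[3] = {0, 0, 0};
    double lw[3], p[3];
    for (int j = 0; j < 3; ++j) lw[j] = log(eps[j]) - log(sd[j]);
    for (int i = 0; i < m; ++i) {
      const double xi = x[i];
      double logd[3], mx = R_NegInf;
      for (int j = 0; j < 3; ++j) {
        const double r = (xi - mu[j]) / sd[j];
        logd[j] = lw[j] - 0.5 * (r * r);
        if (logd[j] > mx) mx = logd[j];
      }
      int lab_fixed = -1;
      long double total_acc = 0.0;
      double total = 0.0;
      if (!R_FINITE(mx)) {
        // all three densities underflow: assign to nearest mean
        ++underflow;
        double best = R_PosInf;
        for (int j = 0; j < 3; ++j) {
          const double d = fabs(xi - mu[j]);
          if (d < best) { best = d; lab_fixed = j; }
        }
      } else {
        for (int j = 0; j < 3; ++j) { p[j] = exp(logd[j] - mx); total_acc += p[j]; }
        total = (double) total_acc;
      }
      const int wi = w[i];
      const double xi2 = xi * xi;
      for (int k = 0; k < wi; ++k) {
        int lab;
        if (lab_fixed >= 0) {
          lab = lab_fixed;
        } else {
          const double u = unif_rand() * total;
          lab = (u < p[0]) ? 0 : ((u < p[0] + p[1]) ? 1 : 2);
        }
        n[lab] += 1.0; s_acc[lab] += xi; ss_acc[lab] += xi2;
      }
    }
    double s[3], ss[3];
    for (int j = 0; j < 3; ++j) { s[j] = (double) s_acc[j]; ss[j] = (double) ss_acc[j]; }
    // --- mixture proportions ---
    double g[3];
    long double gt_acc = 0.0;
    for (int j = 0; j < 3; ++j) { g[j] = R::rgamma(gamma[j] + n[j], 1.0); gt_acc += g[j]; }
    const double gt = (double) gt_acc;
    for (int j = 0; j < 3; ++j) eps[j] = g[j] / gt;
    // --- component means (using current variances) ---
    for (int j = 0; j < 3; ++j) {
      const double denom = tau[j] + n[j];
      const double pm = (tau[j] * lambda[j] + s[j]) / denom;
      mu[j] = R::rnorm(pm, sd[j] / sqrt(denom));
    }
    // --- component variances (using the new means) ---
    for (int j = 0; j < 3; ++j) {
      double SS = (n[j] > 0) ? ss[j] - s[j] * s[j] / n[j] : 0.0;
      if (SS < 0) SS = 0;
      const double dlt = mu[j] - lambda[j];
      const double shape = alpha + 0.5 * (n[j] + 1.0);
      const double rate = beta + 0.5 * tau[j] * (dlt * dlt) + 0.5 * SS;
      const double prec = R::rgamma(shape, 1.0 / rate);
      sd[j] = 1.0 / sqrt(prec);
    }
    if (t >= n_burnin) {
      const int r = t - n_burnin;
      for (int j = 0; j < 3; ++j) {
        trace(r, j) = eps[j];
        trace(r, 3 + j) = mu[j];
        trace(r, 6 + j) = sd[j];
      }
    }
  }
  return List::create(_["trace"] = trace, _["n_underflow"] = underflow);
}
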