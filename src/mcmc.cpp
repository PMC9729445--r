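#include <Rcpp.h>
using namespace Rcpp;

// Per-locus random-walk Metropolis for genomic cline parameters (alpha, beta)
// with fixed per-individual hybrid indices h and parental frequencies p0, p1.
// Loci are conditionally independent, so each locus gets its own chain.
// Uses R's RNG so results are reproducible under set.seed().

static inline double phi_fun(double h, double a, double b) {
  double v = h + 2.0 * h * (1.0 - h) * (a + b * (2.0 * h - 1.0));
  if (v < 0.0) v = 0.0;
  if (v > 1.0) v = 1.0;
  return v;
}

// log-likelihood for one locus; g = -1 encodes missing
static double locus_ll(const int *g, const double *h, int n,
                       double a, double b, double p0, double p1,
                       double eps) {
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    int gi = g[i];
    if (gi < 0) continue;
    double ph = phi_fun(h[i], a, b);
    double pi = ph * p1 + (1.0 - ph) * p0;
    if (eps > 0.0) pi = pi * (1.0 - eps) + (1.0 - pi) * eps;
    if (pi < 1e-12) pi = 1e-12;
    if (pi > 1.0 - 1e-12) pi = 1.0 - 1e-12;
    ll += gi * std::log(pi) + (2 - gi) * std::log(1.0 - pi);
  }
  return ll;
}

// [[Rcpp::export(name = ".mcmc_genomic_clines")]]
List mcmc_genomic_clines(IntegerMatrix G, NumericVector h,
                         NumericVector p0, NumericVector p1,
                         int iterations, int burnin, int thin,
                         double proposal_sd, double prior_sd,
                         double eps) {
  const int n = G.nrow();
  const int L = G.ncol();
  const int n_keep = iterations / thin;
  NumericMatrix alpha_s(n_keep, L), beta_s(n_keep, L);
  NumericVector acc_rate(L), tuned_sd(L);
  const double pv = prior_sd * prior_sd;
  std::vector<int> gcol(n);
  RNGScope scope;

  for (int l = 0; l < L; ++l) {
    for (int i = 0; i < n; ++i) {
      int v = G(i, l);
      gcol[i] = (v == NA_INTEGER) ? -1 : v;
    }
    double a = 0.0, b = 0.0;
    double sd_a = proposal_sd, sd_b = proposal_sd;
    double ll = locus_ll(gcol.data(), h.begin(), n, a, b, p0[l], p1[l], eps);
    int acc = 0, tries = 0;
    int tune_acc_a = 0, tune_acc_b = 0, tune_n = 0;
    int keep = 0;
    for (int it = 0; it < burnin + iterations; ++it) {
      // alpha update
      double ap = a + norm_rand() * sd_a;
      double llp = locus_ll(gcol.data(), h.begin(), n, ap, b,
                            p0[l], p1[l], eps);
      double lr = llp - ll + (a * a - ap * ap) / (2.0 * pv);
      if (lr >= 0.0 || unif_rand() < std::exp(lr)) {
        a = ap; ll = llp;
        if (it < burnin) ++tune_acc_a; else ++acc;
      }
      if (it >= burnin) ++tries;
      // beta update
      double bp = b + norm_rand() * sd_b;
      llp = locus_ll(gcol.data(), h.begin(), n, a, bp, p0[l], p1[l], eps);
      lr = llp - ll + (b * b - bp * bp) / (2.0 * pv);
      if (lr >= 0.0 || unif_rand() < std::exp(lr)) {
        b = bp; ll = llp;
        if (it < burnin) ++tune_acc_b; else ++acc;
      }
      if (it >= burnin) ++tries;
      // proposal tuning towards 0.2-0.5 acceptance, burnin only
      if (it < burnin) {
        ++tune_n;
        if (tune_n == 100) {
          double ra = tune_acc_a / 100.0, rb = tune_acc_b / 100.0;
          if (ra < 0.2) sd_a *= 0.7; else if (ra > 0.5) sd_a *= 1.4;
          if (rb < 0.2) sd_b *= 0.7; else if (rb > 0.5) sd_b *= 1.4;
          tune_acc_a = tune_acc_b = tune_n = 0;
        }
      }
      if (it >= burnin && ((it - burnin + 1) % thin == 0) && keep < n_keep) {
        alpha_s(keep, l) = a;
        beta_s(keep, l) = b;
        ++keep;
      }
    }
    acc_rate[l] = tries > 0 ? (double)acc / tries : NA_REAL;
    tuned_sd[l] = 0.5 * (sd_a + sd_b);
  }
  return List::create(_["alpha"] = alpha_s, _["beta"] = beta_s,
                      _["accept"] = acc_rate, _["tuned_sd"] = tuned_sd);
}
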