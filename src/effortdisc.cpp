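#include <Rcpp.h>
using namespace Rcpp;

// utility model codes (kept in sync with UTILITY_MODELS on the R side):
// 0 = log_difference, 1 = difference, 2 = hyperbolic, 3 = hyperbolic_log

static inline double utility_c(double E, int model, bool &ok) {
  if (!(E > 0.0)) { ok = false; return 0.0; }
  switch (model) {
  case 0: return -std::log(E);
  case 1: return -E;
  case 2: return 1.0 / E;
  default: {
    double lE = std::log(E);
    if (std::fabs(lE) < 1e-10) { ok = false; return 0.0; }
    return 1.0 / lE;
  }
  }
}

// log Bernoulli-probit likelihood of one subject's trials
static double subject_loglik_c(double alpha, double beta, double gamma,
                               const double *FR, const double *FT,
                               const int *nrep, const int *choice,
                               int n, int model) {
  if (!(alpha > 0.0) || !(beta > 0.0) || !(gamma > 0.0))
    return R_NegInf;
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    bool ok = true;
    double ER = nrep[t] * (std::pow(FR[t], alpha) + beta);
    double ET = std::pow(FT[t], alpha) + beta;
    double z = (utility_c(ER, model, ok) - utility_c(ET, model, ok)) / gamma;
    if (!ok || !R_finite(z)) return R_NegInf;
    // log P(choice): lower tail for reference, upper tail for test
    ll += R::pnorm(z, 0.0, 1.0, choice[t], 1);
  }
  return ll;
}

// [[Rcpp::export]]
NumericVector cpp_pointwise_loglik(NumericVector alpha, NumericVector beta,
                                   NumericVector gamma, IntegerVector subj,
                                   NumericVector FR, NumericVector FT,
                                   IntegerVector nrep, IntegerVector choice,
                                   int model) {
  int n = FR.size();
  NumericVector out(n);
  for (int t = 0; t < n; ++t) {
    int i = subj[t];
    bool ok = true;
    double ER = nrep[t] * (std::pow(FR[t], alpha[i]) + beta[i]);
    double ET = std::pow(FT[t], alpha[i]) + beta[i];
    double z = (utility_c(ER, model, ok) - utility_c(ET, model, ok)) / gamma[i];
    out[t] = (ok && R_finite(z)) ? R::pnorm(z, 0.0, 1.0, choice[t], 1)
                                 : R_NegInf;
  }
  return out;
}

// pointwise log-likelihood for every posterior draw (rows) and trial (cols)
// [[Rcpp::export]]
NumericMatrix cpp_loglik_matrix(NumericMatrix alpha_d, NumericMatrix beta_d,
                                NumericMatrix gamma_d, IntegerVector subj,
                                NumericVector FR, NumericVector FT,
                                IntegerVector nrep, IntegerVector choice,
                                int model) {
  int S = alpha_d.nrow(), n = FR.size();
  NumericMatrix out(S, n);
  for (int s = 0; s < S; ++s) {
    for (int t = 0; t < n; ++t) {
      int i = subj[t];
      bool ok = true;
      double a = alpha_d(s, i), b = beta_d(s, i), g = gamma_d(s, i);
      double ER = nrep[t] * (std::pow(FR[t], a) + b);
      double ET = std::pow(FT[t], a) + b;
      double z = (utility_c(ER, model, ok) - utility_c(ET, model, ok)) / g;
      out(s, t) = (ok && R_finite(z)) ? R::pnorm(z, 0.0, 1.0, choice[t], 1)
                                      : R_NegInf;
    }
  }
  return out;
}

// univariate slice sampler, stepping out + shrinkage (Neal 2003)
template <class F>
static double slice_update(F logf, double x0, double w,
                           double lower, double upper) {
  double f0 = logf(x0);
  if (!R_finite(f0)) return x0;
  double logy = f0 - exp_rand();
  double u = unif_rand() * w;
  double L = x0 - u;
  double R = x0 + (w - u);
  int m = 50;
  while (m-- > 0 && L > lower && logf(L) > logy) L -= w;
  if (L < lower) L = lower;
  m = 50;
  while (m-- > 0 && R < upper && logf(R) > logy) R += w;
  if (R > upper) R = upper;
  for (int it = 0; it < 200; ++it) {
    double x1 = L + unif_rand() * (R - L);
    if (logf(x1) > logy) return x1;
    if (x1 < x0) L = x1; else R = x1;
  }
  return x0;
}

// one Gibbs sweep of slice updates over all subjects' (alpha, beta, gamma),
// conditional on the population means/SDs. Trials must be sorted by subject;
// subj_start/subj_len give each subject's block (0-based).
// [[Rcpp::export]]
NumericMatrix cpp_slice_sweep(NumericMatrix params, NumericVector mu,
                              NumericVector sigma, IntegerVector subj_start,
                              IntegerVector subj_len, NumericVector FR,
                              NumericVector FT, IntegerVector nrep,
                              IntegerVector choice, int model,
                              double lower, NumericVector width) {
  RNGScope scope;
  NumericMatrix p = clone(params);
  int nsub = p.nrow();
  for (int i = 0; i < nsub; ++i) {
    const double *fr = &FR[0] + subj_start[i];
    const double *ft = &FT[0] + subj_start[i];
    const int *nr = &nrep[0] + subj_start[i];
    const int *ch = &choice[0] + subj_start[i];
    int n = subj_len[i];
    double a = p(i, 0), b = p(i, 1), g = p(i, 2);
    for (int j = 0; j < 3; ++j) {
      double m_j = mu[j], s_j = sigma[j], w = width[j];
      auto logf = [&](double x) -> double {
        double aa = a, bb = b, gg = g;
        if (j == 0) aa = x; else if (j == 1) bb = x; else gg = x;
        double ll = subject_loglik_c(aa, bb, gg, fr, ft, nr, ch, n, model);
        if (!R_finite(ll)) return R_NegInf;
        double zp = (x - m_j) / s_j;
        return ll - 0.5 * zp * zp;
      };
      double x0 = (j == 0) ? a : (j == 1) ? b : g;
      double x1 = slice_update(logf, x0, w, lower, R_PosInf);
      if (j == 0) a = x1; else if (j == 1) b = x1; else g = x1;
    }
    p(i, 0) = a; p(i, 1) = b; p(i, 2) = g;
  }
  return p;
}
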