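// Weighted Dirichlet-multinomial log-likelihood and gradient in log-alpha
// space: the inner objective of the mixture M-step. Fused loops avoid the
// matrix temporaries a vectorized R implementation would allocate on every
// optimizer evaluation.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
double dm_wobj_cpp(NumericVector la, NumericMatrix X, NumericVector w,
                   NumericVector Nrow) {
  const int n = X.nrow(), J = X.ncol();
  std::vector<double> alpha(J);
  double A = 0.0, lg_alpha_sum = 0.0;
  for (int j = 0; j < J; ++j) {
    alpha[j] = std::exp(la[j]);
    A += alpha[j];
    lg_alpha_sum += R::lgammafn(alpha[j]);
  }
  const double lgA = R::lgammafn(A);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    if (w[i] == 0.0) continue;
    double ll = lgA - R::lgammafn(Nrow[i] + A) - lg_alpha_sum;
    for (int j = 0; j < J; ++j) ll += R::lgammafn(X(i, j) + alpha[j]);
    total += w[i] * ll;
  }
  return -total;
}

// [[Rcpp::export]]
NumericVector dm_wgrad_cpp(NumericVector la, NumericMatrix X, NumericVector w,
                           NumericVector Nrow) {
  const int n = X.nrow(), J = X.ncol();
  std::vector<double> alpha(J);
  double A = 0.0;
  for (int j = 0; j < J; ++j) {
    alpha[j] = std::exp(la[j]);
    A += alpha[j];
  }
  const double digA = R::digamma(A);
  double sw = 0.0, g_common = 0.0;
  NumericVector g(J);
  std::vector<double> dig_alpha(J);
  for (int j = 0; j < J; ++j) dig_alpha[j] = R::digamma(alpha[j]);
  for (int i = 0; i < n; ++i) {
    if (w[i] == 0.0) continue;
    sw += w[i];
    g_common -= w[i] * R::digamma(Nrow[i] + A);
    for (int j = 0; j < J; ++j) g[j] += w[i] * R::digamma(X(i, j) + alpha[j]);
  }
  g_common += sw * digA;
  for (int j = 0; j < J; ++j) {
    g[j] = -(alpha[j] * (g_common + g[j] - sw * dig_alpha[j]));
  }
  return g;
}

// [[Rcpp::export]]
NumericVector dm_rowll_cpp(NumericMatrix X, NumericVector alpha,
                           NumericVector Nrow) {
  const int n = X.nrow(), J = X.ncol();
  double A = 0.0, lg_alpha_sum = 0.0;
  for (int j = 0; j < J; ++j) {
    A += alpha[j];
    lg_alpha_sum += R::lgammafn(alpha[j]);
  }
  const double lgA = R::lgammafn(A);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double ll = lgA - R::lgammafn(Nrow[i] + A) - lg_alpha_sum;
    for (int j = 0; j < J; ++j) ll += R::lgammafn(X(i, j) + alpha[j]);
    out[i] = ll;
  }
  return out;
}
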