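#include <Rcpp.h>
using namespace Rcpp;

// Byte-per-genotype backend for simulating GWAS panels too large to hold as
// doubles (n up to ~1e5 samples). Sampling uses R's RNG so results are
// reproducible under set.seed().

// [[Rcpp::export]]
RawVector sample_geno_raw(int n, NumericVector freq) {
  int p = freq.size();
  RawVector out((R_xlen_t)n * p);
  R_xlen_t k = 0;
  for (int j = 0; j < p; ++j) {
    double f = freq[j];
    double p0 = (1.0 - f) * (1.0 - f);
    double p01 = p0 + 2.0 * f * (1.0 - f);
    for (int i = 0; i < n; ++i, ++k) {
      double u = unif_rand();
      out[k] = (u > p0) + (u > p01);
    }
  }
  return out;
}

// [[Rcpp::export]]
List raw_col_moments(RawVector X, int n, int p) {
  NumericVector mu(p), sd(p);
  R_xlen_t k = 0;
  for (int j = 0; j < p; ++j) {
    long s = 0, ss = 0;
    for (int i = 0; i < n; ++i, ++k) { int g = X[k]; s += g; ss += g * g; }
    mu[j] = (double)s / n;
    sd[j] = sqrt(((double)ss - n * mu[j] * mu[j]) / (n - 1));
  }
  return List::create(_["mean"] = mu, _["sd"] = sd);
}

// X'y (p-vector) on the raw byte matrix
// [[Rcpp::export]]
NumericVector raw_crossprod_vec(RawVector X, int n, int p, NumericVector y) {
  NumericVector out(p);
  R_xlen_t k = 0;
  for (int j = 0; j < p; ++j) {
    double s = 0;
    for (int i = 0; i < n; ++i, ++k) s += (double)X[k] * y[i];
    out[j] = s;
  }
  return out;
}

// X w (n-vector) on the raw byte matrix
// [[Rcpp::export]]
NumericVector raw_prod_vec(RawVector X, int n, int p, NumericVector w) {
  NumericVector out(n);
  R_xlen_t k = 0;
  for (int j = 0; j < p; ++j) {
    double wj = w[j];
    if (wj == 0) { k += n; continue; }
    for (int i = 0; i < n; ++i, ++k) out[i] += (double)X[k] * wj;
  }
  return out;
}
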