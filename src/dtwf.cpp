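// Discrete-time Wright-Fisher core: genic selection with fitness floor,
// one-way mutation, binomial resampling, quasi-stationary initialization
// conditioned on non-fixation, and piecewise-constant demography.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// post-selection, post-mutation allele frequency for a source frequency f
static inline double freq_after(double f, double s, double mu) {
  double w = 1.0 - s;
  if (w < 0.0) w = 0.0;
  double fp;
  if (f >= 1.0) {
    fp = 1.0; // fixed class retained (degenerate case: zero normalizer)
  } else {
    double num = f * w;
    fp = num / (num + (1.0 - f));
  }
  return fp + (1.0 - fp) * mu;
}

// Fill out[0..n] with Binomial(n, p) pmf using a two-sided recurrence from
// the mode; one log-scale anchor avoids per-entry exp. Entries that underflow
// double range are set to 0.
static void binom_row(int n, double p, double* out) {
  if (p <= 0.0) {
    for (int j = 0; j <= n; ++j) out[j] = 0.0;
    out[0] = 1.0;
    return;
  }
  if (p >= 1.0) {
    for (int j = 0; j <= n; ++j) out[j] = 0.0;
    out[n] = 1.0;
    return;
  }
  int m = (int)std::floor((n + 1) * p);
  if (m > n) m = n;
  double lanchor = R::dbinom((double)m, (double)n, p, 1);
  double anchor = std::exp(lanchor);
  out[m] = anchor;
  double odds = p / (1.0 - p);
  double val = anchor;
  for (int j = m; j < n; ++j) { // upward
    val *= odds * (double)(n - j) / (double)(j + 1);
    out[j + 1] = val;
  }
  val = anchor;
  for (int j = m; j > 0; --j) { // downward
    val *= (double)j / (odds * (double)(n - j + 1));
    out[j - 1] = val;
  }
}

// Transposed transition matrix between populations of haploid size
// twoNfrom -> twoNto: column i holds the offspring pmf of source count i,
// so the fill is contiguous in memory and one generation is Tt * v.
static arma::mat transition_matrix_t(int twoNfrom, int twoNto, double s,
                                     double mu) {
  arma::mat Tt(twoNto + 1, twoNfrom + 1);
  for (int i = 0; i <= twoNfrom; ++i) {
    double p = freq_after((double)i / (double)twoNfrom, s, mu);
    binom_row(twoNto, p, Tt.colptr(i));
  }
  return Tt;
}

// [[Rcpp::export]]
NumericMatrix cpp_transition_matrix(int twoNfrom, int twoNto, double s,
                                    double mu) {
  arma::mat T = transition_matrix_t(twoNfrom, twoNto, s, mu).t();
  return wrap(T);
}

// [[Rcpp::export]]
NumericVector cpp_dtwf_step(NumericVector v, double s, double mu,
                            int twoNto) {
  int twoNfrom = v.size() - 1;
  std::vector<double> row(twoNto + 1);
  NumericVector out(twoNto + 1);
  for (int i = 0; i <= twoNfrom; ++i) {
    double vi = v[i];
    if (vi == 0.0) continue;
    double p = freq_after((double)i / (double)twoNfrom, s, mu);
    binom_row(twoNto, p, row.data());
    for (int j = 0; j <= twoNto; ++j) out[j] += vi * row[j];
  }
  return out;
}

static double tv_dist(const arma::rowvec& a, const arma::rowvec& b) {
  return 0.5 * arma::accu(arma::abs(a - b));
}

// Quasi-stationary distribution of the chain conditioned on non-fixation
// (the fixed class at count 2N is absorbing under one-way mutation).
// Power iteration over doubling horizons, then single-step polish until the
// conditioned one-generation update leaves the distribution invariant to
// within tol in total variation. Errors if the generation cap is exceeded.
static arma::rowvec quasi_stationary(int N, double s, double mu, double tol,
                                     int capFactor) {
  int twoN = 2 * N;
  long cap = (long)capFactor * (long)twoN;
  // substochastic matrix over segregating-or-absent states 0..twoN-1
  arma::mat M(twoN, twoN);
  std::vector<double> row(twoN + 1);
  for (int i = 0; i < twoN; ++i) {
    double p = freq_after((double)i / (double)twoN, s, mu);
    binom_row(twoN, p, row.data());
    for (int j = 0; j < twoN; ++j) M(i, j) = row[j];
  }
  arma::rowvec v0(twoN, arma::fill::zeros);
  v0[0] = 1.0;
  arma::rowvec v = v0 * M;
  v /= arma::accu(v);
  long t = 1;
  arma::mat A = M;
  bool converged = false;
  while (!converged) {
    if (2 * t > cap) break;
    A = A * A;
    double mx = A.max();
    if (mx > 0) A /= mx; // guard against underflow over long horizons
    t *= 2;
    arma::rowvec vn = v0 * A;
    double sm = arma::accu(vn);
    if (!(sm > 0.0) || !vn.is_finite())
      stop("quasi-stationary iteration degenerated (N=%d, s=%g, mu=%g)", N, s,
           mu);
    vn /= sm;
    if (tv_dist(vn, v) < tol) converged = true;
    v = vn;
  }
  // polish with single conditioned generations; certifies the invariance
  // post-condition at tol
  bool invariant = false;
  while (t <= cap) {
    arma::rowvec vn = v * M;
    vn /= arma::accu(vn);
    ++t;
    if (tv_dist(vn, v) < tol) {
      v = vn;
      invariant = true;
      break;
    }
    v = vn;
  }
  if (!invariant)
    stop(
        "quasi-stationary distribution did not converge within %ld "
        "generations (N=%d, s=%g, mu=%g, tol=%g)",
        cap, N, s, mu, tol);
  arma::rowvec out(twoN + 1, arma::fill::zeros);
  out.head(twoN) = v;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_quasi_stationary(int N, double s, double mu, double tol,
                                   int capFactor) {
  arma::rowvec v = quasi_stationary(N, s, mu, tol, capFactor);
  return wrap(arma::vec(v.t()));
}

// Evolve from the oldest epoch's quasi-stationary distribution through all
// later epochs; returns the present-day allele-count distribution.
static arma::rowvec evolve_epochs(double s, double mu, IntegerVector durations,
                                  IntegerVector sizes, double tol,
                                  int capFactor) {
  int E = sizes.size();
  arma::rowvec v = quasi_stationary(sizes[0], s, mu, tol, capFactor);
  int twoNprev = 2 * sizes[0];
  std::vector<double> rowbuf;
  for (int e = 1; e < E; ++e) {
    int twoN = 2 * sizes[e];
    rowbuf.resize(twoN + 1);
    // first generation of the epoch (may change population size)
    arma::rowvec w(twoN + 1, arma::fill::zeros);
    for (int i = 0; i <= twoNprev; ++i) {
      double vi = v[i];
      if (vi == 0.0) continue;
      double p = freq_after((double)i / (double)twoNprev, s, mu);
      binom_row(twoN, p, rowbuf.data());
      for (int j = 0; j <= twoN; ++j) w[j] += vi * rowbuf[j];
    }
    int rest = durations[e] - 1;
    if (rest > 0) {
      arma::mat Tt = transition_matrix_t(twoN, twoN, s, mu);
      arma::vec wc = w.t();
      for (int g = 0; g < rest; ++g) wc = Tt * wc;
      w = wc.t();
    }
    v = w;
    twoNprev = twoN;
  }
  return v;
}

// Present-day allele-count distributions for a vector of selection
// coefficients (columns) under a shared mutation rate and demography.
// [[Rcpp::export]]
NumericMatrix cpp_present_dists(NumericVector svals, double mu,
                                IntegerVector durations, IntegerVector sizes,
                                double tol, int capFactor) {
  int E = sizes.size();
  int twoN = 2 * sizes[E - 1];
  int K = svals.size();
  NumericMatrix out(twoN + 1, K);
  for (int k = 0; k < K; ++k) {
    arma::rowvec v =
        evolve_epochs(svals[k], mu, durations, sizes, tol, capFactor);
    for (int j = 0; j <= twoN; ++j) out(j, k) = v[j];
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// vectorized post-selection post-mutation frequency (used by the forward
// simulator so the simulated dynamics share one definition with the matrix)
// [[Rcpp::export]]
NumericVector cpp_freq_after(NumericVector f, double s, double mu) {
  int n = f.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = freq_after(f[i], s, mu);
  return out;
}
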