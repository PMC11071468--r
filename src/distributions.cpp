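#include <Rcpp.h>
using namespace Rcpp;

// Chinese-restaurant-table draw: l = sum_{i=1..n} Bernoulli(r / (r + i - 1)).
// Used for the conjugate Gamma update of negative-binomial shape parameters.
// [[Rcpp::export(name = ".crt_sample_cpp")]]
IntegerVector crt_sample_cpp(IntegerVector n, NumericVector r) {
  R_xlen_t len = n.size();
  if (r.size() != len && r.size() != 1)
    stop("r must have length 1 or length(n)");
  IntegerVector out(len);
  for (R_xlen_t i = 0; i < len; ++i) {
    int ni = n[i];
    if (ni < 0) stop("negative count in CRT draw");
    double ri = (r.size() == 1) ? r[0] : r[i];
    if (!(ri > 0)) stop("CRT rate must be positive");
    int l = 0;
    for (int j = 0; j < ni; ++j) {
      if (unif_rand() < ri / (ri + j)) ++l;
    }
    out[i] = l;
  }
  return out;
}

static inline double pg_mean(double b, double c) {
  double ac = std::fabs(c);
  if (ac < 1e-6) return b / 4.0 - b * c * c / 48.0;  // series about c = 0
  return b / (2.0 * c) * std::tanh(c / 2.0);
}

static inline double pg_var(double b, double c) {
  double ac = std::fabs(c);
  if (ac < 1e-4) return b / 24.0;
  double ch = std::cosh(c / 2.0);
  return b * (std::sinh(ac) - ac) / (4.0 * ac * ac * ac * ch * ch);
}

// One Polya-Gamma draw.  For b < 30: truncated sum-of-Gammas representation
//   PG(b, c) = 1/(2 pi^2) sum_k Gamma(b, 1) / ((k - 1/2)^2 + c^2 / (4 pi^2))
// with a deterministic correction equal to the mean of the dropped tail.
// For b >= 30 a moment-matched Normal (mean/variance exact in closed form).
static double pg_draw_one(double b, double c, int trunc) {
  if (!(b > 0)) stop("PG shape must be positive");
  if (b >= 30.0) {
    double m = pg_mean(b, c), s = std::sqrt(pg_var(b, c));
    double x = m + s * norm_rand();
    return x > 0 ? x : m;  // negative draws are ~impossible at this shape
  }
  const double pi2 = M_PI * M_PI;
  double a = c * c / (4.0 * pi2);
  double acc = 0.0;
  for (int k = 1; k <= trunc; ++k) {
    double d = (k - 0.5) * (k - 0.5) + a;
    acc += R::rgamma(b, 1.0) / d;
  }
  // tail mean: b/(2 pi^2) * integral_{trunc}^{inf} dx / ((x - 1/2)^2 + a)
  double tail;
  if (a > 1e-12) {
    double sa = std::sqrt(a);
    tail = b * (M_PI / 2.0 - std::atan((trunc - 0.5) / sa)) / sa;
  } else {
    tail = b / (trunc - 0.5);
  }
  return (acc + tail) / (2.0 * pi2);
}

// Vectorized PG(b, c) sampling (recycles b or c of length 1).
// [[Rcpp::export(name = ".pg_sample_cpp")]]
NumericVector pg_sample_cpp(NumericVector b, NumericVector c, int trunc = 200) {
  R_xlen_t len = std::max(b.size(), c.size());
  if ((b.size() != len && b.size() != 1) || (c.size() != len && c.size() != 1))
    stop("b and c must be recyclable to a common length");
  NumericVector out(len);
  for (R_xlen_t i = 0; i < len; ++i) {
    double bi = (b.size() == 1) ? b[0] : b[i];
    double ci = (c.size() == 1) ? c[0] : c[i];
    out[i] = pg_draw_one(bi, ci, trunc);
  }
  return out;
}
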