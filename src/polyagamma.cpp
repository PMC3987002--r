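// Devroye-type exact sampler for Polya-Gamma PG(1, z) random variates,
// used for the auxiliary-variable augmentation of the Bernoulli-logit
// likelihood.  Uses R's RNG so draws are reproducible under set.seed().
#include <Rcpp.h>
using namespace Rcpp;

static const double TRUNC = 0.64;

// Jacobi-theta alternating-series coefficients a_n(x)
static double a_coef(int n, double x) {
  double k = n + 0.5;
  if (x > TRUNC) {
    return M_PI * k * std::exp(-k * k * M_PI * M_PI * x / 2.0);
  } else {
    return std::pow(2.0 / (M_PI * x), 1.5) * M_PI * k *
           std::exp(-2.0 * k * k / x);
  }
}

// CDF of inverse-Gaussian(mu = 1/z, lambda = 1) at x, z >= 0
static double pigauss(double x, double z) {
  double rx = 1.0 / std::sqrt(x);
  double p = R::pnorm(rx * (x * z - 1.0), 0.0, 1.0, 1, 0);
  double q = R::pnorm(-rx * (x * z + 1.0), 0.0, 1.0, 1, 0);
  return p + std::exp(2.0 * z) * q;
}

// Inverse-Gaussian(1/z, 1) truncated to (0, TRUNC]
static double rtigauss(double z) {
  double t = TRUNC;
  double x = t + 1.0;
  if (1.0 / z > t) {
    // rejection via truncated chi-squared proposal (small-mu regime)
    double alpha = 0.0;
    while (unif_rand() > alpha) {
      double e1, e2;
      do {
        e1 = exp_rand();
        e2 = exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  } else {
    double mu = 1.0 / z;
    while (x > t) {
      double y = norm_rand();
      y = y * y;
      double muy = mu * y;
      x = mu + 0.5 * mu * muy -
          0.5 * mu * std::sqrt(4.0 * muy + muy * muy);
      if (unif_rand() > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

static double rpg1(double zin) {
  double z = std::fabs(zin) * 0.5;
  double fz = M_PI * M_PI / 8.0 + z * z / 2.0;
  // mixture masses of the two proposal pieces
  double p = (0.5 * M_PI / fz) * std::exp(-fz * TRUNC);
  double q = 2.0 * std::exp(-z) * pigauss(TRUNC, z);

  for (;;) {
    double x;
    if (unif_rand() * (p + q) < p) {
      x = TRUNC + exp_rand() / fz;
    } else {
      x = rtigauss(z);
    }
    // squeeze accept/reject on the alternating series
    double s = a_coef(0, x);
    double y = unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return x / 4.0;
      } else {
        s += a_coef(n, x);
        if (y > s) break;
      }
    }
  }
}

//' Draw Polya-Gamma PG(1, z) variates
//'
//' Exact sampler for the Polya-Gamma distribution with shape 1, used as
//' the data augmentation for Bernoulli-logit likelihoods.
//'
//' @param z numeric vector of tilting parameters (one draw per element).
//' @return numeric vector of PG(1, z) draws, same length as `z`.
//' @keywords internal
// [[Rcpp::export]]
NumericVector rpg_devroye(NumericVector z) {
  int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(z[i]);
  return out;
}
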