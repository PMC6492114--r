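// Compiled kernels for voxelwise fitting and restricted-diffusion signals.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace Rcpp;

// GPD (Murday-Cotts) PGSE attenuation for spins restricted in an impermeable
// sphere of radius R.  `roots` are the positive roots x_m of
// (x^2 - 2) sin x + 2 x cos x = 0 (derivative condition of the first-order
// spherical Bessel function); alpha_m = x_m / R.
//
//   ln S = -2 g^2 G^2 sum_m [ 2 d a^2 dl - 2 + 2 e^{-d a^2 dl} + 2 e^{-d a^2 DL}
//                             - e^{-d a^2 (DL - dl)} - e^{-d a^2 (DL + dl)} ]
//                           / ( d^2 a^6 (a^2 R^2 - 2) )
//
// with a = alpha_m, dl = delta (pulse duration), DL = Delta (separation).
// [[Rcpp::export]]
NumericVector cpp_sphere_gpd(double R, double d,
                             NumericVector G, NumericVector big_delta,
                             NumericVector small_delta, double gamma,
                             NumericVector roots) {
  const int n = G.size();
  NumericVector out(n);
  if (R <= 1e-12) {          // vanishing radius: no dephasing
    std::fill(out.begin(), out.end(), 1.0);
    return out;
  }
  const int nr = roots.size();
  // measurements sharing (Delta, delta) reuse the series sum; G enters only
  // through the prefactor
  std::vector<double> uDL, udl, usum;
  for (int i = 0; i < n; ++i) {
    if (G[i] == 0.0) { out[i] = 1.0; continue; }
    const double DL = big_delta[i], dl = small_delta[i];
    double s = -1.0;
    for (size_t k = 0; k < uDL.size(); ++k)
      if (uDL[k] == DL && udl[k] == dl) { s = usum[k]; break; }
    if (s < 0.0) {
      s = 0.0;
      for (int m = 0; m < nr; ++m) {
        const double a2 = roots[m] * roots[m] / (R * R);
        const double da2 = d * a2;
        const double ed = std::exp(-da2 * dl), eD = std::exp(-da2 * DL);
        const double num = 2.0 * da2 * dl - 2.0
          + 2.0 * ed + 2.0 * eD - std::exp(-da2 * (DL - dl)) - eD * ed;
        const double den = d * d * a2 * a2 * a2 * (a2 * R * R - 2.0);
        s += num / den;
      }
      uDL.push_back(DL); udl.push_back(dl); usum.push_back(s);
    }
    out[i] = std::exp(-2.0 * gamma * gamma * G[i] * G[i] * s);
  }
  return out;
}

// Lawson-Hanson active-set nonnegative least squares: min ||A x - b||_2, x >= 0.
// [[Rcpp::export]]
List cpp_nnls(const arma::mat& A, const arma::vec& b,
              double tol = -1.0, int max_iter = 300) {
  const arma::uword n = A.n_cols;
  arma::vec x(n, arma::fill::zeros);
  std::vector<bool> passive(n, false);
  arma::vec w = A.t() * (b - A * x);
  if (tol < 0) tol = 10.0 * std::numeric_limits<double>::epsilon() *
    arma::norm(A, 1) * static_cast<double>(A.n_rows);
  int iter = 0;
  while (iter < max_iter) {
    // most positive gradient among active (zero) coordinates
    int t = -1; double wmax = tol;
    for (arma::uword j = 0; j < n; ++j)
      if (!passive[j] && w[j] > wmax) { wmax = w[j]; t = (int)j; }
    if (t < 0) break;
    passive[t] = true;
    while (true) {
      ++iter;
      arma::uvec P;
      { std::vector<arma::uword> idx;
        for (arma::uword j = 0; j < n; ++j) if (passive[j]) idx.push_back(j);
        P = arma::uvec(idx); }
      arma::vec z(n, arma::fill::zeros);
      arma::vec zp = arma::solve(A.cols(P), b,
                                 arma::solve_opts::fast + arma::solve_opts::no_approx);
      z.elem(P) = zp;
      if (zp.min() > 0) { x = z; break; }
      // step toward z until a passive coordinate hits zero
      double alpha = std::numeric_limits<double>::max();
      for (arma::uword k = 0; k < P.n_elem; ++k) {
        const arma::uword j = P[k];
        if (z[j] <= 0) {
          const double a = x[j] / (x[j] - z[j]);
          if (a < alpha) alpha = a;
        }
      }
      x += alpha * (z - x);
      for (arma::uword j = 0; j < n; ++j)
        if (passive[j] && x[j] <= 1e-14) { x[j] = 0.0; passive[j] = false; }
      if (iter >= max_iter) break;
    }
    w = A.t() * (b - A * x);
  }
  const double rn = arma::norm(b - A * x);
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["resnorm"] = rn, _["iterations"] = iter);
}

// Residual vector for the constrained non-linear fit, evaluated in the
// unconstrained parameterization: theta = (t1, t2, t3[, t4]) with
// f_IC = cos^2 t1, f_EES = sin^2 t1 cos^2 t2, f_VASC = sin^2 t1 sin^2 t2,
// R = rmin + (rmax - rmin) * logistic(t3) and, when free_d, d_EES =
// dmin + (dmax - dmin) * logistic(t4).  `astro` is the precomputed
// astrosticks signal per measurement.  Residuals are y - S (sigma = 0) or
// (y - sqrt(S^2 + sigma^2)) / sigma.
// [[Rcpp::export]]
NumericVector cpp_nlls_resid(NumericVector theta, NumericVector y,
                             double sigma, bool free_d,
                             NumericVector G, NumericVector big_delta,
                             NumericVector small_delta, double gamma,
                             NumericVector roots, NumericVector b,
                             NumericVector astro, LogicalVector is_b0,
                             double rmin, double rmax, double d_ic,
                             double d_ees_fixed, double dmin, double dmax) {
  const double c1 = std::cos(theta[0]), s1 = std::sin(theta[0]);
  const double c2 = std::cos(theta[1]), s2 = std::sin(theta[1]);
  const double f_ic = c1 * c1;
  const double f_ees = s1 * s1 * c2 * c2;
  const double f_vasc = s1 * s1 * s2 * s2;
  const double R = rmin + (rmax - rmin) / (1.0 + std::exp(-theta[2]));
  const double d_ees = free_d
    ? dmin + (dmax - dmin) / (1.0 + std::exp(-theta[3])) : d_ees_fixed;
  NumericVector sph = cpp_sphere_gpd(R, d_ic, G, big_delta, small_delta,
                                     gamma, roots);
  const int n = y.size();
  NumericVector r(n);
  for (int i = 0; i < n; ++i) {
    double s;
    if (is_b0[i]) s = 1.0;
    else s = f_ic * sph[i] + f_ees * std::exp(-b[i] * d_ees) + f_vasc * astro[i];
    if (sigma == 0.0) r[i] = y[i] - s;
    else r[i] = (y[i] - std::sqrt(s * s + sigma * sigma)) / sigma;
  }
  return r;
}

// Monte-Carlo random walk of spins inside an impermeable sphere under a PGSE
// gradient along z; returns the magnitude signal E[cos(phi)].  Radial mirror
// reflection at the boundary; uniform initial positions; fixed time step dt.
// [[Rcpp::export]]
double cpp_mc_sphere(double R, double d, double G,
                     double big_delta, double small_delta, double gamma,
                     int n_walkers, double dt, int seed) {
  if (G == 0.0) return 1.0;
  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::normal_distribution<double> gauss(0.0, 1.0);
  std::uniform_real_distribution<double> unif(-1.0, 1.0);
  const double T = big_delta + small_delta;
  const int n_steps = (int)std::ceil(T / dt);
  const double step_sd = std::sqrt(2.0 * d * dt);
  double sum_cos = 0.0;
  for (int wk = 0; wk < n_walkers; ++wk) {
    double x, y, z;
    do {  // uniform in sphere by rejection
      x = unif(rng) * R; y = unif(rng) * R; z = unif(rng) * R;
    } while (x * x + y * y + z * z > R * R);
    double phase = 0.0;
    double t = 0.0;
    for (int s = 0; s < n_steps; ++s) {
      const double h = std::min(dt, T - t);
      // gradient waveform: +G on [0, delta), -G on [Delta, Delta+delta)
      double g = 0.0;
      const double tm = t + 0.5 * h;   // midpoint rule
      if (tm < small_delta) g = G;
      else if (tm >= big_delta && tm < big_delta + small_delta) g = -G;
      if (g != 0.0) phase += gamma * g * z * h;
      x += step_sd * gauss(rng);
      y += step_sd * gauss(rng);
      z += step_sd * gauss(rng);
      const double r2 = x * x + y * y + z * z;
      if (r2 > R * R) {  // mirror about the surface along the radius
        const double r = std::sqrt(r2);
        const double f = (2.0 * R - r) / r;
        x *= f; y *= f; z *= f;
      }
      t += h;
    }
    sum_cos += std::cos(phase);
  }
  return sum_cos / n_walkers;
}
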