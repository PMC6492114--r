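# Signal models for the three VERDICT water compartments: restricted sphere
# (intracellular), isotropic ball (extracellular-extravascular) and
# astrosticks (vascular pseudo-diffusion).  All signals are normalized to the
# b = 0 measurement, so every model returns exactly 1 where |G| = 0.

# Fixed diffusivities of the prostate VERDICT model (m^2/s).
D_IC_FIXED  <- 2e-9
D_EES_FIXED <- 2e-9
P_VASC_FIXED <- 8e-9

# Radius bounds spanned by the dictionary and the non-linear fit (m).
R_MIN <- 0.01e-6
R_MAX <- 15.1e-6

.verdict_env <- new.env(parent = emptyenv())

#' Roots of the sphere GPD eigenvalue condition
#'
#' Positive roots x_m of (x^2 - 2) sin(x) + 2 x cos(x) = 0, the derivative
#' condition of the first-order spherical Bessel function. The first root is
#' approximately 2.0816. Roots are found by bracketed bisection
#' (`stats::uniroot`) on a sign-change scan and cached per session.
#'
#' @param n Number of roots (default 100, the truncation used throughout).
#' @return Strictly increasing numeric vector of length `n`.
#' @export
sphere_roots <- function(n = 100) {
  key <- as.character(n)
  cached <- .verdict_env$roots
  if (!is.null(cached) && length(cached) >= n) return(cached[seq_len(n)])
  g <- function(x) (x^2 - 2) * sin(x) + 2 * x * cos(x)
  xs <- seq(1e-3, (n + 2) * pi, length.out = 200 * (n + 2))
  gs <- g(xs)
  idx <- which(gs[-1] * gs[-length(gs)] < 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(g, c(xs[i], xs[i + 1]), tol = 1e-14)$root
  }, numeric(1))
  roots <- roots[roots > 1e-6]
  if (length(roots) < n) abort("failed to bracket enough sphere roots")
  roots <- roots[seq_len(n)]
  .verdict_env$roots <- roots
  roots
}

#' Ball compartment signal
#'
#' Free isotropic Gaussian diffusion: S = exp(-b d). Direction-independent
#' because the diffusion tensor is isotropic.
#'
#' @param b b-value(s), s/m^2.
#' @param d Diffusivity, m^2/s.
#' @return Signal in (0, 1]; exactly 1 at b = 0.
#' @export
ball_signal <- function(b, d = D_EES_FIXED) {
  if (d <= 0) abort("ball diffusivity must be positive")
  if (any(b < 0)) abort("b-values must be nonnegative")
  exp(-b * d)
}

#' Astrosticks compartment signal
#'
#' Orientation average of stick signals exp(-b P (n . g)^2) over the uniform
#' sphere, which reduces analytically to
#' S = sqrt(pi) * erf(sqrt(bP)) / (2 sqrt(bP)).
#'
#' @param b b-value(s), s/m^2.
#' @param p Pseudo-diffusivity P, m^2/s.
#' @return Signal in (0, 1]; 1 in the bP -> 0 limit.
#' @export
astrosticks_signal <- function(b, p = P_VASC_FIXED) {
  if (p <= 0) abort("astrosticks pseudo-diffusivity must be positive")
  if (any(b < 0)) abort("b-values must be nonnegative")
  u <- b * p
  out <- numeric(length(u))
  small <- u < 1e-8
  # series of (1/2) int_{-1}^{1} exp(-u t^2) dt about u = 0
  out[small] <- 1 - u[small] / 3
  su <- sqrt(u[!small])
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  out[!small] <- sqrt(pi) * erf(su) / (2 * su)
  out
}

#' Restricted sphere (GPD) compartment signal
#'
#' PGSE attenuation of spins inside an impermeable sphere of radius `radius`
#' under the Gaussian phase distribution approximation (Murday-Cotts series),
#' truncated at `n_roots` terms. Direction-independent.
#'
#' @param protocol A `pgse_protocol` (or data frame with `gradient`,
#'   `big_delta`, `small_delta` columns).
#' @param radius Sphere radius (m); `radius = 0` is the no-attenuation limit.
#' @param d Intracellular diffusivity (m^2/s).
#' @param n_roots Series truncation (default 100).
#' @return Signal vector in (0, 1], one entry per measurement; exactly 1 at
#'   |G| = 0.
#' @export
sphere_signal <- function(protocol, radius, d = D_IC_FIXED, n_roots = 100) {
  if (radius < 0) abort("sphere radius must be nonnegative")
  if (d <= 0) abort("intracellular diffusivity must be positive")
  gamma <- attr(protocol, "gamma") %||% GAMMA_PROTON
  cpp_sphere_gpd(radius, d, protocol$gradient, protocol$big_delta,
                 protocol$small_delta, gamma, sphere_roots(n_roots))
}

#' Monte-Carlo oracle for restricted sphere diffusion
#'
#' Unbiased random-walk estimate of the PGSE magnitude signal for spins in an
#' impermeable sphere, used to validate the GPD series. Walkers start
#' uniformly in the sphere, take Gaussian steps with mirror reflection at the
#' boundary, and accumulate phase under the two gradient pulses.
#'
#' @param radius Sphere radius (m).
#' @param d Diffusivity (m^2/s).
#' @param gradient,big_delta,small_delta Scalar PGSE parameters (SI).
#' @param n_walkers Number of walkers (>= 1e4).
#' @param seed Integer seed; identical seeds give identical output.
#' @param dt Time step (s); default chosen so the RMS step is radius/20.
#' @param gamma Gyromagnetic ratio.
#' @return Scalar signal estimate.
#' @export
mc_sphere_signal <- function(radius, d, gradient, big_delta, small_delta,
                             n_walkers = 1e5, seed = 1, dt = NULL,
                             gamma = GAMMA_PROTON) {
  if (n_walkers < 1e4) abort("use at least 1e4 walkers for a usable estimate")
  if (is.null(dt)) dt <- (radius / 20)^2 / (6 * d)
  step <- sqrt(6 * d * dt)
  if (step > radius / 8) {
    warn("MC step length is coarse relative to the sphere radius; estimate may be biased")
  }
  cpp_mc_sphere(radius, d, gradient, big_delta, small_delta, gamma,
                as.integer(n_walkers), dt, as.integer(seed))
}

#' Three-compartment VERDICT signal
#'
#' Forward model S = f_IC S_sphere + f_EES S_ball + f_VASC S_astrosticks per
#' measurement; b = 0 entries are exactly 1 by the normalization convention.
#'
#' @param protocol A `pgse_protocol`.
#' @param f_ic,f_ees,f_vasc Signal fractions; must be nonnegative and sum
#'   to 1 (within 1e-9).
#' @param radius Cell radius (m).
#' @param d_ic,d_ees,p Compartment diffusivities (m^2/s).
#' @param n_roots GPD series truncation.
#' @return Numeric signal vector, one entry per protocol row.
#' @export
verdict_signal <- function(protocol, f_ic, f_ees, f_vasc = 1 - f_ic - f_ees,
                           radius = 8e-6, d_ic = D_IC_FIXED,
                           d_ees = D_EES_FIXED, p = P_VASC_FIXED,
                           n_roots = 100) {
  f <- c(f_ic, f_ees, f_vasc)
  if (any(f < -1e-12) || abs(sum(f) - 1) > 1e-9) {
    abort("signal fractions must be nonnegative and sum to 1")
  }
  s <- f_ic * sphere_signal(protocol, radius, d_ic, n_roots) +
    f_ees * ball_signal(protocol$b, d_ees) +
    f_vasc * astrosticks_signal(protocol$b, p)
  s[protocol$is_b0] <- 1
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
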