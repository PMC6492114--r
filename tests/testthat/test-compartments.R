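test_that("ball signal is the isotropic exponential decay", {
  expect_identical(ball_signal(0, 2e-9), 1)
  # closed form: exp(-b d) with b d = 4
  expect_equal(ball_signal(2e9, 2e-9), exp(-4), tolerance = 1e-15)
  expect_error(ball_signal(1e9, -1e-9), "positive")
})

test_that("astrosticks analytic form equals the spherical quadrature", {
  # oracle: (1/2) int_{-1}^{1} exp(-bP t^2) dt by adaptive quadrature
  quad <- function(u) {
    stats::integrate(function(t) exp(-u * t^2), -1, 1,
                     rel.tol = 1e-13, abs.tol = 1e-14)$value / 2
  }
  u <- c(0, 1e-6, 0.01, 0.5, 1, 2, 4, 8, 15, 30, 50)
  analytic <- astrosticks_signal(u / 8e-9, 8e-9)
  numeric <- vapply(u, quad, numeric(1))
  expect_lt(max(abs(analytic - numeric)), 1e-9)
  # frozen spot value at bP = 4 (quadrature oracle)
  expect_equal(analytic[u == 4], 0.4410407, tolerance = 1e-6)
  # averaging exp(-bP t^2) with t^2 <= 1 bounds the signal from below
  expect_true(all(analytic >= exp(-u) - 1e-12))
})

test_that("sphere GPD signal has the correct limits and monotonicity", {
  p <- fix_protocol()
  # no gradient: exactly 1
  expect_true(all(sphere_signal(p, 8e-6)[p$is_b0] == 1))
  # vanishing radius: negligible dephasing on the strongest shell
  i3000 <- which(!p$is_b0 & p$b > 2.9e9)[1]
  expect_gt(sphere_signal(p, 0.01e-6)[i3000], 0.999)
  # all signals in (0, 1]
  for (r in c(0.01, 3, 8, 15.1) * 1e-6) {
    s <- sphere_signal(p, r)
    expect_true(all(s > 0 & s <= 1))
  }
  # non-increasing in R at every diffusion-weighted measurement
  radii <- seq(0.01e-6, 15.1e-6, length.out = 25)
  sig <- vapply(radii, function(r) sphere_signal(p, r), numeric(nrow(p)))
  dw <- which(!p$is_b0)
  expect_true(all(apply(sig[dw, ], 1, function(x) all(diff(x) <= 1e-12))))
  # non-increasing in |G| at fixed timings
  row <- p[i3000, ]
  gs <- seq(0, 80e-3, length.out = 10)
  q <- pgse_protocol(tibble::tibble(
    gx = 1, gy = 0, gz = 0, gradient = gs,
    big_delta = row$big_delta, small_delta = row$small_delta, te = row$te))
  expect_true(all(diff(sphere_signal(q, 8e-6)) <= 0))
})

test_that("sphere eigenvalue roots match the Bessel derivative condition", {
  r <- sphere_roots(100)
  expect_length(r, 100)
  expect_equal(r[1], 2.0816, tolerance = 1e-4)
  expect_true(all(diff(r) > 0))
  # every root satisfies (x^2 - 2) sin x + 2 x cos x = 0
  expect_lt(max(abs((r^2 - 2) * sin(r) + 2 * r * cos(r))), 1e-8)
})

test_that("GPD series agrees with the Monte-Carlo walker oracle", {
  p <- fix_protocol()
  i500 <- which(!p$is_b0 & p$b > 4e8 & p$b < 6e8)[1]
  row <- p[i500, ]
  gpd <- sphere_signal(p, 8e-6)[i500]
  mc <- mc_sphere_signal(8e-6, 2e-9, row$gradient, row$big_delta,
                         row$small_delta, n_walkers = 2e4, seed = 42,
                         dt = (8e-6 / 15)^2 / (6 * 2e-9))
  expect_lt(abs(gpd - mc) / mc, 0.02)
})

test_that("Monte-Carlo oracle is deterministic and recovers free diffusion", {
  p <- fix_protocol()
  row <- p[1, ]  # b = 90 shell: short diffusion time
  a <- mc_sphere_signal(8e-6, 2e-9, row$gradient, row$big_delta,
                        row$small_delta, n_walkers = 1e4, seed = 7)
  b <- mc_sphere_signal(8e-6, 2e-9, row$gradient, row$big_delta,
                        row$small_delta, n_walkers = 1e4, seed = 7)
  expect_identical(a, b)
  expect_identical(mc_sphere_signal(8e-6, 2e-9, 0, row$big_delta,
                                    row$small_delta, n_walkers = 1e4,
                                    seed = 1), 1)
  # huge sphere, short Delta: free-diffusion limit exp(-b d)
  free <- exp(-row$b * 2e-9)
  mc <- suppressWarnings(
    mc_sphere_signal(150e-6, 2e-9, row$gradient, row$big_delta,
                     row$small_delta, n_walkers = 2e4, seed = 3,
                     dt = 2e-4))
  expect_lt(abs(mc - free) / free, 0.02)
  expect_error(mc_sphere_signal(8e-6, 2e-9, 0.04, 0.03, 0.01,
                                n_walkers = 100), "1e4")
})

test_that("the three-compartment signal recomposes its parts", {
  p <- fix_protocol()
  s <- verdict_signal(p, f_ic = 0.4, f_ees = 0.35, f_vasc = 0.25,
                      radius = 6e-6)
  manual <- 0.4 * sphere_signal(p, 6e-6) + 0.35 * ball_signal(p$b, 2e-9) +
    0.25 * astrosticks_signal(p$b, 8e-9)
  manual[p$is_b0] <- 1
  expect_equal(s, manual, tolerance = 1e-13)
  expect_lt(max(abs(s - manual)), 1e-12)
  expect_true(all(s > 0 & s <= 1))
  # single-compartment limit and b0 normalization
  expect_equal(verdict_signal(p, 0, 1, 0), {
    x <- ball_signal(p$b, 2e-9); x[p$is_b0] <- 1; x
  })
  expect_true(all(verdict_signal(p, 0.5, 0.5, 0)[p$is_b0] == 1))
  # fractions off the simplex are rejected
  expect_error(verdict_signal(p, 0.8, 0.5, 0.2), "sum to 1")
  expect_error(verdict_signal(p, -0.1, 0.6, 0.5), "nonnegative|sum to 1")
})
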