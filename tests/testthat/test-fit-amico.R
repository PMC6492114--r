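test_that("unregularized NNLS recovers single atoms and the zero signal", {
  d <- fix_dictionary()
  for (j in c(1, 8, 18, 19)) {
    x <- solve_rnnls(d, d$phi[, j], lambda = 0)$x
    expect_lt(max(abs(x - replace(numeric(19), j, 1))), 1e-8)
  }
  expect_equal(solve_rnnls(d, numeric(20), lambda = 0)$x, numeric(19))
  expect_error(solve_rnnls(d, numeric(10)), "rows")
  expect_error(solve_rnnls(d, c(NA, numeric(19))), "finite")
  expect_error(solve_rnnls(d, numeric(20), lambda = -1), "nonnegative")
})

test_that("solutions satisfy the KKT optimality conditions", {
  d <- fix_dictionary()
  lambda <- 0.001
  withr::with_seed(99, {
    for (k in 1:20) {
      y <- runif(20, 0.1, 1)
      x <- solve_rnnls(d, y, lambda, normalize_columns = FALSE)$x
      g <- crossprod(d$phi, d$phi %*% x - y) + 2 * lambda * x
      expect_gt(min(g[x == 0]), -1e-8)
      if (any(x > 0)) expect_lt(max(abs(g[x > 0])), 1e-8)
    }
  })
})

test_that("the regularized objective matches an independent convex-QP oracle", {
  d <- fix_dictionary()
  lambda <- 0.001
  withr::with_seed(7, {
    for (k in 1:5) {
      phi <- matrix(runif(20 * 19), 20, 19)
      y <- runif(20)
      x <- solve_rnnls(phi, y, lambda, normalize_columns = FALSE)$x
      obj <- rnnls_objective(phi, y, lambda, x)
      oracle <- qp_oracle_objective(phi, y, lambda)
      expect_lt(abs(obj - oracle) / max(oracle, 1e-12), 1e-8)
    }
  })
})

test_that("stronger regularization shrinks the weight vector", {
  d <- fix_dictionary()
  y <- add_rician_noise(matrix(simulate_signals(
    tibble::tibble(f_ic = 0.4, f_ees = 0.35, f_vasc = 0.25, radius = 8e-6,
                   d_ic = 2e-9, d_ees = 2e-9, p = 8e-9),
    fix_protocol()), 1), 20, 1, seed = 5)[[1]][1, ]
  norms <- vapply(c(0, 1e-4, 1e-3, 1e-2, 1e-1), function(l) {
    sqrt(sum(solve_rnnls(d, y, l, normalize_columns = FALSE)$x^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("parameter extraction implements the weighted-radius rules", {
  d <- fix_dictionary()
  # single sphere atom
  e5 <- replace(numeric(19), 5, 1)
  p5 <- extract_parameters(e5, d)
  expect_equal(p5$f_ic, 1)
  expect_equal(p5$radius, d$atoms$radius[5])
  # equal weights on two radii average them; 3 and 5 um -> 4 um
  x <- numeric(19)
  r3 <- which.min(abs(d$atoms$radius[1:17] - 3e-6))
  r5 <- which.min(abs(d$atoms$radius[1:17] - 5e-6))
  x[r3] <- 0.5; x[r5] <- 0.5
  px <- extract_parameters(x, d)
  expect_equal(px$f_ic, 1)
  expect_equal(px$radius,
               (d$atoms$radius[r3] + d$atoms$radius[r5]) / 2)
  # zero sphere mass: radius is the undefined sentinel, never 0/0
  pz <- extract_parameters(replace(numeric(19), 18, 0.7), d)
  expect_equal(pz$f_ic, 0)
  expect_true(is.na(pz$radius))
  expect_equal(pz$f_ees, 0.7)
  # free-d_EES dictionary: weight-averaged diffusivity
  df <- fix_dictionary(TRUE)
  xf <- numeric(19); xf[14] <- 0.5; xf[16] <- 0.5
  expect_equal(extract_parameters(xf, df)$d_ees, (1.1e-9 + 2.1e-9) / 2)
  expect_error(extract_parameters(numeric(5), d), "match")
  expect_error(extract_parameters(replace(numeric(19), 1, -1), d),
               "nonnegative")
})

test_that("noiseless in-dictionary mixtures are recovered exactly (lambda 0)", {
  p <- fix_protocol()
  d <- fix_dictionary()
  r_atom <- d$atoms$radius[9]
  y <- verdict_signal(p, 0.4, 0.35, 0.25, radius = r_atom)
  fit <- fit_amico(y, d, lambda = 0)
  est <- fit$params
  expect_lt(abs(est$f_ic - 0.4), 1e-6)
  expect_lt(abs(est$f_ees - 0.35), 1e-6)
  expect_lt(abs(est$f_vasc - 0.25), 1e-6)
  expect_lt(abs(est$f_ic + est$f_ees + est$f_vasc - 1), 1e-6)
  expect_lt(abs(est$radius - r_atom), 1e-12)
})

test_that("noisy replicates stay within the expected error band", {
  p <- fix_protocol()
  d <- fix_dictionary()
  r_atom <- d$atoms$radius[9]
  clean <- matrix(verdict_signal(p, 0.4, 0.35, 0.25, radius = r_atom),
                  nrow = 1)
  reps <- add_rician_noise(clean[rep(1, 10), ], 20, 1, seed = 31)[[1]]
  fit <- fit_amico(reps, d, lambda = 0.001, sigma = 1 / 20)
  # f_IC is the best determined fraction; the collinear ball/astrosticks
  # split is noisier
  expect_lte(mean(abs(fit$params$f_ic - 0.4)), 0.15)
  expect_lte(mean(abs(fit$params$f_ees - 0.35)), 0.2)
  expect_lte(mean(abs(fit$params$f_vasc - 0.25)), 0.2)
})

test_that("estimate spread shrinks as SNR grows", {
  p <- fix_protocol()
  d <- fix_dictionary()
  clean <- matrix(verdict_signal(p, 0.4, 0.35, 0.25, radius = 8e-6), nrow = 1)
  spread <- vapply(c(20, 50), function(snr) {
    reps <- add_rician_noise(clean[rep(1, 30), ], snr, 1, seed = 77)[[1]]
    stats::sd(fit_amico(reps, d)$params$f_ic)
  }, numeric(1))
  expect_true(all(is.finite(spread)))
  expect_lt(spread[2], spread[1])
})

test_that("voxels with non-finite signals are skipped, not fatal", {
  d <- fix_dictionary()
  p <- fix_protocol()
  sig <- rbind(verdict_signal(p, 0.5, 0.3, 0.2, radius = 8e-6),
               rep(NA_real_, 20))
  expect_message(fit <- fit_amico(sig, d), "skipped 1")
  expect_equal(fit$skipped, 1L)
  expect_true(is.na(fit$params$f_ic[2]))
  expect_false(is.na(fit$params$f_ic[1]))
})

test_that("tidy and glance expose the fit in broom style", {
  d <- fix_dictionary()
  p <- fix_protocol()
  fit <- fit_amico(simulate_signals(subsample_grid(verdict_parameter_grid(), 5),
                                    p), d)
  td <- tidy(fit, units = "um")
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("voxel", "f_ic", "radius_um", "f_obj") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$engine, "amico")
  expect_equal(gl$n_voxels, 5)
})
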