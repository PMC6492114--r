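toy_truth <- function() {
  tibble::tibble(f_ic = c(0.5, 0.2, 0.7), f_ees = c(0.3, 0.5, 0.1),
                 f_vasc = c(0.2, 0.3, 0.2), radius = c(5, 8, 12) * 1e-6)
}

test_that("errors against ground truth follow the definitions", {
  truth <- toy_truth()
  e0 <- estimation_errors(truth, truth)
  expect_true(all(e0$error == 0))
  est <- truth
  est$f_ic[1] <- 0.6
  e <- estimation_errors(est, truth)
  expect_equal(e$abs_error[e$parameter == "f_ic" & e$voxel == 1], 0.1)
  expect_equal(sum(e$abs_error > 0), 1)
  # radius errors are reported in um
  est2 <- truth
  est2$radius[2] <- 10e-6
  e2 <- estimation_errors(est2, truth)
  expect_equal(e2$error[e2$parameter == "radius_um" & e2$voxel == 2], 2)
  # radius errors only where the true f_IC is positive
  truth3 <- truth; truth3$f_ic[3] <- 0
  e3 <- estimation_errors(truth3, truth3)
  expect_true(is.na(e3$error[e3$parameter == "radius_um" & e3$voxel == 3]))
  expect_error(estimation_errors(truth[1:2, ], truth), "aligned")
})

test_that("pooling several instances equals the pooled mean identity", {
  truth <- toy_truth()
  est1 <- truth; est1$f_ic <- truth$f_ic + 0.1
  est2 <- truth; est2$f_ic <- truth$f_ic - 0.3
  pooled <- dplyr::bind_rows(estimation_errors(est1, truth, 1),
                             estimation_errors(est2, truth, 2))
  s <- error_summary(pooled)
  m <- s$mean_abs_error[s$parameter == "f_ic"]
  expect_equal(m, (0.1 + 0.3) / 2)
})

test_that("precision ratios behave as identities and homogeneous maps", {
  truth <- toy_truth()
  withr::with_seed(5, {
    est <- truth
    est$f_ic <- truth$f_ic + rnorm(3, sd = 0.05)
    est$radius <- truth$radius + rnorm(3, sd = 1e-6)
  })
  e <- estimation_errors(est, truth)
  # identical error distributions give exactly 1
  r1 <- precision_ratio(e, e)
  expect_true(all(r1$ratio[!r1$degenerate] == 1))
  # doubling every numerator error doubles the ratio
  e2 <- e
  e2$error <- 2 * e$error
  e2$abs_error <- 2 * e$abs_error
  r2 <- precision_ratio(e2, e)
  expect_equal(r2$ratio[!r2$degenerate],
               rep(2, sum(!r2$degenerate)))
  # a zero-SD reference is flagged
  ez <- estimation_errors(truth, truth)
  rz <- precision_ratio(e, ez)
  expect_true(all(rz$degenerate))
  expect_true(all(is.infinite(rz$ratio) | is.nan(rz$ratio)))
})

test_that("Pearson r2 and SSE match hand-computed cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r2_sse(x, x)$r2, 1)
  expect_equal(pearson_r2_sse(x, x)$sse, 0)
  neg <- pearson_r2_sse(x, -x)
  expect_equal(neg$r2, 1)
  expect_equal(neg$sse, 4 * sum(x^2))
  # 4-point set by hand: cov = 1, var = 5/3 each, r = 0.6, SSE = 4
  y <- c(2, 1, 4, 3)
  got <- pearson_r2_sse(x, y)
  expect_equal(got$r2, 0.36, tolerance = 1e-12)
  expect_equal(got$sse, 4)
  expect_true(is.na(pearson_r2_sse(x, rep(1, 4))$r2))
  expect_error(pearson_r2_sse(1:2, 1:2), "3")
})

test_that("Bland-Altman statistics match hand arithmetic", {
  a <- c(1, 2, 3, 4, 5)
  same <- bland_altman(a, a)
  expect_equal(same$rpc_pct, 0)
  expect_equal(same$cv_pct, 0)
  shift <- bland_altman(a + 0.5, a)
  expect_equal(shift$bias, 0.5)
  expect_equal(shift$rpc_pct, 0)
  # 5-pair toy set: d = (-0.1, 0.1, -0.2, 0.2, 0), sd(d) = sqrt(0.1/4),
  # grand mean = 3
  b <- c(1.1, 1.9, 3.2, 3.8, 5.0)
  got <- bland_altman(a, b)
  sdd <- sqrt(0.1 / 4)
  expect_equal(got$bias, 0)
  expect_equal(got$rpc_pct, 1.96 * sdd / 3 * 100, tolerance = 1e-12)
  expect_equal(got$cv_pct, sdd / (sqrt(2) * 3) * 100, tolerance = 1e-12)
  expect_error(bland_altman(1, 2), "2")
})

test_that("metrics are invariant to voxel ordering", {
  truth <- toy_truth()
  withr::with_seed(11, {
    est <- truth
    est$f_ic <- truth$f_ic + rnorm(3, sd = 0.05)
  })
  e <- estimation_errors(est, truth)
  perm <- sample(nrow(truth))
  ep <- estimation_errors(est[perm, ], truth[perm, ])
  expect_equal(error_summary(e)[, -1], error_summary(ep)[, -1])
})

test_that("the Welch comparison wraps t.test faithfully", {
  withr::with_seed(2, {
    a <- abs(rnorm(40, 0.1, 0.05))
    b <- abs(rnorm(40, 0.3, 0.05))
  })
  got <- welch_error_test(a, b)
  ref <- stats::t.test(a, b)
  expect_equal(got$p_value, ref$p.value)
  expect_lt(got$p_value, 0.001)
})
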