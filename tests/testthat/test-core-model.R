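test_that("time grids are validated", {
  expect_equal(time_grid(c(1, 2, 3)), c(1, 2, 3))
  expect_error(time_grid(5), "at least 2")
  expect_error(time_grid(c(0, 1)), "strictly positive")
  expect_error(time_grid(c(-1, 1)), "strictly positive")
  expect_error(time_grid(c(2, 1)), "strictly increasing")
  expect_error(time_grid(c(1, 1, 2)), "strictly increasing")
  expect_error(time_grid(c(1, NA, 3)), "non-finite")
})

test_that("signal matrices enforce shape and non-negativity", {
  g <- time_grid(c(1, 10, 100))
  I <- signal_matrix(matrix(1:6 / 10, 3, 2), g)
  expect_s3_class(I, "bz_signal")
  expect_equal(dim(I), c(3L, 2L))
  expect_error(signal_matrix(matrix(1, 2, 2), g), "does not match")
  bad <- matrix(1, 3, 2); bad[2, 1] <- -0.5
  expect_error(signal_matrix(bad, g), "row 2, column 1")
})

test_that("basis matrix matches the scalar exponential everywhere", {
  # t = tau gives exp(-1)
  expect_equal(basis_matrix(5, time_grid(c(5, 6)))[1, 1], exp(-1))
  # t -> 0+ limit: entries approach 1
  expect_equal(basis_matrix(10, time_grid(c(1e-12, 1)))[1, 1], 1,
               tolerance = 1e-9)
  # element-wise scalar oracle on the documented 3x2 case
  taus <- c(10, 100); times <- c(1.002, 10, 1000)
  W <- basis_matrix(taus, time_grid(times))
  expect_equal(dim(W), c(3L, 2L))
  for (j in 1:3) for (r in 1:2)
    expect_identical(W[j, r], exp(-times[j] / taus[r]))
  # log-linearity: ln w_jr = -t_j / tau_r exactly
  expect_equal(log(W), outer(times, taus, function(t, tau) -t / tau))
  # columns strictly decreasing in t
  expect_true(all(diff(W[, 1]) < 0) && all(diff(W[, 2]) < 0))
  expect_error(basis_matrix(c(1, -1), time_grid(c(1, 2))), "positive")
})

test_that("reconstruction equals the explicit double loop and is linear in H", {
  inst <- random_instance(M = 4, N = 3, R = 2, seed = 42)
  f <- inst$f
  W <- basis_matrix(f$taus, f$times)
  manual <- matrix(0, 4, 3)
  for (j in 1:4) for (i in 1:3) for (r in 1:2)
    manual[j, i] <- manual[j, i] + W[j, r] * f$coeffs[r, i]
  expect_equal(reconstruct(f), manual)

  # single component, single point
  f1 <- factorization(10, matrix(1), time_grid(c(10, 20)))
  expect_equal(reconstruct(f1)[1, 1], exp(-1))

  # zero coefficients give the zero matrix
  f0 <- f; f0$coeffs[] <- 0
  expect_equal(reconstruct(f0), matrix(0, 4, 3))

  # linearity in H
  f2 <- f; f2$coeffs <- matrix(runif(6), 2, 3)
  fsum <- f; fsum$coeffs <- f$coeffs + f2$coeffs
  expect_equal(reconstruct(fsum), reconstruct(f) + reconstruct(f2))
})

test_that("least-squares objective matches the brute-force sum", {
  inst <- random_instance(seed = 7)
  wh <- reconstruct(inst$f)
  expect_equal(lse_objective(inst$I, inst$f),
               sum((inst$I$values - wh)^2))
  # exact fit scores zero
  Ifit <- signal_matrix(wh, inst$g)
  expect_equal(lse_objective(Ifit, inst$f), 0)
  # 1-element case: (1 - 0.5)^2, via a grid of length 2
  g <- time_grid(c(1, 2))
  f <- factorization(1 / log(2), matrix(1), g)  # w_11 = 0.5
  I <- signal_matrix(matrix(c(1, reconstruct(f)[2, 1])), g)
  expect_equal(lse_objective(I, f), 0.25)
})

test_that("generalized KL objective follows the elementwise definition", {
  inst <- random_instance(seed = 8)
  wh <- reconstruct(inst$f)
  x <- inst$I$values
  manual <- sum(x * log(x / wh) - x + wh)
  expect_equal(as.numeric(kl_objective(inst$I, inst$f)), manual)

  # zero at exact fit
  Ifit <- signal_matrix(wh, inst$g)
  expect_equal(as.numeric(kl_objective(Ifit, inst$f)), 0, tolerance = 1e-12)

  # 0 * log(0/x) convention: zero data cell contributes exactly (WH)_ji
  g <- time_grid(c(1, 2))
  f <- factorization(2, matrix(1), g)
  I0 <- signal_matrix(matrix(0, 2, 1), g)
  expect_equal(as.numeric(kl_objective(I0, f)), sum(reconstruct(f)))
})

test_that("KL objective approaches its quadratic approximation near the fit", {
  inst <- random_instance(M = 5, N = 4, R = 2, seed = 9)
  wh <- reconstruct(inst$f)
  eps <- 1e-6
  Ipert <- signal_matrix(wh * (1 + eps), inst$g)
  quad <- sum((Ipert$values - wh)^2 / (2 * wh))
  expect_equal(as.numeric(kl_objective(Ipert, inst$f)), quad,
               tolerance = 1e-4)
})

test_that("both objectives are non-negative across random instances", {
  for (s in 1:20) {
    inst <- random_instance(M = 5, N = 3, R = 2, seed = s)
    expect_gte(lse_objective(inst$I, inst$f), 0)
    expect_gte(as.numeric(kl_objective(inst$I, inst$f)), 0)
  }
})

test_that("objective dispatch and shape checks work", {
  inst <- random_instance(seed = 10)
  expect_equal(objective_value(inst$I, inst$f, "lse"),
               lse_objective(inst$I, inst$f))
  expect_equal(objective_value(inst$I, inst$f, "kl"),
               as.numeric(kl_objective(inst$I, inst$f)))
  other <- random_instance(M = 4, N = 2, R = 2, seed = 11)
  expect_error(lse_objective(inst$I, other$f), "grid")
})

test_that("factorizations are canonically ordered", {
  g <- time_grid(c(1, 10))
  f <- factorization(c(100, 10), rbind(c(1, 1), c(2, 2)), g)
  expect_equal(f$taus, c(10, 100))
  expect_equal(f$coeffs[1, ], c(2, 2))
  # tau ties break by descending mean coefficient
  ftie <- factorization(c(5, 5), rbind(c(1, 1), c(3, 3)), g)
  expect_equal(ftie$coeffs[1, ], c(3, 3))
})
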