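# AR(1) model algebra: stationary covariance, lagged cross-covariance,
# simulation, and estimation from time series.

test_that("stationary covariance solves the Lyapunov equation", {
  # no dynamics: Sigma(X) reduces to the noise covariance
  m0 <- ar_model(matrix(0, 3, 3), diag(3))
  expect_equal(stationary_covariance(m0), diag(3))

  # decoupled elements: scalar fixed point sigma^2 / (1 - a^2)
  m1 <- ar_model(diag(0.5, 2), diag(2))
  expect_equal(stationary_covariance(m1), diag(4 / 3, 2), tolerance = 1e-12)

  # random stable 5x5: agree with the truncated series sum_k A^k SigE A'^k
  set.seed(101)
  m <- rand_strong_model(5)
  SX <- stationary_covariance(m)
  series <- m$SigmaE
  term <- m$SigmaE
  for (k in 1:300) {
    term <- m$A %*% term %*% t(m$A)
    series <- series + term
  }
  expect_lt(max(abs(SX - series)), 1e-8)
})

test_that("Lyapunov residual vanishes on generated benchmark models", {
  set.seed(7)
  for (kind in c("normal", "block")) {
    for (rep in 1:5) {
      m <- generate_network(kind, 8, sigma = 0.1)
      SX <- stationary_covariance(m)
      resid <- SX - m$A %*% SX %*% t(m$A) - m$SigmaE
      expect_lt(max(abs(resid)), 1e-8)
      # the assembled joint is PD whenever Sigma(E) is
      expect_no_error(chol(ar_joint_gaussian(m)$Sigma))
    }
  }
})

test_that("model validation rejects bad inputs", {
  expect_error(ar_model(diag(1.0, 3), diag(3)), "stationary")
  expect_error(ar_model(diag(0.5, 3), diag(c(1, -1, 1))), "positive definite")
  expect_error(ar_model(matrix(0.1, 2, 3), diag(2)), "square")
})

test_that("cross covariance is Sigma(X) A^T", {
  expect_equal(cross_covariance(diag(2), matrix(0, 2, 2)), matrix(0, 2, 2))
  # decoupled scalar channels: 4/3 * 0.5 = 2/3
  SX <- diag(4 / 3, 2)
  expect_equal(cross_covariance(SX, diag(0.5, 2)), diag(2 / 3, 2))
  expect_error(cross_covariance(diag(2), diag(3)), "same size")
})

test_that("simulation reproduces the analytic second moments", {
  set.seed(5)
  m <- rand_strong_model(5, coupling = 0.4)
  SX <- stationary_covariance(m)
  Cr <- cross_covariance(SX, m$A)
  x <- simulate_ar(m, 1e5, seed = 42)
  n <- nrow(x) - 1
  past <- scale(x[1:n, ], scale = FALSE)
  pres <- scale(x[2:(n + 1), ], scale = FALSE)
  expect_lt(max(abs(crossprod(past) / n - SX)) / max(abs(SX)), 0.05)
  expect_lt(max(abs(crossprod(past, pres) / n - Cr)), 0.05 * max(abs(SX)))

  # white noise: sample covariance close to the identity
  w <- simulate_ar(ar_model(matrix(0, 3, 3), diag(3)), 1e5, seed = 9)
  expect_lt(max(abs(cov(w) - diag(3))), 0.05)

  # strong scalar autocorrelation matches AR(1) theory
  y <- simulate_ar(ar_model(diag(0.9, 2), diag(2)), 1e5, seed = 10)
  expect_equal(cor(y[-1e5, 1], y[-1, 1]), 0.9, tolerance = 0.02)

  # determinism under a fixed seed
  expect_identical(simulate_ar(m, 500, seed = 3), simulate_ar(m, 500, seed = 3))
})

test_that("joint Gaussian estimation recovers the analytic blocks", {
  set.seed(11)
  m <- rand_strong_model(4, coupling = 0.4)
  x <- simulate_ar(m, 1e5, seed = 21)
  est <- estimate_joint_gaussian(x, lag = 1)
  truth <- ar_joint_gaussian(m)
  frob <- function(M) sqrt(sum(M^2))
  expect_lt(frob(past_cov(est) - past_cov(truth)) / frob(past_cov(truth)), 0.05)
  expect_lt(frob(lag_cov(est) - lag_cov(truth)) / frob(past_cov(truth)), 0.05)
  expect_lt(
    frob(present_cov(est) - present_cov(truth)) / frob(present_cov(truth)),
    0.05
  )

  # lag 0: both segments are the same, so the cross block is Sigma(X) and
  # the assembled 2N x 2N matrix is singular, triggering the jitter path
  expect_warning(e0 <- estimate_joint_gaussian(x, lag = 0), "jitter")
  expect_equal(lag_cov(e0), past_cov(e0), tolerance = 1e-8)

  # constant channels cannot be normalized into a distribution
  bad <- cbind(x[, 1:3], 1)
  expect_error(estimate_joint_gaussian(bad), "zero-variance")
})
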