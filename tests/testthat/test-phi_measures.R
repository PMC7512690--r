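# Gaussian entropies and the three integrated-information measures.

test_that("gaussian entropy matches closed forms and sampling", {
  expect_equal(gaussian_entropy(matrix(1)), 0.5 * log(2 * pi * exp(1)))
  expect_equal(gaussian_entropy(diag(2)), 2 * gaussian_entropy(matrix(1)))
  expect_error(gaussian_entropy(diag(c(1, -1))), "positive definite")

  # Monte-Carlo estimate -E[log p] on a random PD covariance
  set.seed(31)
  Sigma <- stats::rWishart(1, 8, diag(4))[, , 1]
  z <- MASS::mvrnorm(1e6, rep(0, 4), Sigma)
  expect_equal(gaussian_entropy(Sigma), -mean(logdens_gauss(z, Sigma)),
               tolerance = 0.01)
})

test_that("phi_mi vanishes for independent subsystems and matches a direct KL", {
  # block-diagonal joint over (M1, M1') vs (M2, M2')
  set.seed(32)
  N <- 4
  S <- c(1, 2)
  blk <- function(n) stats::rWishart(1, 2 * n, diag(n))[, , 1]
  Sigma <- matrix(0, 2 * N, 2 * N)
  i1 <- c(S, N + S)
  i2 <- setdiff(seq_len(2 * N), i1)
  Sigma[i1, i1] <- blk(4)
  Sigma[i2, i2] <- blk(4)
  j <- joint_gaussian(Sigma)
  expect_equal(phi_mi(j, S)$value, 0, tolerance = 1e-12)

  # independent recomputation via LU determinants on a coupled instance
  set.seed(33)
  j <- rand_strong_joint(3)
  ld <- function(M) as.numeric(determinant(M, logarithm = TRUE)$modulus)
  i1 <- c(1, 4)
  i2 <- c(2, 3, 5, 6)
  direct <- 0.5 * (ld(j$Sigma[i1, i1]) + ld(j$Sigma[i2, i2]) - ld(j$Sigma))
  expect_equal(phi_mi(j, 1)$value, direct, tolerance = 1e-10)
})

test_that("phi_si vanishes exactly when the transition factorizes", {
  # no dynamics, independent noise: present independent of past and parts
  j <- ar_joint_gaussian(ar_model(matrix(0, 4, 4), diag(c(1, 2, 3, 4))))
  expect_equal(phi_si(j, c(1, 3))$value, 0, tolerance = 1e-12)

  # block dynamics and block noise: factorizes across the half split only
  set.seed(34)
  h <- 3
  A <- matrix(0, 2 * h, 2 * h)
  A[1:h, 1:h] <- rnorm(h * h, 0, 0.2)
  A[h + 1:h, h + 1:h] <- rnorm(h * h, 0, 0.2)
  SigE <- matrix(0, 2 * h, 2 * h)
  SigE[1:h, 1:h] <- stats::rWishart(1, 2 * h, diag(h))[, , 1]
  SigE[h + 1:h, h + 1:h] <- stats::rWishart(1, 2 * h, diag(h))[, , 1]
  j <- ar_joint_gaussian(ar_model(A, SigE))
  expect_equal(phi_si(j, 1:h)$value, 0, tolerance = 1e-10)
  expect_gt(phi_si(j, c(1, 4))$value, 1e-4)
})

test_that("all measures are symmetric under complementation", {
  set.seed(35)
  for (rep in 1:5) {
    N <- sample(3:6, 1)
    j <- rand_strong_joint(N)
    S <- sort(sample(seq_len(N), sample(seq_len(N - 1), 1)))
    Sc <- setdiff(seq_len(N), S)
    expect_identical(phi_mi(j, S)$value, phi_mi(j, Sc)$value)
    expect_identical(phi_si(j, S)$value, phi_si(j, Sc)$value)
    expect_equal(phi_g(j, S)$value, phi_g(j, Sc)$value, tolerance = 1e-9)
  }
})

test_that("phi_g is zero across the causal split of a block model", {
  set.seed(36)
  m <- generate_network("block", 12, sigma = 0.1)
  j <- ar_joint_gaussian(m)
  g <- phi_g(j, 1:6)
  expect_lt(g$value, 1e-8)
  # noise is full Wishart, so equal-time interactions remain: SI stays up
  expect_gt(phi_si(j, 1:6)$value, 1e-3)
})

test_that("phi_g reports convergence metadata and fails loudly at max_iter", {
  set.seed(37)
  j <- rand_strong_joint(5, coupling = 0.6)
  g <- phi_g(j, c(1, 3))
  expect_true(g$converged)
  expect_lt(g$residual, 1e-8)
  expect_gt(g$iterations, 1)
  expect_error(phi_g(j, c(1, 3), max_iter = 1), "did not converge")
})

test_that("phi_g agrees with a black-box constrained minimization", {
  set.seed(38)
  for (rep in 1:3) {
    j <- rand_strong_joint(4, coupling = 0.5)
    S <- list(1, c(1, 2), c(1, 4))[[rep]]
    expect_equal(phi_g(j, S)$value, direct_phi_g(j, S), tolerance = 1e-5)
  }
})
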