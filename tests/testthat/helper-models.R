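# Shared fixtures: random stationary AR models and joint Gaussians built
# in code, plus independent oracles used to cross-check the package's
# implementations.

# Random stable AR model with adjustable coupling strength (stronger than
# the benchmark default so Phi values are well away from zero).
rand_strong_model <- function(N, coupling = 0.3, sigma = 0.1) {
  repeat {
    A <- matrix(rnorm(N * N, 0, sqrt(coupling / N)), N, N)
    if (max(Mod(eigen(A, only.values = TRUE)$values)) < 0.95) break
  }
  SigmaE <- stats::rWishart(1, 2 * N, diag(sigma, N))[, , 1]
  ar_model(A, SigmaE)
}

rand_strong_joint <- function(N, coupling = 0.3, sigma = 0.1) {
  ar_joint_gaussian(rand_strong_model(N, coupling, sigma))
}

# ---------------------------------------------------------------------------
# Independent oracles (kept deliberately naive; they never share code with
# the implementation paths they check).

# log density of N(0, Sigma) at the rows of x, via Cholesky
logdens_gauss <- function(x, Sigma) {
  R <- chol(Sigma)
  z <- forwardsolve(t(R), t(x))
  -0.5 * (ncol(x) * log(2 * pi) + 2 * sum(log(diag(R))) + colSums(z^2))
}

# Monte-Carlo KL oracle for the mutual-information measure: sample from p
# and average log p - log q with q the product of part marginals.
mc_phi_mi <- function(joint, S, n = 1e6) {
  N <- joint$N
  Sc <- setdiff(seq_len(N), S)
  i1 <- c(S, N + S)
  i2 <- c(Sc, N + Sc)
  z <- MASS::mvrnorm(n, rep(0, 2 * N), joint$Sigma)
  mean(
    logdens_gauss(z, joint$Sigma) -
      logdens_gauss(z[, i1, drop = FALSE], joint$Sigma[i1, i1]) -
      logdens_gauss(z[, i2, drop = FALSE], joint$Sigma[i2, i2])
  )
}

# Monte-Carlo KL oracle for stochastic interaction:
# q(x, x') = p(x) * prod_i p(m_i' | m_i), each factor evaluated as a ratio
# of joint to marginal Gaussian densities.
mc_phi_si <- function(joint, S, n = 1e6) {
  N <- joint$N
  Sc <- setdiff(seq_len(N), S)
  z <- MASS::mvrnorm(n, rep(0, 2 * N), joint$Sigma)
  px_idx <- seq_len(N)
  log_cond <- function(idx) {
    ii <- c(idx, N + idx)
    logdens_gauss(z[, ii, drop = FALSE], joint$Sigma[ii, ii]) -
      logdens_gauss(z[, idx, drop = FALSE], joint$Sigma[idx, idx])
  }
  log_p <- logdens_gauss(z, joint$Sigma)
  log_q <- logdens_gauss(z[, px_idx, drop = FALSE],
                         joint$Sigma[px_idx, px_idx]) +
    log_cond(S) + log_cond(Sc)
  mean(log_p - log_q)
}

# Direct black-box minimization of the constrained Gaussian KL over the
# free parameters of q (within-part regression blocks + Cholesky factor of
# the noise covariance).  Independent of the package's iterative solver.
direct_phi_g <- function(joint, S) {
  N <- joint$N
  parts <- list(sort(S), setdiff(seq_len(N), S))
  SX <- past_cov(joint)
  Cr <- lag_cov(joint)
  B <- t(solve(SX, Cr))
  Scond <- present_cov(joint) - B %*% Cr
  Scond <- (Scond + t(Scond)) / 2
  ldet <- function(M) 2 * sum(log(diag(chol(M))))
  ldet_c <- ldet(Scond)
  nfree <- sum(vapply(parts, length, 1L)^2)
  nl <- N * (N + 1) / 2
  unpack <- function(th) {
    Ap <- matrix(0, N, N)
    off <- 0
    for (p in parts) {
      k <- length(p)
      Ap[p, p] <- matrix(th[(off + 1):(off + k * k)], k, k)
      off <- off + k * k
    }
    L <- matrix(0, N, N)
    L[lower.tri(L, diag = TRUE)] <- th[(off + 1):(off + nl)]
    diag(L) <- exp(diag(L))
    list(Ap = Ap, Sp = tcrossprod(L))
  }
  f <- function(th) {
    u <- unpack(th)
    D <- B - u$Ap
    M <- Scond + D %*% SX %*% t(D)
    v <- try(
      0.5 * (sum(diag(solve(u$Sp, M))) + ldet(u$Sp) - ldet_c - N),
      silent = TRUE
    )
    if (inherits(v, "try-error") || !is.finite(v)) 1e10 else v
  }
  th0 <- numeric(nfree + nl)
  Lt <- t(chol(Scond))
  diag(Lt) <- log(diag(Lt))
  th0[(nfree + 1):(nfree + nl)] <- Lt[lower.tri(Lt, diag = TRUE)]
  o <- stats::optim(th0, f, method = "BFGS",
                    control = list(maxit = 5000, reltol = 1e-15))
  o <- stats::optim(o$par, f, method = "BFGS",
                    control = list(maxit = 5000, reltol = 1e-15))
  o$value
}
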