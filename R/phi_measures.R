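# Gaussian measures of integrated information.  All three measures are KL
# divergences between the joint past-present Gaussian p(X, X') and a
# "disconnected" Gaussian q in which cross-partition interactions are
# removed; they differ in which interactions the constraint on q removes.
# Natural logarithms (nats) throughout.  Determinants via Cholesky
# log-determinants; no explicit inverses of full covariances.

# log-determinant of a symmetric PD matrix via Cholesky; `what` names the
# offending block in error messages.
logdet_pd <- function(M, what = "covariance") {
  R <- try(chol(M), silent = TRUE)
  if (inherits(R, "try-error")) {
    stop(what, " block is not positive definite")
  }
  2 * sum(log(diag(R)))
}

# Values in (-tol, 0) are float noise and clamped to 0; more negative
# values indicate a genuine defect and raise.
clamp_phi <- function(value, measure, tol = 1e-9) {
  if (value < -tol) {
    stop(sprintf(
      "Phi_%s = %.3e is negative beyond numerical tolerance", measure, value
    ))
  }
  max(value, 0)
}

#' Differential entropy of a Gaussian
#'
#' Closed form `0.5 * log((2 * pi * e)^k * det(cov))` in nats.
#'
#' @param cov `k x k` symmetric positive definite covariance.
#' @return Entropy in nats (may be negative for small variances).
#' @examples
#' gaussian_entropy(matrix(1))  # 0.5 * log(2 * pi * e) = 1.41894
#' @export
gaussian_entropy <- function(cov) {
  cov <- as.matrix(cov)
  k <- nrow(cov)
  if (ncol(cov) != k) stop("covariance must be square")
  0.5 * (k * log(2 * pi * exp(1)) + logdet_pd(cov, "entropy"))
}

new_phi_value <- function(measure, value, iterations = NULL, residual = NULL,
                          converged = NULL) {
  out <- list(measure = measure, value = value)
  if (measure == "G") {
    out$iterations <- iterations
    out$residual <- residual
    out$converged <- converged
  }
  structure(out, class = "phi_value")
}

#' @export
print.phi_value <- function(x, ...) {
  cat(sprintf("Phi_%s = %.6g nats", x$measure, x$value))
  if (x$measure == "G") {
    cat(sprintf(
      " (%d iterations, final residual %.2g)", x$iterations, x$residual
    ))
  }
  cat("\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Precomputed per-joint quantities shared by all partition evaluations.
# These are partition-independent, so search oracles compute them once.

joint_precompute <- function(joint) {
  stopifnot(inherits(joint, "joint_gaussian"))
  SX <- past_cov(joint)
  SXp <- present_cov(joint)
  Cr <- lag_cov(joint)
  # full regression X' = B X + residual; conditional covariance of X' | X
  B <- t(solve(SX, Cr))
  Scond <- SXp - B %*% Cr
  Scond <- (Scond + t(Scond)) / 2
  list(
    N = joint$N, Sigma = joint$Sigma, SX = SX, SXp = SXp, Cr = Cr,
    B = B, Scond = Scond,
    ldet_full = logdet_pd(joint$Sigma, "joint"),
    ldet_cond = logdet_pd(Scond, "conditional present-given-past")
  )
}

part_indices <- function(part, N) {
  if (inherits(part, "bipartition")) {
    stopifnot(part$N == N)
    S <- part$S
  } else {
    S <- bipartition(part, N)$S
  }
  list(S, setdiff(seq_len(N), S))
}

# Phi_MI as a plain number, given precomputed joint data.
phi_mi_value <- function(jd, parts) {
  N <- jd$N
  acc <- -jd$ldet_full
  for (idx in parts) {
    ii <- c(idx, N + idx)
    acc <- acc + logdet_pd(jd$Sigma[ii, ii, drop = FALSE], "subsystem joint")
  }
  0.5 * acc
}

# Conditional covariance of M' | M for the elements `idx`.
part_cond_cov <- function(jd, idx) {
  P <- jd$SX[idx, idx, drop = FALSE]
  Cr <- jd$Cr[idx, idx, drop = FALSE]
  Pp <- jd$SXp[idx, idx, drop = FALSE]
  C <- Pp - crossprod(Cr, solve(P, Cr))
  (C + t(C)) / 2
}

phi_si_value <- function(jd, parts) {
  acc <- -jd$ldet_cond
  for (idx in parts) {
    acc <- acc + logdet_pd(part_cond_cov(jd, idx), "conditional subsystem")
  }
  0.5 * acc
}

# Phi_G by block-coordinate descent on the Gaussian KL.  The disconnected
# model is q(X) = p(X), q(X' | X) = N(A' X, Sigma'), where A' is
# constrained to be block-diagonal with respect to the partition (each
# part's present regresses only on its own past) and Sigma' is a free
# symmetric PD matrix.  Writing Delta = B - A' with B the unconstrained
# regression of p, the divergence is
#   KL = 0.5 * ( tr(Sigma'^{-1} (Scond + Delta SX Delta^T))
#                + logdet Sigma' - logdet Scond - N ).
# Minimizing over Sigma' for fixed A' gives Sigma' = Scond + Delta SX
# Delta^T; minimizing over the free blocks of A' for fixed Sigma' is the
# linear (generalized Sylvester) system
#   sum_j  Sigma'^{-1}[Si, Sj] A'_j SX[Sj, Si] = (Sigma'^{-1} B SX)[Si, Si]
# solved by vectorization.  Both half-steps are exact minimizers, so the
# objective is monotone non-increasing.
phi_g_value <- function(jd, parts, tol = 1e-8, max_iter = 10000) {
  N <- jd$N
  SX <- jd$SX
  B <- jd$B
  Scond <- jd$Scond
  sizes <- vapply(parts, length, 1L)
  off <- c(0L, cumsum(sizes^2))
  n_unknown <- off[length(off)]

  # init: full-model regression restricted to its within-part blocks
  Ap <- matrix(0, N, N)
  for (idx in parts) Ap[idx, idx] <- B[idx, idx]

  update_noise <- function(Ap) {
    D <- B - Ap
    Sp <- Scond + D %*% SX %*% t(D)
    (Sp + t(Sp)) / 2
  }
  Sp <- update_noise(Ap)

  it <- 0L
  resid <- Inf
  Msys <- matrix(0, n_unknown, n_unknown)
  rhs <- numeric(n_unknown)
  repeat {
    it <- it + 1L
    Dinv <- chol2inv(chol(Sp))
    RHSfull <- Dinv %*% B %*% SX
    for (i in seq_along(parts)) {
      Si <- parts[[i]]
      ri <- (off[i] + 1L):off[i + 1L]
      rhs[ri] <- RHSfull[Si, Si]
      for (k in seq_along(parts)) {
        Sk <- parts[[k]]
        Msys[ri, (off[k] + 1L):off[k + 1L]] <-
          kronecker(t(SX[Sk, Si, drop = FALSE]), Dinv[Si, Sk, drop = FALSE])
      }
    }
    sol <- solve(Msys, rhs)
    Ap_new <- matrix(0, N, N)
    for (i in seq_along(parts)) {
      Si <- parts[[i]]
      Ap_new[Si, Si] <- matrix(sol[(off[i] + 1L):off[i + 1L]],
                               sizes[i], sizes[i])
    }
    resid <- max(abs(Ap_new - Ap))
    Ap <- Ap_new
    Sp <- update_noise(Ap)
    if (resid < tol || it >= max_iter) break
  }
  if (resid >= tol) {
    stop(sprintf(
      "Phi_G iteration did not converge in %d iterations (last residual %.3e)",
      max_iter, resid
    ))
  }
  # at the Sigma' half-step optimum the trace term equals N, so
  # KL = 0.5 * (logdet Sigma' - logdet Scond)
  value <- 0.5 * (logdet_pd(Sp, "optimized noise") - jd$ldet_cond)
  list(value = value, iterations = it, residual = resid)
}

# ---------------------------------------------------------------------------
# Public measure interfaces.

#' Integrated information of a bipartitioned Gaussian system
#'
#' Computes one of the three Gaussian measures of integrated information
#' across a bipartition, in nats:
#'
#' * `phi_mi()`: mutual information between the two parts' past+present
#'   blocks, `H(M1, M1') + H(M2, M2') - H(X, X')`.  Symmetric and
#'   submodular as a set function.
#' * `phi_si()`: stochastic interaction,
#'   `sum_i H(M_i' | M_i) - H(X' | X)`, removing causal and equal-time
#'   cross-partition influences on the present.
#' * `phi_g()`: geometric integrated information, the minimum KL
#'   divergence to a Gaussian in which each part's present depends only on
#'   its own past (causal cross-influence removed, equal-time noise
#'   covariance free).  No closed form; solved by block-coordinate descent
#'   (see Details).
#'
#' The measures satisfy `phi_g <= phi_si <= phi_mi` on every instance, and
#' each is symmetric under exchanging a subset with its complement.
#'
#' @param joint a [joint_gaussian()].
#' @param part a [bipartition()], or an integer subset of `1..N`.
#' @param tol (`phi_g`) convergence tolerance on the maximum absolute
#'   change of the constrained regression coefficients per iteration.
#' @param max_iter (`phi_g`) iteration cap; exceeding it without
#'   convergence is an error (never a silent partial value).
#' @return A `"phi_value"` object: the measure tag, the value in nats
#'   (tiny negative numerical values are clamped to 0), and for `phi_g`
#'   the iteration count, final residual and convergence flag.
#' @details For `phi_g` the disconnected model is `q(X) = p(X)`,
#'   `q(X'|X) = N(A'X, Sigma')` with `A'` block-diagonal in the partition
#'   and `Sigma'` unconstrained.  The solver alternates two exact
#'   half-steps -- the closed-form `Sigma'` update and a linear solve for
#'   the free blocks of `A'` -- so the objective decreases monotonically;
#'   it is initialized from the full regression restricted to its
#'   within-part blocks.
#' @examples
#' m <- ar_model(matrix(c(0.5, 0.2, 0.1, 0.4), 2, 2), diag(2))
#' j <- ar_joint_gaussian(m)
#' phi_mi(j, 1)
#' phi_si(j, 1)
#' phi_g(j, 1)
#' @export
phi_mi <- function(joint, part) {
  jd <- joint_precompute(joint)
  parts <- part_indices(part, jd$N)
  new_phi_value("MI", clamp_phi(phi_mi_value(jd, parts), "MI"))
}

#' @rdname phi_mi
#' @export
phi_si <- function(joint, part) {
  jd <- joint_precompute(joint)
  parts <- part_indices(part, jd$N)
  new_phi_value("SI", clamp_phi(phi_si_value(jd, parts), "SI"))
}

#' @rdname phi_mi
#' @export
phi_g <- function(joint, part, tol = 1e-8, max_iter = 10000) {
  jd <- joint_precompute(joint)
  parts <- part_indices(part, jd$N)
  res <- phi_g_value(jd, parts, tol = tol, max_iter = max_iter)
  new_phi_value(
    "G", clamp_phi(res$value, "G"),
    iterations = res$iterations, residual = res$residual,
    converged = TRUE
  )
}
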