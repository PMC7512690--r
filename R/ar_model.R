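# First-order vector autoregressive model X' = A X + E and its stationary
# Gaussian description.  Convention throughout: X is the past state, X' the
# present state.

#' Construct a first-order autoregressive model
#'
#' Represents the model `X' = A X + E`, where `X` is the past state of an
#' `N`-element system, `X'` its present state, `A` the connectivity matrix
#' and `E` zero-mean Gaussian noise with covariance `SigmaE`.
#'
#' The model must be stationary: the spectral radius of `A` must be
#' strictly below 1.  `SigmaE` must be symmetric positive definite.
#'
#' @param A numeric `N x N` connectivity matrix.
#' @param SigmaE numeric `N x N` noise covariance matrix.
#' @return An object of class `"ar_model"` with fields `A`, `SigmaE`, `N`.
#' @examples
#' m <- ar_model(matrix(c(0.5, 0.1, 0, 0.4), 2, 2), diag(2))
#' m$N
#' @export
ar_model <- function(A, SigmaE) {
  A <- as.matrix(A)
  SigmaE <- as.matrix(SigmaE)
  N <- nrow(A)
  if (ncol(A) != N) stop("connectivity matrix A must be square")
  if (N < 2) stop("an AR model for partition analysis needs N >= 2 elements")
  if (!all(dim(SigmaE) == c(N, N))) {
    stop("SigmaE must be ", N, " x ", N, " to match A")
  }
  if (max(abs(SigmaE - t(SigmaE))) > 1e-8 * max(1, max(abs(SigmaE)))) {
    stop("noise covariance SigmaE must be symmetric")
  }
  SigmaE <- (SigmaE + t(SigmaE)) / 2
  if (inherits(try(chol(SigmaE), silent = TRUE), "try-error")) {
    stop("noise covariance SigmaE must be positive definite")
  }
  sr <- spectral_radius(A)
  if (sr >= 1 - 1e-9) {
    stop(sprintf(
      "AR model is not stationary: spectral radius of A is %.6g (must be < 1)",
      sr
    ))
  }
  structure(list(A = A, SigmaE = SigmaE, N = N), class = "ar_model")
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf(
    "AR(1) model: N = %d, spectral radius of A = %.4f\n",
    x$N, spectral_radius(x$A)
  ))
  invisible(x)
}

spectral_radius <- function(A) {
  max(Mod(eigen(A, only.values = TRUE)$values))
}

#' Stationary covariance of an AR model
#'
#' Solves the discrete Lyapunov equation
#' `Sigma(X) = A Sigma(X) A^T + Sigma(E)` for the covariance of the
#' stationary distribution, by the vectorization identity
#' `vec(Sigma) = (I - A (x) A)^{-1} vec(Sigma(E))`.
#'
#' @param model an [ar_model()].
#' @return The `N x N` stationary covariance `Sigma(X)` (symmetric
#'   positive definite).
#' @examples
#' m <- ar_model(matrix(c(0.5, 0, 0, 0.5), 2, 2), diag(2))
#' stationary_covariance(m)  # diag(4/3, 4/3)
#' @export
stationary_covariance <- function(model) {
  stopifnot(inherits(model, "ar_model"))
  N <- model$N
  S <- matrix(
    solve(diag(N * N) - kronecker(model$A, model$A), as.vector(model$SigmaE)),
    N, N
  )
  (S + t(S)) / 2
}

#' Lag-one cross-covariance of a stationary AR model
#'
#' Computes `Sigma(X, X') = Sigma(X) A^T`, the covariance between the past
#' state `X` and the present state `X'`.
#'
#' @param SigmaX `N x N` stationary covariance of `X`.
#' @param A `N x N` connectivity matrix.
#' @return The `N x N` matrix `Sigma(X, X')` with entry `(i, j)` equal to
#'   `cov(X_i, X'_j)`.
#' @export
cross_covariance <- function(SigmaX, A) {
  SigmaX <- as.matrix(SigmaX)
  A <- as.matrix(A)
  if (!all(dim(SigmaX) == dim(A)) || nrow(A) != ncol(A)) {
    stop("SigmaX and A must be square matrices of the same size")
  }
  SigmaX %*% t(A)
}

#' Simulate a stationary AR time series
#'
#' Draws the initial state from the stationary distribution and iterates
#' `X' = A X + E`.
#'
#' @param model an [ar_model()].
#' @param T_len number of samples to generate (rows of the output).
#' @param seed optional integer seed; when supplied the series is
#'   reproducible.
#' @return A `T_len x N` numeric matrix; rows are time points, columns are
#'   elements.
#' @export
simulate_ar <- function(model, T_len, seed = NULL) {
  stopifnot(inherits(model, "ar_model"))
  if (T_len < 1) stop("T_len must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  N <- model$N
  SX <- stationary_covariance(model)
  X <- matrix(0, T_len, N)
  X[1, ] <- MASS::mvrnorm(1, rep(0, N), SX)
  if (T_len > 1) {
    E <- MASS::mvrnorm(T_len - 1, rep(0, N), model$SigmaE)
    if (T_len == 2) E <- matrix(E, 1, N)
    tA <- t(model$A)
    for (t in 2:T_len) {
      X[t, ] <- X[t - 1, ] %*% tA + E[t - 1, ]
    }
  }
  X
}
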