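# Stationary joint Gaussian description of (X, X'): the sole input to all
# integrated-information computations.  Block convention is fixed: indices
# 1..N are the past X, N+1..2N the present X'.  All downstream code goes
# through the named block accessors, never raw offsets.

#' Construct a joint past--present Gaussian
#'
#' Wraps a `2N x 2N` covariance matrix of the stacked vector `(X, X')`,
#' with the fixed convention that indices `1..N` index the past state `X`
#' and `N+1..2N` the present state `X'`.
#'
#' @param Sigma numeric `2N x 2N` symmetric positive definite covariance.
#' @return An object of class `"joint_gaussian"` with fields `Sigma` and
#'   `N`, plus cached block views.
#' @seealso [ar_joint_gaussian()] to build one analytically from an AR
#'   model, [estimate_joint_gaussian()] to estimate one from a time
#'   series; accessors [past_cov()], [present_cov()], [lag_cov()].
#' @export
joint_gaussian <- function(Sigma) {
  Sigma <- as.matrix(Sigma)
  d <- nrow(Sigma)
  if (ncol(Sigma) != d || d %% 2 != 0) {
    stop("Sigma must be a square 2N x 2N matrix")
  }
  N <- d %/% 2
  if (N < 2) stop("joint Gaussian needs at least N = 2 elements")
  if (max(abs(Sigma - t(Sigma))) > 1e-6 * max(1, max(abs(Sigma)))) {
    stop("joint covariance must be symmetric")
  }
  Sigma <- (Sigma + t(Sigma)) / 2
  if (inherits(try(chol(Sigma), silent = TRUE), "try-error")) {
    stop("joint covariance must be positive definite")
  }
  structure(
    list(Sigma = Sigma, N = N),
    class = "joint_gaussian"
  )
}

#' @export
print.joint_gaussian <- function(x, ...) {
  cat(sprintf(
    "Joint past-present Gaussian: N = %d elements (%d x %d covariance)\n",
    x$N, 2 * x$N, 2 * x$N
  ))
  invisible(x)
}

#' Block accessors for a joint Gaussian
#'
#' `past_cov()` returns `Sigma(X)`, `present_cov()` returns `Sigma(X')`,
#' and `lag_cov()` returns the cross block `Sigma(X, X')` whose `(i, j)`
#' entry is `cov(X_i, X'_j)`.
#'
#' @param joint a [joint_gaussian()].
#' @return An `N x N` numeric matrix.
#' @export
past_cov <- function(joint) {
  stopifnot(inherits(joint, "joint_gaussian"))
  N <- joint$N
  joint$Sigma[seq_len(N), seq_len(N), drop = FALSE]
}

#' @rdname past_cov
#' @export
present_cov <- function(joint) {
  stopifnot(inherits(joint, "joint_gaussian"))
  N <- joint$N
  joint$Sigma[N + seq_len(N), N + seq_len(N), drop = FALSE]
}

#' @rdname past_cov
#' @export
lag_cov <- function(joint) {
  stopifnot(inherits(joint, "joint_gaussian"))
  N <- joint$N
  joint$Sigma[seq_len(N), N + seq_len(N), drop = FALSE]
}

#' Analytic joint Gaussian of a stationary AR model
#'
#' Assembles the `2N x 2N` stationary covariance of `(X, X')` from the
#' Lyapunov solution `Sigma(X)` and the cross block
#' `Sigma(X, X') = Sigma(X) A^T`; for a stationary source
#' `Sigma(X') = Sigma(X)`.
#'
#' @param model an [ar_model()].
#' @return A [joint_gaussian()].
#' @export
ar_joint_gaussian <- function(model) {
  SX <- stationary_covariance(model)
  Cr <- cross_covariance(SX, model$A)
  joint_gaussian(rbind(cbind(SX, Cr), cbind(t(Cr), SX)))
}

#' Estimate a joint Gaussian from a multichannel time series
#'
#' Approximates the joint past--present distribution of a recorded signal
#' (for example multichannel electrophysiology) with a Gaussian, using the
#' sample covariances of the lagged and leading segments of the series and
#' their lag-`lag` cross-covariance.  Covariances use the biased (`1/T`)
#' normalization and are symmetrized.
#'
#' @param series `T x N` numeric matrix; rows are samples, columns are
#'   channels.
#' @param lag lag in samples between past and present (default 1; e.g. one
#'   sample equals 10 ms for a 100 Hz signal).
#' @return A [joint_gaussian()].
#' @details If the assembled `2N x 2N` covariance is numerically rank
#'   deficient, a diagonal jitter of `1e-10 * trace / (2N)` is added once,
#'   with a warning.  Constant (zero-variance) channels are an error.
#' @export
estimate_joint_gaussian <- function(series, lag = 1) {
  series <- as.matrix(series)
  T_len <- nrow(series)
  N <- ncol(series)
  if (lag < 0) stop("lag must be nonnegative")
  if (T_len <= lag + N) {
    stop("series too short for a full-rank estimate: need T > lag + N")
  }
  v <- apply(series, 2, stats::var)
  if (any(v <= 0)) {
    stop(
      "constant (zero-variance) channel(s): ",
      paste(which(v <= 0), collapse = ", ")
    )
  }
  past <- series[seq_len(T_len - lag), , drop = FALSE]
  pres <- series[lag + seq_len(T_len - lag), , drop = FALSE]
  n <- nrow(past)
  cp <- sweep(past, 2, colMeans(past))
  cq <- sweep(pres, 2, colMeans(pres))
  SX <- crossprod(cp) / n
  SXp <- crossprod(cq) / n
  Cr <- crossprod(cp, cq) / n
  SX <- (SX + t(SX)) / 2
  SXp <- (SXp + t(SXp)) / 2
  Sigma <- rbind(cbind(SX, Cr), cbind(t(Cr), SXp))
  Sigma <- (Sigma + t(Sigma)) / 2
  if (inherits(try(chol(Sigma), silent = TRUE), "try-error")) {
    eps <- 1e-10 * sum(diag(Sigma)) / (2 * N)
    warning(
      "estimated joint covariance is rank deficient; ",
      "adding diagonal jitter ", format(eps)
    )
    Sigma <- Sigma + diag(eps, 2 * N)
  }
  joint_gaussian(Sigma)
}
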