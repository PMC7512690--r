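# Counted Phi oracle: the set-function view Phi(S) of a fixed measure on a
# fixed joint Gaussian, with an evaluation counter.  All searchers consume
# this interface, and all reported evaluation counts come from it.

#' Counted integrated-information oracle
#'
#' Binds a measure (`"mi"`, `"si"` or `"g"`) to a [joint_gaussian()] and
#' exposes the symmetric set function `Phi(S)` with an evaluation counter.
#' Partition-independent quantities (Lyapunov blocks, full and conditional
#' log-determinants, the full regression) are precomputed once.
#'
#' The counter increments on every requested evaluation, including
#' repeated subsets.  With `cache = TRUE` repeated requests are answered
#' from a memo table -- the counter still increments, so counts reflect
#' the number of requests, not the computational work.  Counting-mode
#' reports (e.g. the pendant-pair evaluation counts) must use
#' `cache = FALSE`.
#'
#' Empty and full subsets describe the unpartitioned system, for which
#' every measure is 0; such requests return 0 and are counted.
#'
#' @param joint a [joint_gaussian()].
#' @param measure one of `"mi"`, `"si"`, `"g"`.
#' @param cache memoize values by canonical subset (default `FALSE`).
#' @param tol,max_iter passed to the `phi_g` solver when `measure = "g"`.
#' @return An object of class `"phi_oracle"`: a list with elements
#'   `value(S)` (numeric Phi of subset `S`), `count()`, `reset()`, `N`,
#'   and `measure`.
#' @examples
#' j <- ar_joint_gaussian(ar_model(diag(0.4, 3), diag(3)))
#' o <- phi_oracle(j, "mi")
#' o$value(c(1, 2))
#' o$count()
#' @export
phi_oracle <- function(joint, measure = c("mi", "si", "g"), cache = FALSE,
                       tol = 1e-8, max_iter = 10000) {
  measure <- match.arg(measure)
  jd <- joint_precompute(joint)
  N <- jd$N
  eval_fn <- switch(measure,
    mi = function(parts) phi_mi_value(jd, parts),
    si = function(parts) phi_si_value(jd, parts),
    g  = function(parts) phi_g_value(jd, parts, tol, max_iter)$value
  )
  n_calls <- 0L
  memo <- if (cache) new.env(parent = emptyenv()) else NULL

  value <- function(S) {
    n_calls <<- n_calls + 1L
    S <- as.integer(S)
    k <- length(S)
    if (k == 0L || k == N) return(0)
    # canonical key: the side containing element 1
    Sc <- if (1L %in% S) sort(S) else setdiff(seq_len(N), S)
    if (cache) {
      key <- paste(Sc, collapse = ".")
      hit <- memo[[key]]
      if (!is.null(hit)) return(hit)
    }
    v <- clamp_phi(eval_fn(list(Sc, setdiff(seq_len(N), Sc))),
                   toupper(measure))
    if (cache) memo[[key]] <- v
    v
  }

  structure(
    list(
      value = value,
      count = function() n_calls,
      reset = function() {
        n_calls <<- 0L
        invisible(NULL)
      },
      N = N,
      measure = measure
    ),
    class = "phi_oracle"
  )
}

#' @export
print.phi_oracle <- function(x, ...) {
  cat(sprintf(
    "Counted Phi_%s oracle on N = %d elements (%d evaluations so far)\n",
    toupper(x$measure), x$N, x$count()
  ))
  invisible(x)
}
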