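# Bipartitions of {1..N}.  A bipartition is identified with the unordered
# pair {S, complement(S)}; the canonical representative is the side that
# contains element 1.

#' Construct a canonical bipartition
#'
#' A bipartition divides the system `{1..N}` into a nonempty proper subset
#' `S` and its complement.  Since `S` and its complement describe the same
#' split, the stored representative is canonicalized to the side
#' containing element 1.
#'
#' @param S integer vector of member elements (1-based), nonempty and
#'   proper.
#' @param N system size.
#' @return An object of class `"bipartition"` with fields `S` (sorted,
#'   containing 1) and `N`.
#' @examples
#' bipartition(c(2, 3), 3)  # canonicalized to {1}
#' @export
bipartition <- function(S, N) {
  S <- sort(unique(as.integer(S)))
  N <- as.integer(N)
  if (N < 2) stop("bipartitions require N >= 2")
  if (length(S) == 0) stop("S must be nonempty")
  if (any(S < 1 | S > N)) stop("elements of S must lie in 1..", N)
  if (length(S) == N) stop("S must be a proper subset of 1..", N)
  if (!(1L %in% S)) S <- setdiff(seq_len(N), S)
  structure(list(S = S, N = N), class = "bipartition")
}

#' Canonical representative of a subset
#'
#' Maps any nonempty proper subset to the canonical [bipartition()]
#' representative (the side containing element 1).  Idempotent.
#'
#' @inheritParams bipartition
#' @return A [bipartition()].
#' @export
canonicalize <- function(S, N) {
  if (inherits(S, "bipartition")) return(S)
  bipartition(S, N)
}

#' @export
print.bipartition <- function(x, ...) {
  cat(sprintf(
    "Bipartition of 1..%d: {%s} | {%s}\n",
    x$N,
    paste(x$S, collapse = ","),
    paste(setdiff(seq_len(x$N), x$S), collapse = ",")
  ))
  invisible(x)
}

#' @export
format.bipartition <- function(x, ...) paste(x$S, collapse = ",")

#' Sign-vector view of a bipartition
#'
#' Encodes a bipartition as a vector `sigma` in `{-1, +1}^N`, with `+1`
#' marking members of the stored side `S`.
#'
#' @param part a [bipartition()].
#' @return Integer vector of length `N` with entries `+1` / `-1`.
#' @export
sign_vector <- function(part) {
  stopifnot(inherits(part, "bipartition"))
  sigma <- rep(-1L, part$N)
  sigma[part$S] <- 1L
  sigma
}

#' Parse a bipartition from text
#'
#' Inverse of `format()`: reads a comma-separated member list such as
#' `"1,4,7"`.
#'
#' @param text character scalar.
#' @param N system size.
#' @return A [bipartition()].
#' @export
parse_partition <- function(text, N) {
  S <- suppressWarnings(as.integer(strsplit(trimws(text), ",")[[1]]))
  if (any(is.na(S))) stop("could not parse partition text: ", text)
  bipartition(S, N)
}

#' Enumerate all canonical bipartitions
#'
#' Lists all `2^(N-1) - 1` distinct bipartitions of `{1..N}` in a fixed
#' deterministic order (by the bitmask of members `2..N` joining element
#' 1's side).
#'
#' @param N system size.
#' @param cap refusal threshold: enumeration above this size is rejected
#'   with a pointer to the heuristic searchers (default 24).
#' @return A list of [bipartition()] objects, length `2^(N-1) - 1`.
#' @export
enumerate_bipartitions <- function(N, cap = 24) {
  N <- as.integer(N)
  if (N < 2) stop("N must be at least 2")
  if (N > cap) {
    stop(
      "N = ", N, " exceeds the enumeration cap (", cap, "); ",
      "use queyranne_mip() or remcmc_mip() instead"
    )
  }
  n_parts <- 2^(N - 1) - 1
  rest <- seq_len(N)[-1]
  out <- vector("list", n_parts)
  for (mask in seq_len(n_parts) - 1L) {
    members <- c(1L, rest[bitwAnd(mask, bitwShiftL(1L, seq_len(N - 1) - 1L)) > 0])
    out[[mask + 1L]] <- bipartition(members, N)
  }
  out
}

# Equality of the splits described by two bipartitions.
same_partition <- function(p1, p2) {
  p1 <- canonicalize(p1$S, p1$N)
  p2 <- canonicalize(p2$S, p2$N)
  p1$N == p2$N && length(p1$S) == length(p2$S) && all(p1$S == p2$S)
}
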