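# Replica-exchange MCMC (parallel tempering) minimization over bipartition
# space, sampling the Boltzmann family p(S; beta) proportional to
# exp(-beta * Phi(S)) at a ladder of inverse temperatures.

#' Configuration for the replica-exchange MCMC searcher
#'
#' @param replicas number of replicas `R` (default 8).
#' @param beta_min,beta_max ends of the geometric inverse-temperature
#'   ladder.  When `NULL` (default) both are set from a seeded pilot run:
#'   the typical single-flip energy change `s` is measured on random
#'   partitions and the ladder spans `0.1/s` (hottest replica nearly
#'   free) to `4.6/s` (coldest replica accepting roughly 1% of uphill
#'   flips).
#' @param max_sweeps hard cap on sweeps (default `2000 * 1` scaled by
#'   nothing; see [remcmc_mip()]).
#' @param window convergence window `W` in sweeps; `NULL` means `50 * N`.
#' @param pilot number of random partitions used by the ladder pilot.
#' @param seed integer master seed for the whole run.
#' @return A list of class `"remcmc_config"`.
#' @export
remcmc_config <- function(replicas = 8, beta_min = NULL, beta_max = NULL,
                          max_sweeps = 5000, window = NULL, pilot = 100,
                          seed = NULL) {
  if (replicas < 2) stop("need at least 2 replicas")
  structure(
    list(
      replicas = as.integer(replicas), beta_min = beta_min,
      beta_max = beta_max, max_sweeps = as.integer(max_sweeps),
      window = window, pilot = as.integer(pilot), seed = seed
    ),
    class = "remcmc_config"
  )
}

random_proper_subset <- function(N) {
  k <- sample.int(N - 1, 1)
  sort(sample.int(N, k))
}

#' Initialize a replica ensemble
#'
#' Draws a random bipartition for each replica (uniform over subset sizes
#' and memberships) and evaluates its energy through the counted oracle.
#'
#' @param oracle a [phi_oracle()].
#' @param betas strictly increasing vector of positive inverse
#'   temperatures, one per replica.
#' @return A `"replica_ensemble"`: membership matrix (`replicas x N`
#'   logical), energies, beta ladder, exchange counters, best-so-far
#'   state and sweep bookkeeping.
#' @export
new_replica_ensemble <- function(oracle, betas) {
  if (any(diff(betas) <= 0) || any(betas <= 0)) {
    stop("beta ladder must be strictly increasing and positive")
  }
  N <- oracle$N
  R <- length(betas)
  member <- matrix(FALSE, R, N)
  energy <- numeric(R)
  for (r in seq_len(R)) {
    S <- random_proper_subset(N)
    member[r, S] <- TRUE
    energy[r] <- oracle$value(S)
  }
  best <- which.min(energy)
  structure(
    list(
      N = N, betas = betas, member = member, energy = energy,
      best_S = which(member[best, ]), best_phi = energy[best],
      best_sweep = 0L,
      exch_attempt = numeric(R - 1), exch_accept = numeric(R - 1),
      sweep = 0L
    ),
    class = "replica_ensemble"
  )
}

#' Metropolis sweep over all replicas
#'
#' Each replica attempts `N` single-element membership flips in random
#' order at its own inverse temperature.  Proposals that would empty or
#' fill the subset are rejected without an oracle call; every other
#' proposal costs exactly one counted oracle evaluation and is accepted
#' with probability `min(1, exp(-beta * deltaPhi))`.  The best-so-far
#' partition is updated whenever a replica reaches a strictly lower
#' energy.
#'
#' @param ensemble a [new_replica_ensemble()].
#' @param oracle the [phi_oracle()] the ensemble was built with.
#' @return The updated ensemble.
#' @export
mh_sweep <- function(ensemble, oracle) {
  N <- ensemble$N
  R <- length(ensemble$betas)
  ensemble$sweep <- ensemble$sweep + 1L
  for (r in seq_len(R)) {
    mem <- ensemble$member[r, ]
    e <- ensemble$energy[r]
    beta <- ensemble$betas[r]
    # random scan: a fixed visiting order would make every non-uphill
    # accept deterministic, collapsing the infinite-temperature chain
    # onto a periodic orbit
    for (i in sample.int(N)) {
      k <- sum(mem)
      # flipping i would empty or fill the subset: reject outright
      if ((mem[i] && k == 1L) || (!mem[i] && k == N - 1L)) next
      mem[i] <- !mem[i]
      e_new <- oracle$value(which(mem))
      d <- e_new - e
      if (d <= 0 || stats::runif(1) < exp(-beta * d)) {
        e <- e_new
        if (e < ensemble$best_phi) {
          ensemble$best_phi <- e
          ensemble$best_S <- which(mem)
          ensemble$best_sweep <- ensemble$sweep
        }
      } else {
        mem[i] <- !mem[i]
      }
    }
    ensemble$member[r, ] <- mem
    ensemble$energy[r] <- e
  }
  ensemble
}

#' Replica-exchange step
#'
#' Neighboring replica pairs (alternating even/odd pairing across calls)
#' swap their states with probability
#' `min(1, exp((beta_i - beta_j) * (Phi_i - Phi_j)))`.  No oracle calls
#' are made; per-pair attempt/acceptance counters are updated.
#'
#' @param ensemble a [new_replica_ensemble()].
#' @return The updated ensemble.
#' @export
exchange_step <- function(ensemble) {
  R <- length(ensemble$betas)
  if (R < 2) stop("exchange needs at least 2 replicas")
  first <- if (ensemble$sweep %% 2L == 0L) 2L else 1L
  if (first > R - 1L) return(ensemble)
  for (i in seq(first, R - 1L, by = 2L)) {
    j <- i + 1L
    ensemble$exch_attempt[i] <- ensemble$exch_attempt[i] + 1
    logp <- (ensemble$betas[i] - ensemble$betas[j]) *
      (ensemble$energy[i] - ensemble$energy[j])
    if (logp >= 0 || stats::runif(1) < exp(logp)) {
      tmp <- ensemble$member[i, ]
      ensemble$member[i, ] <- ensemble$member[j, ]
      ensemble$member[j, ] <- tmp
      te <- ensemble$energy[i]
      ensemble$energy[i] <- ensemble$energy[j]
      ensemble$energy[j] <- te
      ensemble$exch_accept[i] <- ensemble$exch_accept[i] + 1
    }
  }
  ensemble
}

#' Replica-exchange MCMC minimum information partition search
#'
#' Alternates Metropolis sweeps ([mh_sweep()]) and replica exchanges
#' ([exchange_step()]) until convergence or `max_sweeps`.  Convergence is
#' declared when (a) the best-so-far partition has not changed for
#' `window` consecutive sweeps and (b) every neighboring-pair exchange
#' rate over that window lies in `[0.1, 0.9]`; if the rate condition
#' cannot be met the run continues to `max_sweeps` and is flagged
#' unconverged (the best-so-far result is still returned).
#'
#' The whole run -- ladder pilot, initialization, proposals, exchanges --
#' is driven by a single RNG stream seeded from `config$seed`, so a fixed
#' seed and configuration reproduce the trajectory exactly.
#'
#' @param oracle a [phi_oracle()] (a cached oracle speeds the run up
#'   without changing the trajectory or the request counts).
#' @param config a [remcmc_config()].
#' @return A `"mip_result"` with `method = "remcmc"` and a `diagnostics`
#'   list: `converged`, `sweeps`, `solution_found_sweep` (sweep at which
#'   the final best was first reached), `evals_at_solution` (oracle
#'   requests up to that point), `exchange_rates` (per neighboring pair),
#'   and the beta ladder.
#' @export
remcmc_mip <- function(oracle, config = remcmc_config()) {
  stopifnot(inherits(oracle, "phi_oracle"))
  N <- oracle$N
  if (!is.null(config$seed)) set.seed(config$seed)
  oracle$reset()
  window <- if (is.null(config$window)) 50L * N else as.integer(config$window)

  beta_min <- config$beta_min
  beta_max <- config$beta_max
  if (is.null(beta_min) || is.null(beta_max)) {
    # pilot: typical |deltaPhi| of a single membership flip sets the
    # energy scale of the ladder
    dE <- numeric(config$pilot)
    for (p in seq_len(config$pilot)) {
      S <- random_proper_subset(N)
      e0 <- oracle$value(S)
      repeat {
        i <- sample.int(N, 1)
        S2 <- if (i %in% S) setdiff(S, i) else sort(c(S, i))
        if (length(S2) > 0 && length(S2) < N) break
      }
      dE[p] <- abs(oracle$value(S2) - e0)
    }
    s <- stats::median(dE[dE > 0])
    if (!is.finite(s) || s <= 0) s <- max(stats::sd(dE), .Machine$double.eps)
    if (is.null(beta_min)) beta_min <- 0.6 / s
    if (is.null(beta_max)) beta_max <- 4.6 / s
  }
  betas <- exp(seq(log(beta_min), log(beta_max),
                   length.out = config$replicas))

  ens <- new_replica_ensemble(oracle, betas)
  evals_at_best <- oracle$count()
  last_best_sweep <- 0L
  win_attempt <- ens$exch_attempt
  win_accept <- ens$exch_accept
  converged <- FALSE
  repeat {
    prev_best <- ens$best_phi
    ens <- mh_sweep(ens, oracle)
    ens <- exchange_step(ens)
    if (ens$best_phi < prev_best) {
      evals_at_best <- oracle$count()
      last_best_sweep <- ens$sweep
      win_attempt <- ens$exch_attempt
      win_accept <- ens$exch_accept
    }
    if (ens$sweep - last_best_sweep >= window) {
      att <- ens$exch_attempt - win_attempt
      acc <- ens$exch_accept - win_accept
      rates <- ifelse(att > 0, acc / att, 0)
      if (all(rates >= 0.1 & rates <= 0.9)) {
        converged <- TRUE
        break
      }
      # rates outside band: slide the window forward and keep sampling
      last_best_sweep <- ens$sweep
      win_attempt <- ens$exch_attempt
      win_accept <- ens$exch_accept
    }
    if (ens$sweep >= config$max_sweeps) break
  }

  rates <- ifelse(ens$exch_attempt > 0,
                  ens$exch_accept / ens$exch_attempt, NA_real_)
  new_mip_result(
    partition = bipartition(ens$best_S, N),
    phi = ens$best_phi,
    n_evals = oracle$count(),
    method = "remcmc",
    measure = oracle$measure,
    diagnostics = list(
      converged = converged,
      sweeps = ens$sweep,
      solution_found_sweep = ens$best_sweep,
      evals_at_solution = evals_at_best,
      exchange_rates = rates,
      betas = betas
    )
  )
}
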