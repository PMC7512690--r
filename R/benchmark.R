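# Random AR network generators, search-accuracy metrics, and the
# simulation benchmark harness comparing the searchers.

#' Generate a random AR network
#'
#' Samples a stationary AR(1) model of one of two architectures:
#'
#' * `kind = "normal"`: every entry of the connectivity matrix `A` is iid
#'   normal with mean 0 and variance `0.01 / N`.
#' * `kind = "block"`: `A` consists of two `N/2 x N/2` diagonal blocks
#'   with iid normal entries of variance `0.02 / N`; the off-diagonal
#'   blocks are exactly zero, so there is no causal interaction between
#'   the halves.
#'
#' The noise covariance `Sigma(E)` is drawn from a Wishart distribution
#' with scale matrix `sigma * I` and `2N` degrees of freedom (mean
#' `2N * sigma * I`).  Draws of `A` whose spectral radius reaches 1 are
#' rejected and resampled (statistically negligible at these variances);
#' a resample cap guards against misuse.
#'
#' @param kind `"normal"` or `"block"`.
#' @param N number of elements (even when `kind = "block"`).
#' @param sigma Wishart scale of the noise covariance (default 0.1).
#' @param seed optional integer seed.
#' @param max_resample cap on stationarity resampling attempts.
#' @return An [ar_model()].
#' @export
generate_network <- function(kind = c("normal", "block"), N, sigma = 0.1,
                             seed = NULL, max_resample = 100) {
  kind <- match.arg(kind)
  if (sigma <= 0) stop("sigma must be positive")
  if (kind == "block" && N %% 2 != 0) {
    stop("block networks require an even number of elements")
  }
  if (!is.null(seed)) set.seed(seed)
  draw_A <- function() {
    if (kind == "normal") {
      matrix(stats::rnorm(N * N, 0, sqrt(0.01 / N)), N, N)
    } else {
      h <- N %/% 2
      A <- matrix(0, N, N)
      A[seq_len(h), seq_len(h)] <-
        stats::rnorm(h * h, 0, sqrt(0.02 / N))
      A[h + seq_len(h), h + seq_len(h)] <-
        stats::rnorm(h * h, 0, sqrt(0.02 / N))
      A
    }
  }
  A <- draw_A()
  tries <- 0
  while (spectral_radius(A) >= 1 - 1e-9) {
    tries <- tries + 1
    if (tries > max_resample) {
      stop("could not draw a stationary connectivity matrix")
    }
    A <- draw_A()
  }
  SigmaE <- stats::rWishart(1, df = 2 * N, Sigma = diag(sigma, N))[, , 1]
  ar_model(A, SigmaE)
}

#' Error ratio of a found partition
#'
#' `(Phi_Q - Phi_MIP) / (Phi_bar - Phi_MIP)`: the excess integrated
#' information at the found partition, normalized by the mean excess over
#' all partitions.  0 when the search hits the MIP; by convention 0 when
#' numerator and denominator both vanish (all partitions equivalent).
#'
#' @param phi_q Phi at the found partition.
#' @param phi_mip Phi at the true MIP.
#' @param phi_bar mean Phi over all canonical bipartitions.
#' @return The error ratio (nonnegative).
#' @export
error_ratio <- function(phi_q, phi_mip, phi_bar) {
  if (phi_bar < phi_mip - 1e-9) {
    stop("phi_bar < phi_mip: the mean over partitions cannot undercut the minimum")
  }
  num <- phi_q - phi_mip
  den <- phi_bar - phi_mip
  if (abs(den) < .Machine$double.eps) {
    if (abs(num) < 1e-12) return(0)
    stop("degenerate error ratio: zero denominator with nonzero numerator")
  }
  num / den
}

#' Absolute sign-vector correlation between two bipartitions
#'
#' Encodes each bipartition as a sign vector in `{-1, +1}^N` and returns
#' the absolute Pearson correlation.  The absolute value makes the metric
#' invariant to exchanging either side with its complement; identical
#' splits give 1.
#'
#' @param p1,p2 [bipartition()] objects on the same `N`.
#' @return Numeric in `[0, 1]`.
#' @export
partition_correlation <- function(p1, p2) {
  stopifnot(inherits(p1, "bipartition"), inherits(p2, "bipartition"))
  if (p1$N != p2$N) stop("bipartitions must be over the same system size")
  s1 <- sign_vector(p1)
  s2 <- sign_vector(p2)
  c1 <- s1 - mean(s1)
  c2 <- s2 - mean(s2)
  abs(sum(c1 * c2) / sqrt(sum(c1^2) * sum(c2^2)))
}

# metrics of one search result against an exhaustive ranking
trial_metrics <- function(exh, found_part, found_phi, tol = 1e-9) {
  phis <- exh$ranking$phi
  phi_mip <- phis[1]
  phi_bar <- mean(phis)
  # any partition within tolerance of the minimum counts as a correct hit
  minimizers <- exh$ranking$partition[phis <= phi_mip + tol]
  found_txt <- paste(found_part$S, collapse = ",")
  cr <- found_txt %in% minimizers
  rank <- sum(phis < found_phi - 1e-12) + 1
  er <- error_ratio(found_phi, phi_mip, phi_bar)
  corr <- partition_correlation(exh$partition, found_part)
  if (cr) corr <- 1  # correct hit: compare against the matched minimizer
  list(
    cr = cr, rank = rank, er = er, corr = corr,
    phi_mip = phi_mip, phi_bar = phi_bar
  )
}

#' Accuracy benchmark against exhaustive ground truth
#'
#' For each trial: generate a random AR network, form its analytic joint
#' Gaussian, find the MIP exhaustively (retaining the full ranking), run
#' Queyranne's algorithm, and score the result with four metrics --
#' correct rate (CR), rank (RA), error ratio (ER) and sign-vector
#' correlation (CORR).  Correct hits require the found partition to equal
#' some exact minimizer (ties within `1e-9` in Phi all count).
#'
#' @param N system size (within the enumeration cap; default 14).
#' @param kinds network architectures to test.
#' @param sigmas Wishart noise scales to test.
#' @param measures integrated-information measures to test.
#' @param trials random networks per setting (default 100).
#' @param seed master seed; per-trial seeds are derived from it, so the
#'   full output is a pure function of this value.
#' @return A list with `trials` (one row per trial: setting, seed,
#'   ground-truth and found partitions, Phi values, metrics, evaluation
#'   counts) and `summary` (metric means per setting), both data frames.
#' @export
run_accuracy_benchmark <- function(N = 14,
                                   kinds = c("normal", "block"),
                                   sigmas = c(0.01, 0.1),
                                   measures = c("si", "g"),
                                   trials = 100,
                                   seed = 1) {
  set.seed(seed)
  trial_seeds <- sample.int(.Machine$integer.max, trials)
  rows <- list()
  for (kind in kinds) {
    for (sigma in sigmas) {
      for (trial in seq_len(trials)) {
        model <- generate_network(kind, N, sigma, seed = trial_seeds[trial])
        joint <- ar_joint_gaussian(model)
        for (measure in measures) {
          exh <- exhaustive_mip(phi_oracle(joint, measure, cache = TRUE),
                                ranking = TRUE)
          qy <- queyranne_mip(phi_oracle(joint, measure))
          met <- trial_metrics(exh, qy$partition, qy$phi)
          rows[[length(rows) + 1]] <- data.frame(
            kind = kind, sigma = sigma, measure = measure, trial = trial,
            trial_seed = trial_seeds[trial],
            mip = format(exh$partition), found = format(qy$partition),
            phi_mip = met$phi_mip, phi_q = qy$phi, phi_bar = met$phi_bar,
            cr = met$cr, rank = met$rank, er = met$er, corr = met$corr,
            n_evals_exhaustive = exh$n_evals, n_evals_queyranne = qy$n_evals,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  trials_df <- do.call(rbind, rows)
  agg <- aggregate(
    cbind(cr, rank, er, corr) ~ kind + sigma + measure,
    data = trials_df, FUN = mean
  )
  names(agg) <- c("kind", "sigma", "measure", "CR", "RA", "ER", "CORR")
  list(trials = trials_df, summary = agg)
}

#' Comparison benchmark: Queyranne vs replica-exchange MCMC
#'
#' For systems too large for exhaustive search, runs both heuristics on
#' the same random networks and compares them by the amount of integrated
#' information at the returned partitions.  A trial is scored "even" when
#' the two Phi values agree within `tol`; otherwise the searcher with the
#' lower Phi wins.  Evaluation counts and the REMCMC retrospective
#' solution-found statistics are aggregated.
#'
#' @inheritParams run_accuracy_benchmark
#' @param measure single measure to use (default `"si"`).
#' @param remcmc a [remcmc_config()] template; its seed is replaced by a
#'   per-trial derived seed.
#' @param include_exhaustive also run exhaustive search (small `N` only)
#'   as ground truth.
#' @param tol Phi tolerance for calling a trial even.
#' @return A list with `trials` and `summary` data frames; the summary
#'   holds winning percentages and evaluation-count statistics
#'   (mean and sd).
#' @export
run_comparison_benchmark <- function(N = 20,
                                     measure = "si",
                                     kinds = c("normal", "block"),
                                     sigmas = c(0.01, 0.1),
                                     trials = 20,
                                     seed = 1,
                                     remcmc = remcmc_config(),
                                     include_exhaustive = FALSE,
                                     tol = 1e-9) {
  set.seed(seed)
  trial_seeds <- sample.int(2^30, trials)
  rows <- list()
  for (kind in kinds) {
    for (sigma in sigmas) {
      for (trial in seq_len(trials)) {
        model <- generate_network(kind, N, sigma, seed = trial_seeds[trial])
        joint <- ar_joint_gaussian(model)
        qy <- queyranne_mip(phi_oracle(joint, measure))
        cfg <- remcmc
        cfg$seed <- trial_seeds[trial] + 1
        rem <- remcmc_mip(phi_oracle(joint, measure, cache = TRUE), cfg)
        winner <- if (abs(qy$phi - rem$phi) <= tol) {
          "even"
        } else if (qy$phi < rem$phi) "queyranne" else "remcmc"
        row <- data.frame(
          kind = kind, sigma = sigma, measure = measure, trial = trial,
          trial_seed = trial_seeds[trial],
          queyranne = format(qy$partition), remcmc = format(rem$partition),
          same_partition = same_partition(qy$partition, rem$partition),
          phi_queyranne = qy$phi, phi_remcmc = rem$phi, winner = winner,
          n_evals_queyranne = qy$n_evals, n_evals_remcmc = rem$n_evals,
          remcmc_converged = rem$diagnostics$converged,
          solution_found_evals = rem$diagnostics$evals_at_solution,
          stringsAsFactors = FALSE
        )
        if (include_exhaustive) {
          exh <- exhaustive_mip(phi_oracle(joint, measure, cache = TRUE))
          row$phi_exhaustive <- exh$phi
          row$queyranne_matches_exhaustive <-
            same_partition(qy$partition, exh$partition)
          row$remcmc_matches_exhaustive <-
            same_partition(rem$partition, exh$partition)
        }
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  trials_df <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(
    split(trials_df, list(trials_df$kind, trials_df$sigma), drop = TRUE),
    function(d) data.frame(
      kind = d$kind[1], sigma = d$sigma[1], measure = measure,
      win_queyranne = mean(d$winner == "queyranne"),
      win_even = mean(d$winner == "even"),
      win_remcmc = mean(d$winner == "remcmc"),
      evals_queyranne = mean(d$n_evals_queyranne),
      evals_remcmc_mean = mean(d$n_evals_remcmc),
      evals_remcmc_sd = stats::sd(d$n_evals_remcmc),
      solution_found_mean = mean(d$solution_found_evals),
      solution_found_sd = stats::sd(d$solution_found_evals),
      stringsAsFactors = FALSE
    )
  ))
  rownames(summ) <- NULL
  list(trials = trials_df, summary = summ)
}
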