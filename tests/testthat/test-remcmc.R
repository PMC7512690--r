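# Replica-exchange MCMC: Metropolis sweeps, exchanges, and minimization.

test_that("a near-infinite-temperature replica visits all splits uniformly", {
  set.seed(61)
  j <- rand_strong_joint(3)
  o <- phi_oracle(j, "si", cache = TRUE)
  ens <- new_replica_ensemble(o, betas = 1e-12)
  counts <- c("1" = 0, "1,2" = 0, "1,3" = 0)
  for (s in 1:3000) {
    ens <- mh_sweep(ens, o)
    key <- format(bipartition(which(ens$member[1, ]), 3))
    counts[key] <- counts[key] + 1
  }
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("exchange swaps equal-energy neighbors with certainty", {
  set.seed(62)
  j <- rand_strong_joint(4)
  o <- phi_oracle(j, "si", cache = TRUE)
  ens <- new_replica_ensemble(o, betas = c(1, 2))
  # force distinct states with identical energies (a split and its complement)
  ens$member[1, ] <- c(TRUE, FALSE, TRUE, FALSE)
  ens$member[2, ] <- c(FALSE, TRUE, FALSE, TRUE)
  e <- o$value(c(1, 3))
  ens$energy <- c(e, e)
  ens$sweep <- 1L  # odd parity pairs (1, 2)
  before <- ens$member
  ens <- exchange_step(ens)
  expect_identical(ens$member[1, ], before[2, ])
  expect_identical(ens$member[2, ], before[1, ])
  expect_identical(ens$exch_accept, 1)
  # the multiset of partitions is conserved by exchanges
  expect_setequal(
    apply(ens$member, 1, paste, collapse = ""),
    apply(before, 1, paste, collapse = "")
  )
})

test_that("two-replica joint distribution matches the product Boltzmann law", {
  set.seed(63)
  j <- rand_strong_joint(3, coupling = 0.6)
  o <- phi_oracle(j, "si", cache = TRUE)
  parts <- enumerate_bipartitions(3)
  energies <- vapply(parts, function(p) o$value(p$S), 0)
  betas <- c(2, 6) / max(energies - min(energies))
  ens <- new_replica_ensemble(o, betas)
  keys <- vapply(parts, format, "")
  counts <- matrix(0, 3, 3, dimnames = list(keys, keys))
  for (s in 1:30000) {
    ens <- mh_sweep(ens, o)
    ens <- exchange_step(ens)
    if (s %% 10 == 0) {  # thin to decorrelate successive sweeps
      k1 <- format(bipartition(which(ens$member[1, ]), 3))
      k2 <- format(bipartition(which(ens$member[2, ]), 3))
      counts[k1, k2] <- counts[k1, k2] + 1
    }
  }
  b1 <- exp(-betas[1] * energies)
  b2 <- exp(-betas[2] * energies)
  expected <- outer(b1 / sum(b1), b2 / sum(b2)) * sum(counts)
  stat <- sum((counts - expected)^2 / expected)
  expect_lt(stat, stats::qchisq(0.99, df = 8))
  # marginal of the cold replica concentrates on the minimum
  expect_identical(
    names(which.max(rowSums(t(counts)))),
    keys[which.min(energies)]
  )
})

test_that("remcmc finds the exhaustive minimum on small systems", {
  set.seed(64)
  hits <- 0
  for (rep in 1:10) {
    j <- rand_strong_joint(8, coupling = 0.3)
    e <- exhaustive_mip(phi_oracle(j, "si", cache = TRUE))
    r <- remcmc_mip(
      phi_oracle(j, "si", cache = TRUE),
      remcmc_config(seed = 6400 + rep, max_sweeps = 2000)
    )
    hits <- hits + phimip:::same_partition(e$partition, r$partition)
    expect_equal(r$phi, e$phi, tolerance = 1e-9)
  }
  expect_equal(hits, 10)
})

test_that("remcmc is reproducible and reports coherent diagnostics", {
  set.seed(65)
  j <- rand_strong_joint(7)
  cfg <- remcmc_config(seed = 99, max_sweeps = 800)
  r1 <- remcmc_mip(phi_oracle(j, "si", cache = TRUE), cfg)
  r2 <- remcmc_mip(phi_oracle(j, "si", cache = TRUE), cfg)
  expect_identical(format(r1$partition), format(r2$partition))
  expect_identical(r1$n_evals, r2$n_evals)
  expect_identical(r1$diagnostics$sweeps, r2$diagnostics$sweeps)
  expect_lte(r1$diagnostics$evals_at_solution, r1$n_evals)
  expect_lte(r1$diagnostics$solution_found_sweep, r1$diagnostics$sweeps)
})

test_that("both heuristics recover the causal split of a block model", {
  set.seed(66)
  m <- generate_network("block", 12, sigma = 0.1, seed = 660)
  j <- ar_joint_gaussian(m)
  half <- bipartition(1:6, 12)
  q <- queyranne_mip(phi_oracle(j, "g"))
  r <- remcmc_mip(
    phi_oracle(j, "g", cache = TRUE),
    remcmc_config(seed = 661, max_sweeps = 1500)
  )
  expect_true(phimip:::same_partition(q$partition, half))
  expect_true(phimip:::same_partition(r$partition, half))
  expect_lt(q$phi, 1e-8)
  expect_lt(r$phi, 1e-8)
})
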