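---
title: "Measuring integrated information and finding the minimum information partition"
author: "phimip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring integrated information and finding the minimum information partition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Throughout, a system of $N$ elements is described by the stationary joint
Gaussian distribution of its past state $X$ and present state $X'$ (one
lag apart). The $2N \times 2N$ covariance of $(X, X')$ is the sole input
to every measure; its blocks are $\Sigma(X)$, the cross block
$\Sigma(X, X')$ with entries $\mathrm{cov}(X_i, X'_j)$, and $\Sigma(X')$.
The block order (past first, present second) is fixed once and accessed
only through `past_cov()`, `present_cov()` and `lag_cov()`.

Two routes produce this object:

* **Analytically**, from a first-order autoregressive model
  $X' = AX + E$ with noise covariance $\Sigma(E)$. Stationarity requires
  the spectral radius of $A$ to be below 1; models at or above
  $1 - 10^{-9}$ are rejected rather than regularized, because every
  downstream quantity assumes the stationary distribution exists. The
  stationary covariance solves the discrete Lyapunov equation
  $\Sigma(X) = A\Sigma(X)A^\top + \Sigma(E)$, here by the vectorization
  identity $\mathrm{vec}\,\Sigma = (I - A \otimes A)^{-1}
  \mathrm{vec}\,\Sigma(E)$ — direct, and exact to solver precision at the
  sizes this package targets ($N \le 64$, where $A \otimes A$ is
  $4096^2$). The cross block is $\Sigma(X)A^\top$.
* **Empirically**, from a samples $\times$ channels time series via
  `estimate_joint_gaussian()`: biased ($1/T$) segment covariances and the
  lag-$\tau$ cross-covariance, symmetrized as $(\Sigma+\Sigma^\top)/2$.
  The biased normalization keeps the assembled matrix closer to positive
  definite than the $1/(T-1)$ form; if it is still numerically singular
  (e.g. at lag 0, where past and present segments coincide) a single
  diagonal jitter of $10^{-10}\,\mathrm{tr}(\Sigma)/2N$ is added with a
  warning. For a 100 Hz recording, a 1-minute window with a one-sample
  lag corresponds to 6000 samples and a 10 ms time step.

## Three measures, one template

Each measure is the Kullback–Leibler divergence from $p(X, X')$ to the
closest "disconnected" distribution $q$ in some constraint family; they
differ only in which cross-partition interactions the family removes.
For a bipartition into $M_1 = S$ and $M_2 = \Omega \setminus S$ (with
primed copies for the present):

* $\Phi_{MI} = H(M_1, M_1') + H(M_2, M_2') - H(X, X')$: $q$ makes the
  parts fully independent; everything between the parts counts.
* $\Phi_{SI} = \sum_i H(M_i' \mid M_i) - H(X' \mid X)$: $q$ factorizes
  the transition kernel, removing causal *and* equal-time
  cross-partition influence on the present.
* $\Phi_G$: $q$ satisfies only the Markov constraint
  $q(M_i' \mid X) = q(M_i' \mid M_i)$ — causal influence between parts is
  removed, equal-time correlation is retained.

All entropies are Gaussian closed forms,
$H = \tfrac12 \log\{(2\pi e)^k \det\Sigma\}$, with conditional
covariances via Schur complements. Natural logarithms everywhere: the
measures are reported in nats, and every quantity the benchmarks compare
(zeros, counts, rates) is base-invariant. Log-determinants are computed
from Cholesky factors; full covariances are never explicitly inverted,
which keeps the computation stable at $2N = 128$ dimensions. Values in
$(-10^{-9}, 0)$ are clamped to zero as float noise; anything more
negative raises an error, since a genuinely negative Φ always indicates a
defect, not a result.

The families are nested (independence $\subset$ factorized transition
$\subset$ Markov constraint), which yields the ordering
$\Phi_G \le \Phi_{SI} \le \Phi_{MI}$ on every instance — enforced as a
property test over 1000 random models.

## The geometric measure: a block-coordinate solver

$\Phi_G$ has no closed form. The package parameterizes the constrained
family as $q(X) = p(X)$, $q(X' \mid X) = \mathcal N(A'X, \Sigma')$ with
$A'$ block-diagonal in the partition and $\Sigma'$ a free symmetric PD
matrix. Writing $B$ for the unconstrained regression of $X'$ on $X$,
$\Sigma_c$ for the conditional covariance of $X' \mid X$ under $p$, and
$\Delta = B - A'$:

$$2\,\mathrm{KL}(p \,\|\, q) = \mathrm{tr}\!\left[\Sigma'^{-1}
\left(\Sigma_c + \Delta\,\Sigma(X)\,\Delta^\top\right)\right]
+ \log\det\Sigma' - \log\det\Sigma_c - N.$$

Both blocks of coordinates admit exact minimizers:

* $\Sigma'$ given $A'$: $\Sigma' = \Sigma_c + \Delta\,\Sigma(X)\,
  \Delta^\top$ (closed form).
* $A'$ given $\Sigma'$: the stationarity condition
  $[\Sigma'^{-1}(B - A')\Sigma(X)]_{S_i,S_i} = 0$ for each part is a
  linear (generalized Sylvester) system in the free blocks of $A'$,
  solved by vectorization — at most $(N-1)^2 + 1$ unknowns for a
  bipartition.

Alternating the two exact half-steps gives a monotonically
non-increasing objective. Iteration starts from $A'$ equal to $B$
restricted to its within-part blocks and stops when the maximum absolute
change of $A'$ falls below `tol` ($10^{-8}$ by default; `max_iter`
10,000). Exceeding `max_iter` raises an error carrying the last residual
— never a silent partial value. After the final $\Sigma'$ half-step the
trace term equals $N$ exactly, so
$\Phi_G = \tfrac12(\log\det\Sigma' - \log\det\Sigma_c)$. On weakly
coupled networks convergence takes a handful of iterations;
block-coordinate descent on this objective is the natural iterative
scheme, and the test suite cross-checks it at $N = 4$ against a generic
BFGS minimization over all free parameters of $q$ (agreement to
$10^{-5}$).

A useful exact special case: when the connectivity is block-diagonal
with respect to the partition, $A' = A$ and $\Sigma' = \Sigma(E)$ are
feasible, so $\Phi_G = 0$ across that split *regardless of noise
correlations* — the solver reproduces this to machine precision, and the
benchmark uses it as a known ground truth.

## Search

A bipartition is identified with the unordered pair
$\{S, \Omega\setminus S\}$; the canonical representative contains
element 1, giving $2^{N-1}-1$ distinct splits. Φ is symmetric under
complementation (checked exactly in tests), which is what the searchers
exploit. Elements are 1-based everywhere a user sees them.

**Exhaustive** search enumerates canonical subsets in bitmask order and
optionally retains the full ascending ranking — the accuracy benchmark
needs it for ranks and for $\bar\Phi$, the mean over all partitions.

**Queyranne's algorithm** performs $N-1$ pendant-pair phases. A phase
builds a maximum-adjacency ordering: starting from the merged element
with the lowest original index, it repeatedly appends the candidate $u$
minimizing the key $f(W \cup \{u\}) - f(\{u\})$ (for a graph cut function
this equals $f(W) - 2w(W,u)$, so minimizing the key maximizes adjacency).
The last ordered element is the phase's candidate cut; the pair of last
two elements is merged and the best candidate across phases is returned.
For symmetric submodular $f$ (here $\Phi_{MI}$) this is an exact
minimizer; for $\Phi_{SI}$ and $\Phi_G$ it is a heuristic whose accuracy
the benchmarks quantify. Ties in the key pick the lowest original index
and candidate-cut ties keep the earliest phase, making the search fully
deterministic.

*Evaluation counting.* Reported counts follow a fixed convention: every
key evaluation requests both $f(W \cup \{u\})$ and $f(\{u\})$ from the
counted oracle with no memoization — including forced choices with a
single remaining candidate — and each phase adds one counted request for
its candidate cut. The total is then a function of $N$ alone:
$$\#\text{evals} = \tfrac{N^3 - N}{3} + N - 1,$$
i.e. 2679 at $N=20$, 41,699 at $N=50$, 87,423 at $N=64$. A cached oracle
(`phi_oracle(..., cache = TRUE)`) answers repeated requests from a memo
table for speed; the counter still counts requests, so counting-mode
reports must use an uncached oracle.

**Replica-exchange MCMC** treats $\Phi$ as an energy and samples
$p(S;\beta) \propto e^{-\beta\Phi(S)}$ at $R = 8$ inverse temperatures
simultaneously. Design choices, each of which was genuinely open:

* *Proposals*: single-membership flips, attempted $N$ per sweep per
  replica in **random** order. A fixed scan order would make every
  non-uphill acceptance deterministic; in the infinite-temperature limit
  the chain would collapse onto a periodic orbit of involutions and stop
  mixing (a property test at $\beta \to 0$ guards exactly this).
  Proposals that would empty or fill the subset are rejected without an
  oracle call.
* *Ladder*: geometric between $\beta_{\min} = 0.6/s$ and
  $\beta_{\max} = 4.6/s$, where $s$ is the median absolute single-flip
  energy change measured by a 100-partition pilot run (counted as
  ordinary oracle requests). The scaling makes the coldest replica
  accept roughly $e^{-4.6} \approx 1\%$ of typical uphill moves while
  the hottest moves almost freely; the $0.6$ factor spaces the hot end
  widely enough that neighboring-pair exchange rates stay below 0.9.
* *Exchanges*: after each sweep, neighboring pairs (alternating even/odd
  pairing) swap with probability
  $\min\{1, \exp[(\beta_i-\beta_j)(\Phi_i-\Phi_j)]\}$ — no oracle calls.
* *Convergence*: declared when the best-so-far partition has been stable
  for a window of $50N$ sweeps *and* every neighboring exchange rate
  over that window lies in $[0.1, 0.9]$; otherwise the run continues to
  `max_sweeps` and is flagged unconverged (the best-so-far result is
  still returned and compared). This criterion is a pragmatic stand-in:
  stability-of-solution plus evidence that the ladder actually mixes.
* *RNG*: one master seed drives a single stream through pilot,
  initialization, proposals and exchanges, so a fixed seed reproduces
  the whole trajectory bit-for-bit. Per-replica streams were considered
  and rejected as complexity without a reproducibility gain here.

Sampling correctness is tested directly: a single replica at fixed
$\beta$ on an $N=8$ system is compared against the exact Boltzmann
distribution from full enumeration (thinned χ² test), and a two-replica
ensemble against the product-Boltzmann joint law.

## The synthetic benchmark

`generate_network()` draws the two study architectures: *normal* —
every entry of $A$ iid $\mathcal N(0,\, 0.01/N)$ — and *block* — two
$N/2$ diagonal blocks iid $\mathcal N(0,\, 0.02/N)$ with exactly zero
off-diagonal blocks. $\Sigma(E)$ is Wishart with scale $\sigma I$
($\sigma \in \{0.01, 0.1\}$) and $2N$ degrees of freedom, i.e. mean
$2N\sigma I$; the Wishart "covariance" parameter is read as the scale
matrix in the standard $W(V, \nu)$ convention. Draws of $A$ that are
non-stationary are resampled (at these variances this essentially never
happens; a cap guards against misuse). Every trial is seeded from the
master seed, so a full benchmark table is a pure function of one
integer.

`run_accuracy_benchmark()` scores Queyranne's partition against the
exhaustive MIP with four metrics: **CR** (exact match with any minimizer
within $10^{-9}$ in Φ — ties are all counted correct), **RA** (rank of
the found partition's Φ among all partitions), **ER**
$= (\Phi_Q-\Phi_{MIP})/(\bar\Phi-\Phi_{MIP})$ with $\bar\Phi$ the mean
over all $2^{N-1}-1$ canonical partitions (0/0 defined as 0), and
**CORR**, the absolute Pearson correlation of the $\pm1$ sign vectors
(complement-invariant). A correct hit forces RA $= 1$, ER $= 0$,
CORR $= 1$, and the tests assert these implications per trial.

`run_comparison_benchmark()` compares Queyranne against REMCMC where
exhaustive search is impossible, scoring trials "even" when the two Φ
values agree within $10^{-9}$ (partition identity is recorded
separately), and aggregating evaluation counts plus REMCMC's
retrospective solution-found statistics.

**Problem sizes.** The shipped defaults match the full benchmark ensembles
($N = 14$, 100 trials for accuracy; $N = 20$–50 for comparisons). The
test suite and the acceptance script run reduced presets chosen so a
full run completes in minutes on one core while keeping the statistics
meaningful: Φ_SI accuracy at $N=14$ with 15–100 trials per setting,
Φ_G accuracy at $N=10$ with 30 trials (enough to distinguish a
near-perfect correct rate from a broken search, while tolerating the few
expected block-model misses), and 3–5 comparison trials at $N=20$.
Full-scale runs are a flag away (`--trials`, `--N`).

**What the generator does and does not emulate.** It produces linear,
stationary, Gaussian networks with known ground truth — exactly the
regime in which the Φ formulas are exact and exhaustive search is
meaningful. It does not emulate nonstationarity, non-Gaussian noise,
measurement artifacts, volume conduction, or the re-referencing
pipelines of real electrophysiology. Passing benchmarks therefore
demonstrate the correctness of the measures and searchers and the
accuracy of the heuristics *within the model family*; for real
recordings the recommended practice is to validate the heuristic
against exhaustive search on small random channel
subsets before trusting it at full array size, via
`estimate_joint_gaussian()` plus `run_accuracy_benchmark()`-style
checks.

## Degenerate inputs and edge cases

* Empty and full subsets describe the unpartitioned system; the oracle
  returns 0 for them (and counts the request) — this is also what makes
  the final key of each ordering well-defined.
* Non-PD inputs fail loudly with the offending block named; the
  estimator's jitter path is the only silent-ish repair, and it warns.
* A fully degenerate system ($A = 0$, white noise) scores 0 on every
  partition; the tie rules still give a deterministic search result.
* At $N \le 2$ there is a single bipartition; all searchers return it.

## Known limitations

* Only bipartitions ($K = 2$). The pendant-pair machinery extends to
  $K$-partitions in principle but at $O(N^{3(K-1)})$ cost, and
  comparing partitions across different $K$ raises normalization
  questions this package deliberately avoids (normalized Φ breaks the
  submodularity that justifies the search in the first place).
* No search for the informational "complex" (the Φ-maximizing
  subsystem); the oracle/searcher separation is the right substrate for
  it, but it is a different optimization problem.
* $\Phi_G$ is the expensive measure: each evaluation is an iterative
  solve, so Queyranne at $N = 64$ is practical for Φ_MI/Φ_SI but slow
  for Φ_G.
* No approximation guarantee exists for Queyranne on the non-submodular
  measures; the benchmarks quantify accuracy empirically, which is the
  honest statement of what is known.
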