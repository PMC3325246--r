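---
title: "Stability of random threshold gene networks: model, estimators, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability of random threshold gene networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtnstab)
```

## The model

`rtnstab` studies the Wagner-type gene network model, a random threshold
network (RTN). A network of N genes is an N x N signed interaction matrix
W; `w[i, j]` is the effect of gene j's product on gene i, zero entries mean
no regulation, and diagonal entries are self-regulation. The expression
state x(t) evolves by the synchronous deterministic map

    x(t + 1) = sigma(W x(t)),

where sigma is applied componentwise to the net input h_i = sum_j w_ij x_j.
The transient from an initial state to the attractor is read as a
developmental process and the attractor as the phenotype. Because the
discrete state space is finite and the dynamics deterministic, every
trajectory ends in a fixed point (period 1) or a limit cycle (period >= 2).

The central statistic is **stability**

    S = F / Omega,

the fraction of Omega independent (matrix, initial state) pairs whose
attractor is a fixed point; 1 - S estimates the probability of cycling.
Fixed points are what evolutionary studies of this model treat as
developmentally stable phenotypes, so S measures how often a *random*
network would even be eligible for such studies.

## Parameters that matter

* **N** (`n_genes`) — network size. S decreases with N; dense networks at
  N = 16 are already below 50% stable by a wide margin.
* **K / c** (`k`, `density`) — inputs per gene, or the fraction c = K/N of
  nonzero entries. Sparse networks are markedly more stable than dense ones.
* **Topology** — `regular` (every gene exactly K inputs; the literature's
  default and ours), `poisson` (Poisson in-degrees, mean K), and
  `bio_exp_in_pow_out` (exponential in-degrees, power-law out-degrees, both
  mean K — the pattern reported for transcriptional networks). Topology has
  only a mild effect on S.
* **State map** — `pm1` encodes off as -1, `zero_one` as 0. The maps are
  *not* equivalent: the 0/1 map is systematically more stable, and at K = 1
  it is the one regime where fixed points beat cycles (S > 1/2).
* **Weights** — `binary_pm1` (+/-1 equiprobable) or `real_gaussian`
  (standard normal). Stability is insensitive to this choice.
* **Normalization** — `step` (sign/Heaviside; discrete states) or `sigmoid`
  with steepness `a`. As a grows the sigmoid approaches the step function
  and the stability profiles converge; at small a the continuous system
  contracts toward interior fixed points and behaves differently.
* **sigma(0)** (`zero_convention`) — with binary weights and even K the net
  input can be exactly zero. Conventions: `minus` (off; the default),
  `plus`, `keep_previous`, and `quenched_random`, which draws one tie-break
  sign per gene at matrix creation. A per-evaluation random tie-break is
  deliberately not offered: it would make the update stochastic and void
  exact attractor detection. The choice shifts S only mildly.

## Attractor detection

Discrete case: every visited state is hashed; the first revisit at time t of
a state first seen at t0 gives transient t0 and period t - t0, exactly.
Full-state hashing (memory O(t)) is used rather than Floyd/Brent pointer
tricks because both the transient and the period are wanted for every run.
The iteration cap defaults to `min(2^N + 1, max(1e4, 100 N))`: the 2^N + 1
bound means small networks always resolve exactly, while large or dense
networks are censored at a policy cap. Censored runs are reported as
`unresolved` and counted as non-fixed-point in S by default — conservative
for the claim that cycles dominate — with the unresolved fraction always
reported; a strict mode (`unresolved = "drop"`) removes them from Omega.

Continuous case: there is no finite state space, so a fixed point is
declared when the max-norm step change stays below `eps = 1e-6` for
`window = 10` consecutive steps, and a cycle when a checkpoint state (stored
at power-of-two times, Brent-style, to bound memory) recurs within `eps`
after a non-quiescent step. The reported continuous periods and transients
are therefore tolerance-limited, which is why period-distribution analyses
are restricted to discrete dynamics.

A numerical note: the pm1 sigmoid is evaluated as `tanh(a h / 2)`, which is
algebraically identical to `2 / (1 + exp(-a h)) - 1` but does not round tiny
net inputs to exactly zero in floating point; with the literal form, a
decaying trajectory's sign information is destroyed after a few dozen steps
and the steep-sigmoid/sign equivalence would fail spuriously.

## What the generator emulates — and what it does not

The generator *is* the study's data source: all inputs are simulated, and
its defaults are the study conditions. Regular matrices draw K input
positions per row uniformly; Poisson in-degrees are truncated to the
feasible range by redrawing; the biological topology draws in-degrees from a
discretized exponential (mean solved by root-finding) and assigns each
gene's inputs with probability proportional to per-gene power-law
propensities whose truncated mean is solved to K — in-degrees come out
exact, out-degrees heavy-tailed with the same mean, and no stub-matching
retry loop can fail. The power-law exponent is bisected in (1.5, 4),
widening to (1.01, 50) only when K lies outside that bracket's range and
clamping at the steep end so minimal cases (N = 2, K = 1) stay well-formed.
The truncated exponential's mean cannot exceed N/2, so the biological
topology refuses denser requests.

These are parametric stand-ins: real regulatory networks have correlated
in/out degrees, motif structure, and signed-edge biases that none of the
three topologies reproduce. Passing tests show the *model's* ensemble
behaviour, not that any particular organism's network is stable.

Initial states are uniform over the 2^N discrete states, and continuous
runs also start from these discrete corners, matching how the discrete and
continuous variants are compared.

## Estimators

`estimate_stability()` samples fresh (matrix, state) pairs — one state per
matrix, with replacement across trials — and reports S with a binomial Wald
standard error (`stability_ci(..., method = "exact")` gives Clopper-Pearson
intervals near the boundaries). Per-matrix stability over many initial
states is a separate mode (`matrix_stability`,
`matrix_stability_distribution`): its distribution is strongly bimodal —
matrices are mostly *never* or *always* stable — which is why pair sampling
suffices to characterise an ensemble. Sampled histograms default to 20 bins
of width 0.05 with the exact-0 and exact-1 classes tallied separately;
exact enumerations use one bin per achievable fraction.

`exact_stability()` enumerates every binary regular matrix and every state
(guarded by size bounds that refuse with the computed count), giving S with
zero standard error, and is the oracle against which the Monte Carlo path is
tested. An independent functional-graph census (in-degree peeling over the
full 2^N transition graph) is kept in the test suite as a second, separate
route to the same quantities.

On the pm1 map with weights that never produce a zero net input, negating a
state negates its whole trajectory, so attractors pair up under x -> -x and
even-length cycles are overrepresented — at least 2-fold relative to the
neighbouring odd lengths. `even_odd_ratios()` operationalises this as
f(L)/f(L+1) for L = 2, 4, 6, and `fit_decay()` fits exponential and
power-law decay to the cycle-length distribution (period 1 excluded; even
and odd branches fitted separately on the pm1 map, since the even branch
sits on a higher curve).

`discovery_curve()` treats each distinct fixed-point state, pooled over the
sampled ensemble, as a phenotype, and records the sample index of each new
discovery; hitting the sampling budget before the target is a reported
censoring, not an error.

## Problem sizes and reproducibility

Monte Carlo defaults are desk-scale: 1e4 trials per sweep point (about 0.5%
standard error at S near 0.1) and 1e5 for period distributions; exact
enumeration is used up to N = 3 with K = N (4,096 pairs) and the oracle
census up to N = 4. Published variants of this model run to genome-sized
networks with millions of samples; the package reproduces the qualitative
ordering and the small-N exact values, not the large-N tails. Every
estimator takes a seed; sweeps derive one sub-seed per grid point from the
master seed so grid points are independent and the whole table reproduces
bit for bit.

## A worked sweep

```{r sweep, eval = FALSE}
tab <- sweep_stability("N", c(4, 8, 16), ensemble_spec(4, density = 1),
                       dynamics_spec("pm1"), n_trials = 1e4, seed = 1)
tab[, c("value", "s", "se")]
# monotone decay of S with N; all three points well below 1/2 by N = 16
```

## Known limitations

* Continuous-case attractor calls depend on `eps`/`window`; a cycle with
  amplitude below `eps` is indistinguishable from a fixed point.
* Unresolved runs at the `t_max` cap bias S downward (by design; strict
  mode quantifies the gap). At the default caps the unresolved fraction is
  zero for all shipped problem sizes.
* The biological topology is a parametric stand-in, not an empirically
  measured network.
* Asynchronous updates, gene-specific thresholds, noise in the dynamics,
  and evolutionary simulation on top of the developmental map are out of
  scope.
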