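---
title: "Stability landscapes for Ising symptom networks: model, metrics, and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability landscapes for Ising symptom networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isingscape)
```

## The model

`isingscape` works with Ising networks over `N` binary nodes in the 0/1
coding standard in psychological applications (1 = symptom present). A
network is the triple `(m, W, β)`: thresholds `m_i` (intrinsic activation
tendencies), a symmetric zero-diagonal weight matrix `W` (pairwise
interactions; a positive `w_ij` favours joint activation of `i` and `j`),
and the inverse temperature `β > 0` (default 1), which scales how strongly
the energies shape the distribution. The energy of an activation vector `a`
is

$$H(a) = -\sum_{i<j} w_{ij} a_i a_j - \sum_i m_i a_i
       = -\tfrac12 a^\top W a - a^\top m,$$

and microstates follow the Boltzmann law $P(a) \propto e^{-\beta H(a)}$.
Each node's full conditional is logistic in its local field,
$P(a_i = 1 \mid a_{-i}) = \mathrm{logit}^{-1}\!\big(\beta\,(m_i +
\textstyle\sum_{j \ne i} w_{ij} a_j)\big)$, which is simultaneously the
Gibbs conditional of the joint, the estimation target of nodewise logistic
regression, and the update rule of the Glauber sampler. The test suite
verifies this three-way consistency exactly on enumerable networks.

**Sign convention.** We implement the conditional literally as written
above: larger `m_i` means a *higher* activation probability, and the
expected number of active nodes is strictly increasing in any uniform
threshold shift (a property test asserts this by enumeration). Verbal
descriptions of thresholds in the applied literature sometimes run in the
opposite direction; when in doubt, the formula governs. Empirical symptom
networks typically have negative thresholds (symptoms are mostly absent)
and positive weights.

No −1/+1 spin convention is offered: all formulas, estimates, and
interpretations assume 0/1 coding, and the two parameterizations are not
interchangeable without a reparameterization that is out of scope here.

## From microstates to the landscape

The number of active nodes `n = Σ a_i` serves as the system state
(macrostate); it matches how symptom counts are used diagnostically, at the
price of not distinguishing *which* symptoms are active. The steady-state
distribution groups the Boltzmann mass by `n`,

$$P_\mathrm{SS}(n) = \sum_{a:\,\sum a_i = n} P(a),$$

computed **analytically by full enumeration** of the `2^N` microstates —
no simulation is involved. The stability landscape is the generalized
potential

$$U(n) = -\ln P_\mathrm{SS}(n).$$

Local minima of `U` are the stable phases; lower means more stable. `U` is
defined only up to an additive constant (the normalization of `P_SS`); we
report it for the normalized distribution, and every downstream metric is a
difference of `U` values, hence gauge-invariant (tested).

Numerical choices:

* All aggregation happens in log space with log-sum-exp, so extreme
  parameters (e.g. `β`-scaled multiplier grids, clamped thresholds) cannot
  overflow or underflow into infinite potentials.
* Enumeration is refused above `N = 25` with an explicit error pointing to
  the Glauber sampler; empirical symptom networks (typically 9–20 nodes)
  are far inside the guard. The enumeration is chunked (65,536 states at a
  time), so the full state matrix is never materialized.
* Microstates are canonically ordered by reading `a` as an `N`-bit integer
  with node 1 in the least-significant bit; this fixes serialization and
  test expectations.
* Macrostates of exactly zero probability cannot occur for finite
  parameters; should a potential value ever be non-finite, minima scans
  skip it.

## Phase-stability metrics

A clinical cutoff `c` — the smallest symptom count belonging to the
disorder phase (5 of 9 for the depression-style demonstration network; 8 of
11 for pandemic-anxiety scales) — splits the landscape into a left portion
`n = 0..c−1` and a right portion `n = c..N`. Then:

* **healthy-phase stability** = `max U` over the indices strictly right of
  the *leftmost* local minimum of the left portion, minus `U` at that
  minimum; defined as 0 when that minimum sits at the portion's right edge;
* **disorder-phase stability** mirrors it: the *rightmost* local minimum of
  the right portion and the maximum strictly to its left;
* **stability difference** = healthy − disorder. Positive values mean the
  healthy phase is the more stable one.

Three conventions had to be fixed where a rule is otherwise ambiguous, and
are deliberately conservative:

1. *Within-portion maxima.* The reference maximum is scanned strictly
   inside the portion and may fall on the edge adjacent to the cutoff, but
   never crosses it. This keeps each phase's metric a function of its own
   phase region only.
2. *Plateaus.* Local minima use weak inequalities; a run of equal values
   that qualifies contributes its leftmost and rightmost indices as
   candidates. The healthy rule then takes the leftmost candidate and the
   disorder rule the rightmost, so plateaus resolve symmetrically; a flat
   portion yields stability 0.
3. *Tied maxima.* The reported reference-maximum index is the leftmost
   argmax for the healthy portion and the rightmost for the disorder
   portion (mirror symmetry); the metric value itself is unaffected by the
   tie-break.

The classical barrier height between two minima is provided for
comparability, but it is undefined on single-minimum landscapes — the
cutoff-anchored metrics are always defined, which is why they are the
package's primary summary.

## Estimation

`estimate_ising()` fits each node's logistic regression on all other nodes
(pseudo-likelihood): the intercept is `m_i`, and `w_ij` is the **average**
of the two cross-coefficients. Averaging is the standard symmetrization for
unregularized nodewise fits; the choice is recorded in the output metadata.
`β` is not identifiable from data and is fixed at 1.

* The default fit is unregularized. Perfect separation raises an error
  instructing a small ridge penalty (`ridge = 1e-4` is a reasonable
  choice); inside bootstrap loops, such replicates are instead dropped and
  counted. The penalty used is always logged in the network metadata.
* A constant column makes the intercept diverge; its threshold is clamped
  to ±10 with its weights zeroed (warning). At `β = 1`, `|m| = 10` pins the
  marginal at `logit⁻¹(10) ≈ 0.99995` while keeping all landscape values
  finite.
* The Newton/IRLS solver is implemented in C++ for the resampling
  workloads; a test verifies its coefficients against `stats::glm` to
  `1e-6`, and a saturated, probability-weighted two-node fit recovers known
  parameters to `1e-6` (the pseudo-likelihood optimum equals the truth
  there).
* Ordinal scales are binarized as presence/absence with default threshold 1
  (any endorsement counts as present); rows with missing cells are dropped
  with a logged count.

## Sampling and the synthetic-data generator

`sample_exact()` draws i.i.d. microstates from the enumerated distribution
— exact, but limited by the guard. `glauber_chain()` runs random-scan
single-site heat-bath dynamics: per sweep each node is resampled once from
its full conditional, in a fresh random order. Random scan (rather than a
fixed order) makes the sweep operator a uniform mixture over visit orders,
each of which preserves the Boltzmann distribution; a brute-force test
builds the exact one-sweep operator on small networks and verifies
stationarity to `1e-10`, and a long-chain test checks total-variation
convergence of the `n`-occupancy to the exact landscape. Burn-in defaults
to 10% of sweeps. Trajectories are bit-reproducible for a fixed seed within
a release.

`synthetic_group_data()` generates two-group fixtures: group A from a base
network, group B after a threshold shift and/or weight multiplier, with the
generating networks returned as ground truth. It emulates the first-order
ways real groups differ (global threshold/connectivity shifts) and the
exact sampling removes estimation-irrelevant noise; it does **not** emulate
item-level measurement error, missingness, ordinal response styles, or
violations of the Ising model itself, so passing tests speak to the
correctness of the procedures, not to robustness against model
misspecification.

`synthetic_mdd_network()` is a fixed, hand-constructed (not estimated)
9-node demonstration network whose landscape shows the shape typical of
estimated depression networks — a stable healthy state at `n = 0` and a
shallow high-symptom basin past the cutoff — so examples and the acceptance
script have a deterministic, self-contained input.

## Bootstrap and group comparison

`bootstrap_stability()` resamples persons with replacement, re-estimates
the network per replicate, and recomputes the stability difference. Because
the replicate distribution is typically skewed, intervals use the
bias-corrected and accelerated (BCa) method: bias correction `z₀` from the
fraction of replicates below the point estimate, acceleration from the
skewness of leave-one-person-out jackknife influence values, and endpoints
read from the replicates with normal-order-statistic interpolation. The
implementation is cross-checked in the test suite against the `boot`
package on shared replicates (with explicitly supplied influence values, so
the comparison is exact to `1e-8`). The p-value inverts the interval — the
smallest `α` on a 0.001-step grid whose `(1−α)` interval excludes the null
— and is therefore monotone consistent with the intervals by construction
(tested); its resolution floor is the grid step. Defaults: `B = 1000`,
95% intervals, both overridable.

Degenerate situations are flagged rather than hidden: a constant replicate
distribution yields SE 0, a point interval, and a flagged `NA` p-value;
replicates whose estimation fails are dropped and counted, and a result
with more than 5% failures is marked invalid.

`compare_groups()` contrasts two groups on the difference of their
stability differences, resampling **within** each group per replicate
(stratified bootstrap; the scheme is a package choice, recorded here, since
group-contrast resampling admits alternatives). Acceleration uses a pooled
leave-one-out jackknife across both groups, holding the other group at its
full-data value. Optional size equalization subsamples the larger group
without replacement before any estimation, so both networks are estimated
with equal power. The 2 × 2 parameter-swap grid (thresholds from either
group × weights from either group) attributes landscape differences to
thresholds (rows) versus connectivity (columns); its diagonal equals the
pure per-group landscapes by construction (tested).

`permutation_mean_difference()` is the accompanying location test on raw
symptom counts: after seeded equalization, group labels are permuted
(`B = 10000` by default) and the two-sided p-value is
`(1 + #{|T_perm| ≥ |T_obs|})/(B + 1)`.

All randomness in these workflows flows from a single user seed, split
deterministically into component seeds (subsampling, per-group bootstraps,
between-group bootstrap, permutations) via a seeded draw of sub-seeds, so
any artifact is reproducible from its logged seed alone.

## Problem sizes used by the test suite

The suite exercises exact oracles on networks of 3–6 nodes (where
enumeration, Poisson-binomial convolution, and brute-force sweep operators
are feasible), Monte-Carlo convergence on a 9-node network with 5·10⁵
sweeps (total-variation tolerance 0.02), parameter recovery on a 5-node
network with up to 10⁴ exact samples (mean absolute error below 0.1,
decreasing in `n`), and the size of the between-group test on 200 null
simulations with groups of 400 and `B = 200` (empirical rejection at
nominal 5% required to stay at or below 7%). The null-calibration model is
a 4-node network with moderate parameters — small enough that 200 full
bootstrap studies are routine, large enough that the statistic is not
trivially constant.

## Known limitations

* Conclusions are population-level: a landscape computed from
  cross-sectional group data describes the group's average system, not any
  individual's dynamics.
* The macrostate `n` weights all symptoms equally; networks mixing
  qualitatively different node sets dilute its meaning.
* `β` is fixed at 1 in estimation (it is confounded with the scale of
  `m, W`); it remains a free field on constructed networks.
* Exact landscapes require `N ≤ 25`; beyond that only the Glauber
  approximation is available.
* The bootstrap re-estimates networks unregularized by default; datasets
  prone to separation need an explicit ridge, and heavy failure rates are
  flagged rather than repaired.
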