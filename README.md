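# isingscape

Exact stability landscapes and phase-stability inference for Ising networks
of binary symptom data.

## The problem

Network psychometrics models mental disorders as systems of interacting
symptoms. For cross-sectional binary data (symptom present/absent) the
standard model is the Ising network: node thresholds `m_i` capture each
symptom's intrinsic activation tendency, edge weights `w_ij` the pairwise
interactions, and an inverse temperature `β` the overall randomness. The
probability of a full activation pattern `a ∈ {0,1}^N` is the Boltzmann
distribution

    P(a) ∝ exp(−β H(a)),    H(a) = −Σ_{i<j} w_ij a_i a_j − Σ_i m_i a_i,

and each node's full conditional is logistic,
`P(a_i = 1 | a_−i) = logistic(β (m_i + Σ_{j≠i} w_ij a_j))`.

An estimated network, however, does not directly say whether the *healthy*
or the *disorder* phase of the system is the more stable one. `isingscape`
answers that by computing the **stability landscape**: the number of active
symptoms `n = Σ a_i` is taken as the system state, its steady-state
distribution `P_SS(n)` is obtained **exactly** by enumerating all `2^N`
microstates and grouping the Boltzmann mass by `n` (no simulation), and the
generalized potential is

    U(n) = −ln P_SS(n).

Low values of `U` are stable states; its local minima are the system's
phases. Anchoring the landscape at a clinical symptom-count cutoff `c`
(e.g. 5 of 9 depression symptoms) gives the **phase-stability metrics**: the
healthy-phase stability is the rise of `U` to the right of the leftmost
local minimum within `n < c`, the disorder-phase stability is defined
mirror-symmetrically on `n ≥ c`, and their difference (healthy − disorder)
is the headline statistic — positive when the healthy phase is the more
stable one.

Around this core the package provides, for applied group comparisons:

* nodewise logistic-regression estimation of `(m, W)` from person × symptom
  0/1 data (with binarization of ordinal scales),
* BCa bootstrap standard errors, confidence intervals and p-values for the
  stability difference,
* two-group workflows: seeded size equalization, stratified bootstrap of the
  between-group contrast, 2 × 2 parameter-swap landscapes (thresholds from
  either group × weights from either group), and a permutation test on mean
  symptom counts,
* exact and Glauber-dynamics samplers, a synthetic two-group data generator,
  and a command-line interface.

## Worked example

```r
library(isingscape)

net <- synthetic_mdd_network()     # fixed synthetic 9-node demo network
land <- potential_landscape(net)
land
#> Stability landscape over n = 0..9 active nodes (beta = 1)
#>  n count probability potential
#>  0     1     0.17180     1.761
#>  1     9     0.15770     1.847
#>  2    36     0.11780     2.139
#>  3    84     0.09302     2.375
#>  4   126     0.08273     2.492
#>  5   126     0.08268     2.493
#>  6    84     0.08941     2.415
#>  7    36     0.09609     2.342
#>  8     9     0.08358     2.482
#>  9     1     0.02519     3.681
#> Local minima at n = 0, 7

phase_stability(land, cutoff = 5)
#> Phase stability at cutoff 5 (disorder phase: n >= 5)
#>   healthy phase:  0.7307 (minimum at n = 0)
#>   disorder phase: 0.1503 (minimum at n = 7)
#>   stability difference (healthy - disorder): 0.5805
```

The landscape has a stable healthy state at `n = 0` and a shallow
high-symptom basin at `n = 7`; the positive stability difference 0.58 says
the healthy phase is the more stable of the two. Globally weakening
thresholds and strengthening connectivity tips the system the other way:

```r
weakened <- scale_parameters(net, threshold_multiplier = 0.8,
                             connectivity_multiplier = 1.2)
stability_difference(weakened, cutoff = 5)
#> [1] -3.61077
```

Estimation and bootstrap inference from person-level data:

```r
dat <- sample_exact(net, n_samples = 800, seed = 11)   # exact i.i.d. draws
bootstrap_stability(dat, cutoff = 5, B = 500, seed = 12)
#> Bootstrap of stability_difference (B = 500, 0 failed replicate(s))
#>   estimate 0.5982, SE 0.09795
#>   95% BCa CI [0.4322, 0.8064]
#>   p = 0.001 (vs null 0, by CI inversion)
```

The estimate 0.60 recovers the generating network's 0.58 within its
bootstrap standard error; the interval excludes 0, so the data support a
more stable healthy phase.

The same pipeline is available from the shell via the installed script
(`inst/cli/isingscape`), with subcommands `landscape`, `metrics`,
`estimate`, `bootstrap`, `compare`, and `simulate`; every run can write a
JSON log of its parameters, seeds, and versions.

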