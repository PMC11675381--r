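---
title: "Dissecting noise-induced transitions with information flows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting noise-induced transitions with information flows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinflow)
```

## The model

`spinflow` analyses binary-spin dynamics on a connected, simple, undirected
graph.  Each node holds a state $s_i \in \{0, 1\}$, mapped to a physical spin
$\sigma_i = 2 s_i - 1$, and the system energy is the zero-field ferromagnetic
Ising Hamiltonian

$$E(S) = -J \sum_{(i,j) \in \mathcal{E}} \sigma_i \sigma_j, \qquad J > 0 .$$

The zero-field form is essential: it gives the dynamics a global spin-flip
symmetry, which is what produces the *pair* of symmetric attractors (all-0
and all-1) and the bistable stationary distribution that the whole analysis
revolves around.  An external field would bias one attractor and change the
tipping phenomenology qualitatively.

Time evolves by asynchronous Glauber dynamics: at each discrete step one node
is chosen uniformly at random and flipped with the Boltzmann–Gibbs
probability

$$P(s_i \to s_i') = \frac{1}{1 + e^{-\beta \, \Delta E}},$$

where $\Delta E$ is the energy *released* by the flip, so energy-lowering
flips are favoured, isolated or field-balanced nodes flip with probability
exactly $1/2$, and $\beta = 0$ reduces to a fair coin.  The probability of a
flip and of its reverse always sum to one, which is the detailed-balance
skeleton: the chain is reversible with respect to the Boltzmann distribution
$e^{-\beta E}/Z$.

Two parameters matter:

* **`beta`** (inverse temperature, dimensionless, default `0.534`): the noise
  level.  At the default the 10-node kite fixture sits in the interesting
  regime — the stationary distribution is clearly bimodal yet spontaneous
  transitions between the attractors still occur on simulable time scales.
  Much lower and the barrier disappears; much higher and transitions become
  unobservably rare.
* **`coupling`** (`J`, default `1`): only the product $\beta J$ enters the
  dynamics, so `J` is kept at 1 and `beta` carries the temperature.

## Exact machinery

For $n \le 14$ nodes the package works with the full $2^n$ state space.
Configurations are encoded little-endian (node $i$ contributes bit $i$), a
fixed convention so state-indexed outputs are comparable across runs.  The
one-step transfer operator is sparse — each row holds $n$ single-flip entries
$\tfrac1n P(\mathrm{flip})$ plus a lazy diagonal — and the stationary vector
is obtained by a direct sparse linear solve of $\pi T = \pi$ with one
equation replaced by normalisation.  A direct solve is used deliberately:
in the bistable regime the second eigenvalue of $T$ is extremely close to 1
(slow inter-attractor mixing), so power iteration stalls precisely where the
model is interesting.  The residual $\lVert \pi T - \pi \rVert_1$ is checked
against $10^{-10}$.

The macrostate $\langle S \rangle$ (fraction of nodes in state 1) is the
reaction coordinate.  Projecting $\pi$ onto it gives the free-energy profile
$F(\gamma) = -\log \sum_{\langle S \rangle = \gamma} \pi(S)$; at the default
`beta` the kite profile has minima at $\gamma \in \{0, 1\}$ and its maximum
at the tipping level $\gamma = 0.5$.

## Information-flow curves

For each magnetisation level $\gamma$ the time-0 ensemble is the stationary
distribution restricted to $\{S : \langle S \rangle = \gamma\}$ and
renormalised.  This is the natural "distance to the tipping point"
conditioning: it groups states by how many spins have flipped while
weighting states within a group by how the equilibrium dynamics actually
visits them.  From that ensemble the package evolves, for every node, the
joint law of the node's state now and the entire system state $t$ steps
later, and reports the mutual information

$$I\!\left(s_i^{\tau} : S^{\tau + t} \,\middle|\, \langle S^\tau \rangle = \gamma\right)$$

in bits for $t = 0, \dots, \tau_{\max}$ (default $\tau_{\max} = 300$).  The
curve starts at the node's conditional entropy ($\le 1$ bit) and cannot
increase with lag (data processing along the Markov chain); both properties
are enforced as tests, and for $n \le 4$ every value is checked against a
literal path-enumeration oracle.

Two summary features are extracted per curve:

* **Asymptotic information** $\omega$: the mean of the final 20% of lags
  (`tail_fraction = 0.2`), clipped at zero.  It measures the long-lived
  plateau — information about which attractor the system is heading to —
  and rises sharply as $\gamma$ approaches the tipping level, which makes it
  usable as an early-warning signal.  The window is configurable; 20% of a
  300-lag horizon averages 60 values, long enough to suppress estimator
  noise and late enough that the fast transient has died out on the graph
  sizes the exact machinery handles.  Note that $\omega$ is a finite-horizon
  quantity: on any finite ergodic chain the true $t \to \infty$ limit is
  zero, and the plateau reflects time-scale separation within the horizon.
* **Integrated mutual information** $\mu = \sum_{t=0}^{\tau_{\max}} (I(t) -
  \omega)\,\Delta t$ with $\Delta t = 1$: the area between the curve and its
  plateau, i.e. the intensity-times-duration of the node's short-lived
  contribution.

Two conventions for the $\omega$ subtracted inside $\mu$ are implemented.
The default (`omega_mode = "per-level"`) subtracts each level's own plateau,
making $\mu$ the transient area at that level.  The alternative
(`"shared"`) subtracts a single per-node $\omega$ — the largest plateau
across levels — everywhere.  The per-level form is the default because the
shared form makes $\mu$ strongly negative at low $\gamma$ for exactly the
nodes with large tipping-point plateaus, which inverts the diagnostic
low-degree/high-$\mu$ signature far from the tipping point; with the
per-level form the Spearman correlation between degree and $\mu$ at
$\gamma \in \{0.1, 0.2\}$ on the kite is about $-0.98$.

## Node roles

The role statistic contrasts the two features after max-normalisation over
nodes:

$$r_i \;=\; \max_{\gamma < 0.5} \mu^*(s_i \mid \gamma)
       \;-\; \max_{\gamma < 0.5} \omega^*(s_i \mid \gamma) \;\in\; [-1, 1].$$

Nodes with $r_i > 0$ are **initiators** — they inject and propagate
short-lived fluctuations that destabilise their neighbours, typically
low-degree nodes whose flips are cheap — and nodes with $r_i < 0$ are
**stabilizers**, which carry the long-term memory of the attractor choice,
typically hubs.  The maxima deliberately exclude the tipping level itself:
at $\gamma = 0.5$ the system is choosing its attractor, every node's curve
decays slowly, and the integrated term grows so large for all nodes that the
contrast collapses.  Restricted to the approach ($\gamma < 0.5$; the levels
above are mirror images by spin-flip symmetry), the kite's hub (node 3,
degree 6) is the strongest stabilizer — consistent with the direct
intervention measurement below — and low-degree tail-side nodes top the
initiator ranking.

Normalisation divides each measure by its maximum over nodes and levels, so
both starred quantities live in $[0, 1]$ and at least one node attains 1 in
each; the label threshold sits at $r = 0$ and the continuous score is always
reported alongside.

## Tipping-point trajectories

The path module enumerates *every* state sequence of a given length from a
chosen start (typically the all-zero attractor) that ends at a target
magnetisation level, one flip per step, and scores each by its summed log
one-step transition probability taken directly from the transfer operator.
On the kite, five steps to the tipping level force five distinct 0-to-1
flips, so the count is the pure permutation number
$10 \cdot 9 \cdot 8 \cdot 7 \cdot 6 = 30{,}240$, independent of `beta`.
Maximisers are extracted with an absolute tie tolerance of $10^{-9}$ log
units — ties among symmetric flip orders are exact up to round-off, and the
gap to the next objective value is of order $0.2$, so the tolerance is
uncritical over many orders of magnitude.  The maximal trajectories all
start the cascade in the kite's tail (nodes 9, 8, 7 flip early) and recruit
progressively better-connected nodes — the domino effect in its cleanest
form.  The tie class is closed under the kite's mirror automorphism, which
is asserted as a test.

Since step probabilities depend only on the energy released, the tie class
is exactly the set of flip orderings sharing the optimal released-energy
multiset; on the kite this class has 12 members, which is what both the
enumeration and an independent re-derivation produce.

At the tipping point itself the package computes commitment probabilities:
condition the tipping-level ensemble on a node's state, evolve ten steps
(configurable), and ask on which side of $0.5$ the macrostate lands.  On
the kite, the hub's state *agrees* with the future macrostate sign
(probability $\approx 0.58$) while node 8's state *disagrees*
(agreement $\approx 0.26$): the most likely approach paths flip the tail
first, so a tail-side node in state 1 at the tipping point signals a
failed upward excursion more often than a successful one.

## Pinning interventions

The Monte Carlo module complements the exact machinery with a compiled
asynchronous Glauber sampler (one node-update attempt per step, macrostate
recorded per sweep, bit-reproducible for a fixed seed).  A pinning
intervention freezes one node at state 0 and removes it from the update
pool; its neighbours still feel the frozen state.  This is the standard
causal clamp: any change in the system's behaviour is attributable to the
suppressed degree of freedom.

Three metrics summarise a run against its matched-seed control: the second
central moment of the macrostate trace (fluctuation size), the fraction of
time spent below the tipping level, and the number of *successful*
metastable transitions — crossings that actually reach the strictly
opposite side, so grazes at exactly $0.5$ never count (hysteresis rule).
Ratios are normalised per graph by that graph's own control.

The ensemble experiment draws connected Erdős–Rényi graphs
($n = 10$, $p = 0.2$, 100 graphs, 6 seeds per arm, $2 \times 10^5$ attempts
per run), computes each graph's roles with the exact pipeline, and pins the
top initiator and the top stabilizer.  Across the ensemble,
initiator-pinning yields more successful transitions than stabilizer-pinning
(one-sided sign test across graphs); the acceptance suite runs exactly this
experiment.  The ensemble size of 100 graphs is chosen for the sign test's
power: the per-graph effect is directional but noisy at 6 seeds, and a
20-graph ensemble leaves the test under-powered.

## Synthetic conditions versus real data

Everything the package is tested on is generated by its own fixtures: the
deterministic kite and seeded $G(n, p)$ samples.  These emulate small
networked systems with homogeneous pairwise couplings, symmetric binary
dynamics, and no external drive.  Real systems violate most of these
assumptions — heterogeneous and possibly signed couplings, external fields
breaking the attractor symmetry, non-equilibrium updates, unobserved nodes
— so passing tests demonstrate correctness of the computations under the
model, not validity of the model for any particular dataset.  The
information-theoretic summaries ($\mu$, $\omega$, $r_i$) are, however,
defined on distributions over trajectories and could in principle be
estimated from observational time series without access to the generative
mechanism.

## Numerical choices and degenerate inputs

* State-space cap at $n \le 14$ ($2^{14}$ states); beyond it the
  constructor refuses and points at the Monte Carlo sampler.
* Degenerate conditioning levels ($\gamma = 0$ or $1$: the node state is
  constant) return exact-zero MI curves rather than erroring, so level sweeps
  need no special-casing.
* All-zero information across nodes (e.g. `beta = 0` exactly) makes the
  role normalisation degenerate; this raises an error rather than returning
  arbitrary scores.
* The Monte Carlo consistency check between the sampler and the exact
  stationary distribution uses $4 \times 10^6$ attempts: the error is
  dominated by the imbalance of time spent in the two attractor basins,
  which only falls below 2% total variation after a few thousand basin
  switches (roughly 600 occur per $10^6$ attempts at the reference
  parameters).
* Trajectory-set ties are compared in log space with absolute tolerance
  $10^{-9}$; maximiser output is sorted lexicographically by state indices
  so results are deterministic.

## Problem sizes

The default analyses run on $n = 10$ graphs (1024 states): the full kite
flow analysis ($10$ nodes $\times$ 6 levels $\times$ 300 lags) takes a few
seconds, the 30,240-trajectory enumeration about two, and the 100-graph
intervention ensemble about five minutes, dominated by the per-graph exact
role computation.

## Known limitations

* Exact computation is exponential in $n$; the package is a microscope for
  small systems, not a large-network tool.  Monte Carlo estimation of the
  MI curves themselves is not implemented.
* $\omega$ estimation is a windowed tail mean; no spectral or
  multi-exponential fit is attempted.
* Only state-0 pinning is provided as an intervention; edge removals and
  field biases are out of scope.
* Conditioning on a partition can in principle create synergistic
  information among nodes; the package reports per-node measures only and
  makes no synergy/redundancy decomposition.
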