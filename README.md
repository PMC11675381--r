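# spinflow

Information-theoretic dissection of noise-induced transitions in networked
spin systems.

Small networks of bistable units — neurons, opinions, ferromagnetic spins —
can jump between collective attractor states with no external forcing at
all: noise alone, filtered through the network structure, carries the system
over the free-energy barrier.  `spinflow` is a microscope for this process.
For a connected graph with binary node states $s_i \in \{0,1\}$, zero-field
Ising energy $E(S) = -J\sum_{(i,j)}\sigma_i\sigma_j$
($\sigma_i = 2s_i - 1$) and asynchronous Glauber dynamics

$$P(s_i \to s_i') = \frac{1}{1 + e^{-\beta\,\Delta E}},$$

it builds the exact $2^n \times 2^n$ transfer operator, conditions on the
distance to the tipping point $\langle S \rangle = 0.5$, and computes for
every node the mutual-information flow curve
$I(s_i^\tau : S^{\tau+t} \mid \langle S^\tau \rangle = \gamma)$, its
integrated short-term part

$$\mu(s_i \mid \langle S \rangle) = \sum_{t=0}^{\tau_{\max}}
\bigl(I(t) - \omega(s_i)\bigr)\,\Delta t,$$

and its long-term plateau $\omega$ (asymptotic information).  The role
statistic
$r_i = \max_\gamma \mu^*(s_i\mid\gamma) - \max_\gamma \omega^*(s_i\mid\gamma)
\in [-1,1]$ separates **initiators** (short-lived fluctuation injectors,
typically low degree) from **stabilizers** (long-term memory carriers,
typically hubs).  The package also enumerates and scores all tipping-point
trajectories, computes attractor-commitment probabilities, and validates
roles causally with a compiled Monte Carlo simulator that pins nodes to a
fixed state.

Intended users: researchers studying metastability, early-warning signals
and controllability on small networks, who need exact (not sampled)
information flows.

## Worked example

The built-in fixture is the 10-node, 18-edge Krackhardt kite (hub node 3 has
degree 6, node 8 degree 2, tail node 9 degree 1) at the bistable reference
noise level $\beta = 0.534$:

```r
library(spinflow)
sys <- spin_system(make_kite(), beta = 0.534)
op  <- build_transfer_operator(sys)
pi  <- stationary_distribution(op)
free_energy_profile(pi, op$space)
#>    gamma free_energy
#> 1    0.0    1.549886
#> 2    0.1    2.023467
#> ...
#> 6    0.5    5.114533
#> ...
#> 11   1.0    1.549886
```

The profile is bistable: minima at the two uniform attractors
($\gamma \in \{0,1\}$), barrier top at the tipping level $\gamma = 0.5$.
The information-flow analysis then assigns roles:

```r
flows <- info_flow(sys, tau_max = 300)
node_roles(flows)
#>    node degree mu_star_max omega_star  role_score role_label
#> 1     0      4       0.619      0.221      0.3987  initiator
#> 3     2      3       0.598      0.045      0.5533  initiator
#> 4     3      6       0.726      0.819     -0.0925 stabilizer
#> 9     8      2       1.000      1.000      0.0000    neutral
#> 10    9      1       0.875      0.922     -0.0467 stabilizer
```

The hub (node 3) is the strongest stabilizer; low-degree nodes near the tail
top the initiator ranking.  Far from the tipping point, integrated mutual
information anti-correlates with degree (Spearman $\approx -0.98$ at
$\gamma = 0.1$): noise enters through the tail.

Path analysis makes the cascade explicit:

```r
trajs <- enumerate_tipping_trajectories(op, rep(0, 10), length = 5,
                                        target_gamma = 0.5)
nrow(trajs$states)        # 30240 trajectories reach the tipping level
best <- maximal_trajectories(trajs)
nrow(best$states)         # 12 tie exactly at the maximum
best$objective[1]         # -19.54014 summed log probability
```

Every maximal trajectory starts the domino in the tail (9, 8, 7 flip early).
At the tipping point the hub's state predicts the outcome while a tail-side
node anti-predicts it:

```r
commitment_probabilities(op, 3, horizon = 10)$p_agree[2]  # 0.584
commitment_probabilities(op, 8, horizon = 10)$p_agree[2]  # 0.260
```

Finally, causal pinning confirms the roles — freezing the hub at 0 suppresses
transitions, freezing node 8 promotes them:

```r
rep <- intervention_experiment(sys, pin_nodes = c(3, 8), steps = 2e5, seeds = 1:6)
rep$summary[, c("arm", "n_transitions")]
#>      arm n_transitions
#>  control         117.3
#>    node3          98.0
#>    node8         125.8
```

and the same contrast holds across a 100-graph Erdős–Rényi ensemble
(`er_intervention_ensemble()`: initiator-pinning beats stabilizer-pinning in
71/100 graphs, sign test $p \approx 2\times 10^{-5}$).

A command-line front end wrapping the full pipeline lives at
`inst/cli/spinflow.R` (subcommands `flows`, `roles`, `paths`, `intervene`,
`all`; YAML/JSON config with flag overrides).

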