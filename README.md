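# seizurenet

Seizure propagation on structural brain networks with coupled Epileptor
models.

`seizurenet` is for computational neuroscientists who want to ask, on a
weighted directed connectome: *if a seizure starts in this region, does it
stay focal or generalize — and which minimal structural intervention
confines it?* The package simulates a network of Epileptor neural-mass
models on a structural connectivity matrix, detects per-region seizure
onset from the slow permittivity variable, classifies propagation as
localized or widespread, relates the outcome to graph measures of the
epileptogenic zone (EZ), and evaluates two in-silico interventions:
targeted edge removal (virtual resection) and EZ outgoing-weight reduction
(suppression of local hyperexcitability).

## The model

Each region *i* follows the six-variable Epileptor

```
x1' = y1 - f1(x1, x2, z) - z + I1
y1' = 1 - 5 x1^2 - y1
z'  = r (4 (x1 - x0) - z - 0.1 z^7 [z < 0]) + r K Σ_j w_ji (x1_i - x1_j)
x2' = -y2 + x2 - x2^3 + I2 + 0.002 g - 0.3 (z - 3.5)   (+ noise)
y2' = (1/τ) (-y2 + f2(x2))                              (+ noise)
g'  = -0.01 (g - 0.1 x1)
```

with `I1 = 3.1`, `I2 = 0.45`, `r = 8e-5`, `K = 0.2`, `τ = 10`, additive
Gaussian noise (`σ = 0.0025`) on the `x2`/`y2` updates, and `w_ji` the
weight of the structural connection from region *i* to region *j*. The
per-node excitability `x0` separates spontaneously seizing regions
(EZ, `x0 = -1.6`) from healthy ones (PZ, `x0 = -2.1`) across the critical
value near −2.06. The LFP proxy is `x2 - x1`; seizure onset is the time at
which `z` starts increasing. Integration is a compiled stochastic Heun
scheme; all runs are seed-reproducible.

Graph measures follow the weighted conventions: out/in-degree, eigenvector
centrality (outgoing-influence direction by default), strongest outgoing
weight, and average shortest path on the inverted-weight complete graph
(`l = c_m - c`, Dijkstra).

## Worked example

Simulate a seizure starting in the CA1-like focus node of a synthetic
98-region mirrored connectome, classify its propagation, and confine it by
removing a single edge:

```r
library(seizurenet)

C  <- make_synthetic_connectome(synthetic_spec(seed = 1))
ez <- C$focus_nodes$left_focus[1]          # l CA1-like node (index 73)
p  <- epileptor_params(duration = 6000, seed = 101)
p$x0 <- rep(-2.1, n_nodes(C)); p$x0[ez] <- -1.6

traj <- simulate_epileptor(C, p)
onset_table(traj, ez_nodes = ez)
#> <onset_table> EZ = {73}; 97/97 non-EZ nodes recruited (100.0%): widespread

# remove the EZ's strongest outgoing edge (its only super-threshold pathway)
target <- which.max(C$weights[, ez])
evaluate_interventions(C, ez,
  list(intervention_spec("remove_edges", edges = c(ez, target))), p)
#>        case recruited_count recruited_fraction propagation_class ez_max_out_weight failed
#> 1  baseline              97               1.00        widespread              0.72  FALSE
#> 2  73-x->74               0               0.00         localized              0.40  FALSE
```

The baseline seizure recruits all 97 other regions (widespread); removing
the one outgoing edge whose weight exceeds the model's propagation
threshold leaves the seizure confined to the EZ (localized). A gentler
intervention scans outgoing-weight reduction levels:

```r
rs <- reduction_scan(C, ez, levels = seq(0, 0.5, 0.1), p)
rs[, c("level", "recruited_fraction", "propagation_class")]
#>   level recruited_fraction propagation_class
#> 1   0.0         1.00000000        widespread
#> 2   0.1         1.00000000        widespread
#> 3   0.2         0.01030928         localized
#> 4   0.3         0.00000000         localized
#> 5   0.4         0.00000000         localized
#> 6   0.5         0.00000000         localized
attr(rs, "minimal_confining_level")
#> [1] 0.2
```

Reducing the EZ's outgoing weights by 20% is already enough to keep this
seizure focal while preserving the connectome's total connective strength.
`ez_sweep()` runs such simulations for every candidate EZ across a
surrogate ensemble and `estimate_weight_thresholds()` extracts the
strongest-outgoing-weight band separating the localized from the
widespread regime.

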