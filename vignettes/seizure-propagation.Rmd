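---
title: "Seizure propagation on structural brain networks: model, detection and interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seizure propagation on structural brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(seizurenet)
```

## The model

`seizurenet` simulates epileptic seizure propagation on a weighted, directed
structural connectome by coupling one six-variable Epileptor neural-mass
model per brain region. Each node carries a fast discharging subsystem
(`x1`, `y1`), a sharp-wave subsystem (`x2`, `y2`), a low-pass filter `g`,
and a slow "permittivity" variable `z` that gates seizure onset and offset.
The local field potential of region *i* is proxied by `x2_i - x1_i`.

A node's excitability is set by a single parameter `x0`. Below the critical
value (about −2.06, exported as `CRITICAL_X0` and recomputable with
`find_critical_x0()`) the node rests at a stable interictal fixed point;
above it the fixed point collides with the knee of the fast-subsystem
nullcline and the node seizes spontaneously, with `z` rising through the
ictal phase and falling back after offset. The epileptogenic zone (EZ) is
modelled with `x0 = -1.6`, the healthy propagation zone (PZ) with
`x0 = -2.1`.

Nodes interact through a diffusive coupling on the fast variable: node *i*
receives `K * sum_j w(j->i) * (x1_i - x1_j)` in its slow equation, where
`w(j->i)` is the structural weight of the connection from *j* to *i* and
`K = 0.2` is the global gain. Weights are stored with rows as targets and
columns as sources (`weights[j, i]` is the connection from node *i* to node
*j*); this single orientation is used consistently by every module.

### Where the coupling acts, and why it matters

The package scales the coupling term by the slow rate `r` (it enters the
`z` equation inside the `r(...)` factor, the placement of the original
network-Epileptor formulation). This choice is load-bearing. Written this
way, a sustained input from seizing neighbours shifts a node's *effective*
epileptogenicity by `(K/4) * sum_j w_ji * (x1_j - x1_i)`: recruitment is a
threshold phenomenon in the incoming weight from currently ictal sources,
which is exactly what produces the empirical dichotomy between localized
and widespread seizures. If the coupling is instead added at the fast
timescale (outside `r`; available as `coupling_in_slow = FALSE`), it
overwhelms the slow dynamics by a factor `1/r = 12500` and any edge weight
above roughly `1e-6` recruits its target — every seizure becomes
widespread and no weight-threshold regime can exist. The slow-scaled
placement is therefore the default and is used in all shipped experiments.

With the default constants, the measured single-edge recruitment threshold
is approximately 0.47 on the max-normalized weight scale (an isolated pair
probed over a 6000-unit horizon classifies 0.46 as non-recruiting and 0.48
as recruiting, insensitive to halving `dt`). In a full network the EZ's
seizure bursts are shortened by the diffusive input it receives from its
quiet neighbours, so marginally super-threshold drives may fail to recruit
within a burst; drives comfortably above the threshold recruit within a few
hundred time units.

## Time, integration and noise

Time is dimensionless "model time": the slow rate `r = 8e-5` per unit makes
a full seizure cycle span roughly 4000 units, and all horizons are stated
in these units (durations are configurable everywhere). Integration uses a
stochastic Heun predictor–corrector scheme (compiled, `dt = 0.05` by
default) with additive Gaussian noise of standard deviation
`sigma * sqrt(dt)` per step applied to the `x2` and `y2` updates only
(`sigma = 0.0025` by default); `sigma = 0` gives bit-reproducible runs.
Because neither `z` nor the pre-ictal `x1` branch feels `x2`, the noise
does not perturb onset timing, which keeps the propagation regime sharp.

All nodes start at the interictal fixed point evaluated at the PZ
excitability (computed by root-finding in `interictal_state()`), perturbed
by a seeded uniform jitter of half-width `1e-3`. A non-finite state aborts
the run with the blow-up time rather than returning NaNs.

## Onset detection and classification

Seizure onset is "the time when `z` starts increasing", operationalized in
`detect_onsets()` as a baseline-plus-threshold crossing: the baseline mean
and standard deviation are taken over the 10 units preceding the 15-unit
warmup, and the onset is the first post-warmup time at which the smoothed
`z` exceeds `mean + max(0.05, 5 * sd)` and keeps non-decreasing for one
time unit (centered moving average over 11 samples). The absolute floor of
0.05 dominates in practice since the pre-ictal `z` is noise-free; the
crossing therefore lags the true `z` minimum by the time `z` needs to climb
0.05, which is a consistent per-run offset and leaves recruitment ordering
and flags unaffected. All knobs are arguments.

`time_distances()` implements the EZ-referenced propagation delay: 0 at the
EZ, `T_onset,i - T_onset,EZ` for recruited nodes, `NA` for non-recruited
nodes. With a multi-node EZ the reference is the earliest EZ onset (the
shipped experiments only use single-node EZs). A run is classified
`localized` when at most 2 non-EZ regions are recruited, `widespread` when
at least half are, and `partial` otherwise; the partial class is retained
as a safety valve but does not occur in the shipped experiment conditions.

## Graph measures

`node_measures()` characterizes every node by weighted out- and in-degree,
eigenvector centrality, inverted-weight average shortest path length, and
the strongest outgoing weight, each also max-normalized. Two directionality
conventions were genuinely open:

* **Centrality direction.** The regime analysis keys on *outgoing*
  connectivity of the EZ, so the default centrality aggregates the
  centralities of the nodes a node projects *to* (power iteration on the
  transposed stored matrix); `direction = "in"` gives the other convention.
* **Path direction.** The per-node summary averages shortest paths *from*
  the node (source perspective), consistent with the outgoing-influence
  framing, and divides by `N` with the zero self-distance included.

Edge lengths are `l = c_m - c` with `c_m` the single global maximum weight,
and every ordered pair is an edge (absent connections get length `c_m`), so
the graph is complete and Dijkstra distances (via igraph) are always
defined.

## Interventions

`remove_edges()` zeroes the listed directed entries and renormalizes the
whole matrix so the global maximum is 1 again. Renormalizing "to one" could
also be read as preserving the total sum; both are implemented
(`removal_norm = "max"|"sum"|"none"`) with max-normalization as the
default, matching the convention that connectomes are stored with maximum
weight 1. `reduce_outgoing()` multiplies a node's outgoing weights by
`1 - p` and rescales the whole matrix to preserve the grand total of
connective strength exactly (relative error below 1e-12 is enforced and
tested). Both are pure functions preserving shape, nonnegativity, the zero
diagonal and the zero pattern.

## The synthetic connectome generator

No redistributable copy of the 98-region Allen mouse matrix ships with the
package, so `make_synthetic_connectome()` builds surrogates with the
structural features the analysis depends on:

* two mirrored hemispheres (`L-L = R-R`, `R-L = L-R` exactly, via
  `mirror_right_hemisphere()`), 49 nodes each by default;
* heavy-tailed nonnegative background weights (log-normal, `sdlog = 0.6`,
  density 0.35, cross-hemisphere edges at half weight) with the
  global background maximum normalized to 1. These values were chosen once
  so that total in-strengths land around 4–6, dense enough that a recruited
  core can tip the rest of the network collectively — the qualitative
  behaviour a dense mammalian connectome shows;
* a three-node focus subnetwork per hemisphere in the CA1/CA3/DG roles,
  placed so the left triplet occupies nodes 73–75 in the default layout:
  strong intra-focus and cross-hemisphere focus edges, gateway edges from
  the CA1- and DG-like nodes into the background (entorhinal/subicular
  analogues), and only weak extra-focus output from the CA3-like node.
  Each focus node's realized strongest outgoing weight equals its
  specification exactly.

### Calibration of the default focus weights

The mouse-atlas analysis reports hippocampal strongest-outgoing weights of
0.36 (l CA1), 0.18 (l CA3) and 0.25 (l DG), bracketing that connectome's
empirical propagation band (0.22–0.31). Under the model constants used
here, the propagation band sits near 0.46–0.48 on the same max-normalized
scale, so the literal triplet would fall entirely below it and every focus
seizure would stay localized. The generator's default
`focus_out_weights = c(0.72, 0.36, 0.50)` is that triplet scaled by
exactly 2: the same high/low/mid pattern, placed so it brackets the
model's own band the way the original values bracket the atlas band. With
these defaults the CA1-like node produces widespread seizures, the
CA3-like node localized ones, and the DG-like node sits near the boundary,
across independent background draws. Calling the generator with the
literal atlas values still realizes them exactly; they simply all classify
as localized under these model constants.

What the surrogate does *not* emulate: the anatomical identity of
background regions, the atlas's empirical weight distribution beyond
heavy-tailedness, distance-dependent wiring, and tract lengths
(transmission delays are deliberately absent from the model). Passing
regime tests on surrogates therefore demonstrates that the pipeline
recovers the propagation phenomenology from the structural features it
claims to depend on — not that it reproduces atlas-specific numbers, which
require the original matrix (see the optional integration test gated on
`ALLEN_SC_CSV`).

## Experiment orchestration

`ez_sweep()` runs one simulation per (connectome, EZ) pair with a
single-node EZ, records recruited fractions, classes and the EZ's graph
measures, and flags failing rows instead of aborting.
`estimate_weight_thresholds()` extracts the regime band from a sweep: the
upper threshold is the largest strongest-outgoing weight among
localized-producing EZs, the lower one the smallest among
widespread-producing EZs. `evaluate_interventions()` and
`reduction_scan()` rerun the same seizure under modified connectomes;
`functional_connectivity()` correlates post-warmup LFP proxies and
`fc_similarity()` compares two such matrices by their upper triangles.

Surrogate ensembles mirroring the reference analysis are produced either
by regenerating with different seeds or by `randomize_weights()`, which
redraws each weight from `Normal(c, 0.1 c)` (negative draws fall back to
the original weight); the shipped convention uses seeds 1–20 for a
20-surrogate ensemble.

## Problem sizes and numerical choices in the shipped tests

The test-suite experiments use 98-node surrogates simulated for 6000 time
units at `dt = 0.05` with outputs sampled every 0.5 units — long enough to
contain a full EZ seizure cycle and the recruitment cascade, which
completes by roughly 3500 units in the widespread cases. The critical-x0
bisection probes a single node for 30000 units because the passage time
through the saddle-node ghost diverges near the transition; shorter
horizons bias the estimate toward less negative values. Exhaustive path
enumeration oracles are limited to six nodes; property checks loop over
100 seeded random matrices.

## Known limitations

* The propagation band of the implemented model (~0.47) is higher than the
  band reported for the atlas analysis (0.22–0.31); with the printed model
  constants no coupling placement reproduces the lower band, so
  atlas-specific numbers are out of reach without the atlas matrix and are
  tested only opportunistically.
* Onset times carry a detector lag (the 0.05 climb) relative to the true
  `z` minimum; orderings and classifications are unaffected.
* No transmission delays, no parameter fitting, no alternative Epileptor
  variants, and no voxel-level analysis.
* Whole-node resection is not a first-class operation; it is expressible
  as `remove_edges()` over a node's full edge list.
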