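# dynetsim

Similarity indices and simulation for dynamic weighted networks.

## The problem

Brain functional connectivity is not static: connectomes reorganize during
development, aging, disease and rehabilitation. A longitudinal study
therefore produces, per subject, a *dynamic network* — an ordered sequence
of `T` symmetric weighted adjacency matrices over a fixed set of `n` nodes
(ROIs). Classical network-comparison indices (Dice, Jaccard, spectral
distance, Pearson on vectorized snapshots) compare one snapshot at a time,
ignore temporal evolution, and usually require binarization that discards
weight information and negative connectivity.

`dynetsim` implements two indices that compare whole dynamic networks, for
researchers analyzing longitudinal connectomes (e.g. pre/post-treatment
resting-state fMRI), plus everything needed to validate them in
simulation.

## The indices

Write `V_A` for the **long vector** of network `A`: each snapshot's edge
vector (upper triangle, row-major), concatenated end-to-end along time
(length `T·m`, `m = n(n−1)/2`).

**Dynamic Network Similarity (DNS)** — sensitive to both structural and
temporal differences:

    DNS = ( Corr(V_A, V_B) · min(σ(V_A), σ(V_B)) / max(σ(V_A), σ(V_B)) + 1 ) / 2

The Pearson term measures the match of structural topology and evolutionary
trend; the population-SD ratio corrects for Pearson's amplitude blindness
(the long-vector variance decomposes exactly into a connectivity-strength-
span term plus an evolving-amplitude term, see `sd_decomposition()`).

**Dynamic Network Evolution Similarity (DNES)** — sensitive only to
temporal evolution. With `E_A^i` the `T`-length weight series of edge `i`:

    S_i  = Corr(E_A^i, E_B^i) · min(SD(E_A^i), SD(E_B^i)) / max(SD(E_A^i), SD(E_B^i))
    DNES = ( mean_i(S_i) + 1 ) / 2

Both indices live in `[0, 1]`: 1 = perfect correlation with matched
amplitudes, 0.5 = chance, 0 = perfect anticorrelation. Complexity is
`O(n²T)`, practical for 100–400-node atlas connectomes.

## Worked example

Simulate a pair of 10-node, 10-timepoint networks sharing structure but
with a phase offset of π/3 in their sine evolution, then score them:

```r
library(dynetsim)
pair <- make_network_pair(simulation_spec(delta_phi = pi/3,
                                          noise_power = 0.001, seed = 42))
dns(pair$net1, pair$net2)
#> <index_value> DNS = 0.895415
dnes(pair$net1, pair$net2)
#> <index_value> DNES = 0.724995
```

Both indices sit below 1 because the evolution is out of phase; DNES drops
further because it measures *only* the (desynchronized) evolution, while
DNS also credits the shared initial structure. Sweeping the phase offset
over `[0, π]` across 200 replicate pairs reproduces the index's
characteristic sensitivity:

```r
run_feature_experiment(1, noise_power = 0.001, n_reps = 200, seed = 42)
#> <experiment_result> Experiment 1: 200 replicates sweeping delta_phi (observation noise power 0.001)
#>   DNS : r = -0.9830, p = 1.03e-147, RSS = 0.1677
#>   DNES: r = -0.9934, p = 1.74e-188, RSS = 0.2860
```

The group pipeline runs from ROI time series to same-therapy (ST) vs
different-therapy (DT) statistics on a synthetic cohort (6/5/7 subjects,
20 ROIs, 230 volumes, a shared treatment effect on 9 edges):

```r
run_group_pipeline(generate_synthetic_cohort(seed = 1))
#> <group_pipeline> 19 selected edges; 30 ST pairs, 42 DT pairs
#> DNS:
#> <group_comparison>
#>   ST vs 0.5:   z =  4.782, p = 1.83e-06   d = 29.859 (n = 30)
#>   DT vs 0.5:   z =  5.645, p = 1.71e-08   d = 18.204 (n = 42)
#>   ST vs DT:    z =  7.196, p = 6.47e-13   d =  5.463 (n = 30x42)
#> DNES:
#> <group_comparison>
#>   ST vs 0.5:   z =  4.782, p = 1.83e-06   d = 111.430 (n = 30)
#>   DT vs 0.5:   z =  5.645, p = 1.71e-08   d = 78.278 (n = 42)
#>   ST vs DT:    z =  7.127, p = 1.07e-12   d =  4.165 (n = 30x42)
```

Read: both indices find high within-ST similarity (one-sample Wilcoxon vs
the 0.5 chance level) and significantly higher similarity among
same-therapy pairs than different-therapy pairs (Mann–Whitney), which is
exactly the structure the generator injects.

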