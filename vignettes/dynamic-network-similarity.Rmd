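---
title: "Measuring the similarity of dynamic weighted networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the similarity of dynamic weighted networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynetsim)
```

## The model

A dynamic network is an ordered sequence of `T` undirected weighted
snapshots over a fixed node set: a `T × n × n` array of symmetric,
zero-diagonal adjacency matrices. Two flattened views drive everything in
this package:

* the **long vector** `V` — each snapshot's edge vector (upper triangle
  excluding the diagonal, row-major), concatenated along time
  (`flatten_long_vector()`);
* the **edge time series** — for each of the `m = n(n−1)/2` node pairs,
  the `T`-length trajectory of its weight (`edge_time_series()`).

DNS scores two networks on their long vectors: the Pearson correlation
(structural topology plus evolutionary trend) times the min/max ratio of
the long-vector population standard deviations (amplitude and strength
span), affinely mapped to `[0, 1]`. DNES scores the same
correlation-times-SD-ratio quantity per corresponding edge series and
averages over edges, so it sees *only* temporal synchronization: it never
compares weights across different edges, which is why purely structural
perturbations leave it unchanged.

The long-vector population variance decomposes exactly into a
within-timepoint term (connectivity strength span) plus a
between-timepoint term (variance of the mean network strength over time,
the evolving relative amplitude); `sd_decomposition()` returns both and
the test suite checks their sum against the total variance to `1e-10`.
This is what justifies using the single SD ratio in DNS as a combined
amplitude/strength-span correction.

### Assumptions

Undirected networks, fixed node set over time, no self-loops, finite
weights. Pearson correlation assumes an approximately linear,
homoscedastic relation between corresponding weights; rank-based or
information-theoretic variants are out of scope. Node correspondence
between two networks is by position (an optional strict mode errors when
label lists differ).

## Conventions and numerical choices

* **Edge universe.** The upper triangle excluding the diagonal, row-major.
  Reshaping the full matrix instead would count every off-diagonal entry
  twice; matched duplication rescales the correlation and SDs identically,
  so every index is unchanged (tested). Including the zero diagonal would
  *not* be neutral — matched zeros shift means and SDs — and self-loops are
  meaningless here, so the diagonal is excluded throughout.
* **SD flavor.** Population SD (divide by the count), matching the
  `1/(nm)` normalization of the long-vector variance. The min/max ratio is
  flavor-invariant; reported components are population values.
* **Zero-variance conventions** (degenerate inputs): both vectors/series
  constant and equal → similarity term 1; constant and unequal → term 0
  (index 0.5); exactly one constant → term 0. Rationale: continuity of the
  min/max SD ratio as one σ → 0. Identical inputs short-circuit to exactly
  1 so that `dns(a, a)` is never `1 − 2e-16`.
* **DNES needs `T ≥ 2`.** With `T = 2` every per-edge correlation is ±1
  and `S_i` reduces to the signed ratio of the two pre/post changes; this
  is exactly the regime of the pre/post dynamic motor network, so `T = 2`
  is allowed and documented rather than rejected.
* **Spectral similarity.** Normalized Laplacian
  `L = D^(−1/2)(D − M)D^(−1/2)`; isolated nodes get `D^(−1/2)` entries of
  0 (eigenvalue 0). Spectra are sorted ascending and paired by rank. The
  normalized spectral distance is the Euclidean norm of the spectrum
  difference over the larger spectrum norm — this choice makes the
  distance 0 for identical spectra and exactly 1 when one graph is empty
  and the other is not, the two boundary behaviors the definition is
  required to have; `SS = 1 − SD_norm`, clamped to `[0, 1]`. Two empty
  graphs are identical (`SS = 1`), and likewise Dice/Jaccard of two empty
  edge sets are defined as 1.
* **Symmetry tolerance** for validation: `1e-9` absolute.

## The simulator: a stated world

`make_network_pair()` draws one shared generative state — initial weights
`F(0)` uniform on `[0.5, 1.5]` per edge, base amplitudes `a_i` uniform on
`[0.2, 0.5]`, base phases `φ_i` uniform on `[0, 2π)` — and evolves edge
`i` as `F_i(t) = F_i(0) + a_i sin(t + φ_i) + ε`, `t = 0, …, T−1`, with
i.i.d. Gaussian observation noise `ε` of the configured power, drawn
independently for the two networks (the robustness noise models
measurement error, not shared signal). Network 2 differs through the four
dials: `φ + Δφ`, `a / λ`, initial structure `β·(F(0) + η)` with
`η ~ N(0, √α)` applied before the β-scaling.

Parameter rationale, where the reference design leaves them open:

* `F(0)` on `[0.5, 1.5]` keeps weights positive with mean squared weight
  ≈ 1.08, satisfying the "edge power ≈ 1" premise of the SNR calibration
  (`SNR = 10·log10(P_S/P_N)`, so noise powers 0.1/0.01/0.001 are
  10/20/30 dB).
* `a_i` on `[0.2, 0.5]` lets the sine evolution modulate without
  dominating `F(0)` or flipping edge signs; `t` is the integer timepoint
  index (no sampling interval is part of the model), so `T = 10` spans
  about 1.6 sine periods.
* Sweep ranges: `Δφ ∈ [0, π]` (in-phase to anti-phase), `λ ∈ [0.05, 1]`
  (bounded away from the undefined 0), `α ∈ [0, 0.5]` (up to a
  perturbation comparable to the initial-weight variance), `β ∈ [0.1, 1]`
  (strong shrinkage to neutral; with `β ≤ 1` DNS increases toward 1 as
  `β → 1`, giving the positive correlation the sensitivity analysis
  reports).

"Repeated 200 times" is implemented as 200 replicates each with an
independently drawn variable value and fresh networks, with the Pearson
correlation computed across replicates — the reading that matches a
single scatter per experiment. Experiments 5–6 default to 1000
replicates; the σ of Experiment 5 is a noise *power* swept log-uniformly
up to 10, and Experiment 6's γ is the fraction of timepoints whose order
is permuted. One consequence of the shuffle definition (a random
permutation of `⌊γT⌋` chosen timepoints): for `γ < 2/T` the permutation
is the identity, so both indices are exactly 1 there and "DNS above DNES"
holds strictly only where disruption actually occurs.

Both indices are invariant to a *shared* timepoint permutation (Pearson
and SD are order-free), which is why the timing-disruption experiment
shuffles only one network of the pair.

## The group pipeline

From per-session ROI tables: pairwise Pearson correlations, Fisher-Z
(`atanh`, with r clipped to ±(1 − 1e-12) so duplicated ROIs give a large
finite z), Bonferroni-corrected binarization (strictly below `0.05/m`)
for the traditional indices only. DNS/DNES operate on the weighted
Fisher-Z matrices; negative z-values are retained, since discarding
negative functional connectivity is one of the criticisms of
binarization-based comparison. Edge selection is a paired t-test on
Fisher-Z values (post vs pre) across the *treated* subjects only, at an
uncorrected `p < 0.05` — lenient by design so the selected subnetwork is
not excessively small; sham subjects play no role in selection. Each
subject's `T = 2` dynamic network embeds the selected edges' z-values in
the full ROI node set (unselected edges 0). Pairwise similarities between
groups feed a one-sample Wilcoxon signed-rank test against the 0.5 chance
level (exact for `n ≤ 25`, normal approximation with continuity
correction otherwise, two-sided), a two-sided Mann–Whitney U test between
the ST and DT samples, and Cohen's d (one-sample: `(mean − 0.5)/SD`;
two-sample: pooled SD). Reported z statistics are normal-approximation
scores. A statistical caveat inherited from the design: pairwise values
sharing a subject are treated as independent observations.

## The synthetic cohort: what it emulates and what it does not

Real pre/post patient fMRI is not distributable, so
`generate_synthetic_cohort()` builds a stand-in with the same shape:
groups of 6 (tdcs1), 5 (tdcs2) and 7 (sham) subjects, 20 ROIs, 230
volumes per session. Sessions are zero-mean multivariate normal draws
from a cohort-level base correlation matrix (random 3-factor model;
positive-definiteness maintained by eigenvalue clipping) with per-session
Fisher-z jitter of SD 0.1. Nine designated edges carry a baseline
correlation of 0.45; treated subjects' post sessions reduce those
correlations by `effect_size` (default 0.25, a paired-test Cohen's d of
roughly 1.7 — a deliberately strong effect; `effect_size = 0.22`
corresponds to d ≈ 1.5 and is used in the power test). These defaults
were chosen once from the cohort geometry and are not tuned.

What a green end-to-end test establishes: the pipeline detects a *shared*
reorganization pattern among treated subjects — ST similarity above
chance and above DT — when one exists at this effect size and noise
level. What it does not establish: the generator has no temporal
autocorrelation within sessions, no physiological (cardiac/respiratory)
noise, no motion artifacts, no hemodynamic structure, and the real
study's effect sizes; the published patient-data statistics are therefore
*not* reproduced here, only the qualitative structure they exhibit.

## Design choices where the design was open

* The DNES average runs over **edges** (the per-edge `S_i`), resolving an
  ambiguity in the index's summation notation; the long-vector variance
  uses timepoints × edges.
* The sensitivity analysis of the strength-span dial is implemented with
  `β ∈ (0, 1]` and a positive DNS–β correlation; descriptions of that
  experiment elsewhere mix "increase" and "decrease" language, and the
  positive-correlation reading with `β ≤ 1` is the one consistent with
  the printed correlation signs.
* Structural noise `η` is applied before β-scaling and symmetrized by
  construction (drawn per edge); observation noise is independent between
  the two networks of a pair.
* Eigenvalue pairing by rank after ascending sort (the operative
  normalized-distance definition), rather than all-pairs double
  summation.

## Limitations

Directed or signed-direction networks and time-varying node sets are out
of scope. Missing or irregular timepoints require upstream interpolation
or alignment. The indices assume linearity/homoscedasticity via Pearson;
heavy-tailed weight distributions may warrant rank-based extensions. For
`T = 2`, DNES's per-edge correlations are saturated at ±1, so its
discrimination rests entirely on the SD-ratio term. The spectral
comparator requires nonnegative weights (use binarized or rectified
snapshots).
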