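---
title: "Structural-prior refinement of HD-MEA functional connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural-prior refinement of HD-MEA functional connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meaconn)
```

This vignette documents the models implemented in `meaconn`, the
assumptions behind them, the parameters that matter, and the numerical
and design choices made where more than one reasonable option existed.

## Setting and assumptions

The package targets sparse dissociated cultures (order 10²–10³ neurons)
grown on a high-density micro-electrode array: a 64 × 64 lattice of
square electrodes at 42 μm pitch, sampled at about 7 kHz. Two
observations of the same culture are assumed to be registered to the
lattice: a grayscale image in which neurites and somata are bright on a
dark background, and per-electrode spike-time lists. The analysis further
assumes that (i) essentially one single unit is recorded per electrode,
so electrodes can stand in for neurons; (ii) excitatory interactions
dominate the recording (the cross-correlogram statistic is blind to
inhibition); and (iii) anatomical connections constrain which functional
interactions are plausible — the core hypothesis that motivates using
structure as a prior on function.

## Structural prior

**Directional features.** Each electrode patch is summarised by the
probability that a neurite leaves it towards each of its 8 lattice
neighbours. Line segments stand in for neurite stretches; they are
detected with a Hough transform (bright pixels vote in a (θ, ρ)
accumulator; accumulator peaks are split into collinear runs). Each
segment endpoint contributes one Von Mises component: the mean direction
is the endpoint's bearing from the patch centre (its projection onto the
circumscribed circle), and the concentration κ = `kappa_scale` / (d + ε)
shrinks as the endpoint sits further from the patch boundary — a segment
ending deep inside the patch says little about where the neurite crosses
into a neighbour. Mixture weights are proportional to Hough votes.
Integrating the mixture over eight 45° sectors centred on the neighbour
bearings (E = 0°, counterclockwise, north = up) gives the feature; the
sector probabilities are computed from the Fourier–Bessel series of the
Von Mises distribution with exponentially scaled Bessel ratios, truncated
at order ~8√κ, which is accurate to well below 10⁻⁶ over the supported
range (κ capped at 10⁴).

**Heat-kernel propagation.** The features define a weighted 8-connected
lattice adjacency, symmetrised by summing the two directed contributions
of each edge. With the combinatorial Laplacian L = D − A, the heat kernel
h_t = exp(−Lt) (computed by dense symmetric eigendecomposition, which is
exact and affordable up to the full 4096-node array) measures how much
"heat" injected at one electrode reaches another after time *t*, flowing
preferentially along high-probability neurite directions. Heat is
conserved (rows of h_t sum to 1), h_0 = I, and h_t is symmetric positive
semidefinite — all asserted by the test suite, together with the
semigroup identity h_{t₁+t₂} = h_{t₁}h_{t₂}.

**Time parameter.** `t` trades locality against exploration: small *t*
keeps heat near the seed feature; large *t* mixes many features and, in
the limit, floods a connected graph uniformly (every entry → 1/|V|). The
default `t = 25` suits the 64 × 64 domain: wide enough to compose
features along multi-electrode neurite paths, short of flooding. The
monotonicity of exploration (the number of pairs above any fixed heat
level never decreases with *t*) is property-tested.

**Normalisation.** The heat matrix is restricted to *seed* electrodes
(those with ≥ 1 neuron — the only ones that can contribute recorded
activity) and divided by its maximum. The self-heat diagonal always
dominates, so normalising by the full-matrix maximum would compress all
candidate links into a narrow band near zero; the default therefore
normalises by the maximum *off-diagonal* seed-pair entry and zeroes the
diagonal, keeping strengths in [0, 1] over actual candidate links. The
full-matrix convention remains available (`include_diagonal = TRUE`)
because the alternative reading is defensible.

**SC graph and distances.** Normalised strengths at or above
`sc_threshold` become discrete structural links, with edge length the
euclidean distance between electrode centres (pitch for axial, pitch·√2
for diagonal neighbours, and longer for non-adjacent pairs). The
structural distance d_xy is the shortest-path length (Dijkstra, via
igraph) — the assumption being that minimal anatomical paths are
statistically the most probable routes for interaction. The default
`sc_threshold = 0.05` was calibrated once on the synthetic generator so
that ground-truth neurite edges are recovered essentially completely on
noise-free renderings; it is recorded in every output's parameter block
rather than hard-coded downstream.

## Functional graph

**Correlogram.** For electrode pair (x, y), spike-time differences are
binned at Δτ = 0.5 ms over ±`tau_max` and normalised by √(N_x·N_y). The
normalisation by the geometric mean of the spike counts is the only
reading consistent with the identity C_O = C_P·T·√(MFR_x·MFR_y), which
the feature extractor verifies for every link. `tau_max` defaults to
50 ms — an order of magnitude beyond the longest physiologically
plausible latency on the array (the 3.8 mm diagonal at 400 mm/s is
≈ 9.5 ms), so true peaks cannot fall outside the window. The peak search
covers both lag signs; exact ties resolve to the smallest |lag|, then to
the positive lag, favouring the physiologically proximate causal
reading.

**Velocity filter.** A link with |C_τ| < distance / 400 mm/s would
require above-physiological propagation speed and is discarded. The
filter uses the straight-line distance, which is conservative: any real
path is at least that long.

**Dithering null and C_s.** Each spike is jittered by an i.i.d. uniform
offset in ±5 ms (clipped to the recording window — wrapping would
manufacture coincidences at the record edges), destroying millisecond
synchrony while approximately preserving rates and slow structure. One
hundred repetitions on each of up to 500 randomly sampled active pairs
are pooled into one global null-peak distribution (a single threshold per
recording, matching how a single significance level is applied to the
whole graph); C_s is its empirical 95th-percentile order statistic
(`quantile` type 1), and a link is significant only when its peak
*strictly exceeds* C_s. The order-statistic/strict-exceedance pairing is
a deliberate numerical choice: correlogram peaks are small integer
counts, and an interpolated quantile combined with a ≥ rule measurably
inflates the false-positive rate above the nominal 5% on sparse Poisson
trains, while the chosen convention keeps it at or below nominal (the
acceptance suite measures this on 200 independent pairs).

## Integration

Starting from the unthresholded, velocity-filtered links: electrodes
without neurons are pruned (their "activity" is detection noise or stray
dendritic pickup); peaks are normalised by the maximum over the surviving
links and distances by the maximum finite shortest-path distance; and
each link is reweighted as W = C̃_P^(1+d). The exponent form — rather
than, say, a product or a negative exponential C_P·e^(−d) — has the
property that the *relative* penalty W/C̃_P at fixed distance increases
with C̃_P: weak correlations are penalised hard with distance while
strong correlations survive even over long paths, so the prior modulates
rather than overrides clear functional evidence.

The refined threshold W_s is the same-p order-statistic quantile of the
null peaks passed through the identical normalisation and reweighting,
each null peak paired with the structural distance of its own sampled
electrode pair. Two conventions matter here. First, null pairs involving
pruned electrodes are excluded: the null must live on the same universe
as the links it thresholds, and pruned pairs would carry the maximal
distance penalty and bias W_s downwards. Second, functional links with
no structural path at all are kept with d = 1 (maximum penalty) and an
`unreachable` flag rather than silently dropped — strong functional
evidence is reported even when the structural graph cannot explain it.
Degenerate cases are fixed by convention: a single surviving link
normalises to C̃_P = 1; a null peak exceeding the observed maximum is
clamped to 1.

**Accounting.** The per-network report mirrors the standard summary-table
form: stage counts plus derived percentages, with discard percentages at
one decimal and the pruning reduction as a whole percent (the precision
at which such reductions are customarily quoted). Discarded counts can be
supplied explicitly, because published tables print the discarded column
and it need not tally exactly with the retained column.

## Link classification

Features (C_P, C_O, C_τ, C_H, MFR_x, MFR_y) are computed from the
original spike trains only, so the labels (retained/discarded) come from
the structural prior but the features do not. The correlogram entropy
C_H = −Σ C_n log₂ C_n measures spread: broad, unreliable correlograms
score high, a single sharp peak scores zero. All 31 non-empty subsets of
the five feature groups are ranked by linear-SVM accuracy under seeded,
stratified 10-fold cross-validation; features are standardised per
training fold (never with test data), the SVM cost defaults to C = 1,
and the analytic noise level ACC_η = 100·max(class)/total — numerically
the majority-classifier accuracy — marks the plateau that uninformative
subsets converge to. Per-recording (rather than pooled) evaluation is
used, matching per-recording class imbalances.

## Synthetic generator

The generator emulates the observables of a sparse culture: neurons on
distinct electrodes (one per electrode by default, mirroring the
single-unit-per-electrode recording regime), neurites as curved
polylines between spatially proximal neurons (quadratic Bézier with
perpendicular midpoint jitter; connection probability decays with
distance, mean degree defaulting to 4 within a 6-pitch reach), images as
rasterised polylines plus soma discs under Gaussian blur and additive
noise, and spikes as homogeneous Poisson background (1 Hz default) plus
causal coupling: each functional link converts source background spikes
into target spikes with probability `coupling_p` (default 0.8) at delay
path-length / 100 mm/s plus Gaussian synaptic jitter (0.3 ms SD), never
below the 400 mm/s bound. The 100 mm/s conduction velocity sits in the
unmyelinated in-vitro range and places nearest-neighbour delays in a
non-zero correlogram lag bin, so genuine links are not destroyed by the
velocity filter's zero-lag exclusion. Couplings propagate one generation
(evoked spikes do not trigger further spikes), which keeps cascades
bounded and makes the expected firing rate analytically checkable.
Optionally, neuron-free electrodes emit independent Poisson trains,
emulating the spike-detection noise that the pruning stage exists to
remove.

What the generator does **not** emulate: bursting and network-wide rate
co-modulation, inhibition, multi-unit electrodes, optical artefacts
(uneven illumination, stitching seams), and soma-overlapping neurite
clutter. Consequently, passing the end-to-end tests shows that the
pipeline recovers connectivity under the stated statistical model of
sparse asynchronous cultures; it does not certify performance on
strongly bursting recordings, where the dithering null absorbs slow
co-modulation but chains of precisely timed propagation can still
produce structurally unsupported correlations.

## Problem sizes and budgets

The test and acceptance studies use a 16 × 16 sub-array with 100 neurons
and 300 s recordings (10 seeds) for end-to-end recovery, 256-node graphs
for heat-kernel checks, and 200 independent 1 Hz Poisson pairs for null
calibration — sizes chosen so the full suite runs in minutes on one CPU
while preserving the statistical regime (hundreds of spikes per train,
thousands of candidate pairs) of the full-array analyses.

## Known limitations

- The Hough detector works patch-locally; neurites that cross a patch
  corner in a few pixels can be missed, and crossing neurites within a
  patch share votes.
- The heat kernel is isotropic in time: one global `t` for all seeds. A
  spatially adaptive diffusion time might suit heterogeneous cultures
  better.
- The dithering null preserves structure slower than ±5 ms by design;
  it does not control for burst-locked coincidences.
- Shortest-path distance is a lower bound on the true anatomical path
  length of the interaction, and the SC graph inherits any threshold
  miscalibration from `sc_threshold`.
- With small spike counts the correlogram peak is a small integer; the
  strict-exceedance rule then makes the test conservative rather than
  exact.
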