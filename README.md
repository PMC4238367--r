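# meaconn

Functional connectivity estimation for neuronal cultures on high-density
micro-electrode arrays (HD-MEAs), refined by a structural prior computed
from a fluorescence image of the same culture.

## The problem

A 4096-electrode HD-MEA (64 × 64 lattice, 42 μm pitch) records
extracellular spikes from a sparse dissociated culture at cellular
resolution. Cross-correlating spike trains gives a *functional
connectivity* (FC) graph, but correlation alone produces many spurious
links — chance coincidences, common input, and physiologically
implausible long-range connections. After fixation and neurite staining,
the same chip can be imaged, so the *structural connectivity* (SC) of the
network is observable in the same coordinate frame. `meaconn` implements
a pipeline that uses the image-derived structural graph as a prior to
refine the correlation-based functional graph, and then asks which
functional features distinguish the retained links from the discarded
ones.

## The method

**Structural prior.** The image is partitioned into per-electrode
patches. In each patch, neurites are approximated by Hough-transform line
segments; each segment endpoint contributes a Von Mises component (mean =
the endpoint's bearing on the circle circumscribing the patch,
concentration κ = `kappa_scale / (d + ε)` for an endpoint at distance *d*
from the patch boundary, mixture weights ∝ Hough votes). Integrating the
mixture over eight 45° sectors yields a per-electrode probability
histogram over the 8 lattice neighbours. These directional features
define a weighted lattice adjacency *A* (symmetrised by summing the two
directed contributions), and structural connectivity is estimated by the
graph heat kernel

  h_t = Σ_i e^(−λ_i t) φ_i φ_iᵀ,  (λ_i, φ_i) the eigensystem of L = D − A,

with diffusion time *t* = 25. The heat map, restricted to electrodes that
actually contain neurons and max-normalised, gives SC strengths in
[0, 1]; thresholding it gives the SC graph, on which the *structural
distance* d_xy is the shortest-path length in μm.

**Functional graph.** For every active electrode pair the
cross-correlogram

  C_xy(τ) = (1/√(N_x N_y)) · #{spike pairs with lag in [τ − Δτ/2, τ + Δτ/2)},  Δτ = 0.5 ms,

is summarised by its peak C_P, peak lag C_τ, raw count C_O and entropy
C_H. Links whose lag is too short for the 400 mm/s maximum propagation
velocity are discarded; significance is assessed against a dithering null
(every spike jittered by ±5 ms uniform, 100 repetitions per sampled pair)
whose pooled peak distribution defines the threshold C_s at p = 0.05.

**Integration.** Electrodes without neurons are pruned, peaks and
distances are normalised to [0, 1], and each link is reweighted as

  W = C̃_P^(1 + d_xy),

which penalises weak correlations strongly with distance while letting
strong correlations survive even over long paths. Passing the null model
through the same reweighting yields the refined threshold W_s; links with
W ≥ W_s form the final graph.

**Classification.** Retained vs discarded links are characterised by
(C_P, C_O, C_τ, C_H, MFR_x, MFR_y); a linear SVM under stratified 10-fold
cross-validation ranks all 31 feature subsets, against the analytic noise
level ACC_η = 100 · max(class)/total.

A synthetic-data module generates ground-truth cultures (neurite
polylines rendered to an image, coupled-Poisson spike trains with
distance-consistent delays) so every stage is testable without external
data.

## Worked example

```r
library(meaconn)

grid   <- electrode_grid(16, 16, pixels_per_um = 12 / 42)
net    <- generate_network(n_neurons = 100, grid = grid, seed = 42)
img    <- render_image(net)
spikes <- simulate_spikes(net, T_s = 300, n_noise_electrodes = 15, seed = 42)

cfg <- pipeline_config(n_rows = 16, n_cols = 16, pixels_per_um = 12 / 42,
                       seed = 42)
res <- run_analysis(img, spikes, neuron_map = net$neuron_map, config = cfg)
print(res)
#> <structural_prior> 16 x 16 grid, 100 seed electrodes, 3044 SC links, t = 25
#> <functional_graph> 6555 pairs, 6115 passed velocity filter, 294 significant (C_s = 0.009631)
#> <refined_graph> 6115 links in, 178 retained (W_s = 0.01377, C_s = 0.009631)
#> Accounting report
#>   Neurons:                           100
#>   SC links:                          3044
#>   FC links (initial estimate):       6115
#>   FC links above C_s:                294
#>   Discarded at C_s:                  5821 (95.2%)
#>   FC links (neurons only):           4632
#>   Pruning reduction:                 24%
#>   FC links (neurons only, > C_s):    228
#>   FC links (final, above W_s):       178
#>   Discarded (final vs initial):      5937 (97.1%)

compare_recovery(res, net)
#> refined:  precision 0.517, recall 1.000
#> C_s-only: precision 0.404, recall 1.000
```

Reading the output: of 6115 velocity-plausible correlogram links, only
294 clear the dithering threshold, and the structural reweighting keeps
178. Against the generator's ground truth, the refined graph is
substantially more precise than thresholding on correlation significance
alone, at identical recall — the structural prior removes exactly the
links that have statistical support but no anatomical path of matching
length.

A command-line interface wrapping the same functions is installed at
`inst/cli/meaconn.R` (subcommands `simulate`, `structural`, `functional`,
`run`, `report`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","meaconn.R",package="meaconn"))')" \
    simulate --out-dir demo --seed 1
```

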