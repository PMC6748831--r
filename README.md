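# ectostorm

Quantitative analysis of **synaptic ectosomes (SE)** — the TCR-enriched,
sub-100 nm extracellular vesicles that helper T cells bud into the
immunological synapse. When a CD4⁺ T cell engages an antigen-presenting
surface, it deposits a few dozen SE carrying TCR, CD40L, ICOS and
tetraspanins; their composition, nanoscale organization and transfer
efficiency can be read out by three-color dSTORM, calibrated flow cytometry
and label-free proteomics. `ectostorm` implements that full analysis chain
as composable, data-frame-first R functions, together with a synthetic-data
module that simulates every input the pipeline consumes — so each estimator
can be validated by parameter recovery without any instrument data.

The package is for quantitative microscopists and immunologists who have
localization tables, cytometry exports or LFQ tables in hand, and for method
developers who need a tested reference implementation of the statistics
below.

## What it computes

**Single-molecule localization processing.** Peak detection and integrated
2-D Gaussian fitting (`localize_frames()`), the photon-count inclusion
filter (`filter_photons()`, default ≥ 2000 photons), merging of
localizations re-appearing within one camera pixel in consecutive frames
(`merge_consecutive()`), and Gaussian rendering at the per-localization
precision σ/√N (`render_localizations()`).

**Drift and channel registration.** Stage drift is estimated by
reconstructing images from 500-frame subsets and cross-correlating each
against the first time segment, with sub-pixel parabolic peak interpolation
(`estimate_drift()`, `apply_drift_correction()`). The 488 nm channel is
mapped onto the 640 nm reference by a least-squares polynomial transform
fitted to fiducial beads (`fit_channel_transform()`, `apply_transform()`).

**Vesicle segmentation and sizing.** Density-based clustering of the
membrane label channel (WGA/CD81) segments individual SE
(`segment_vesicles()`, radius ε = 50 nm, minimum 5 neighbors); each vesicle
diameter is the FWHM of the radially averaged rendered intensity profile
about the cluster centroid (`estimate_diameter()`). Receptor localizations
are assigned to vesicles and classified as TCR-only, partner-only or
double-positive (`assign_channels()`, `classify_positivity()`).

**Colocalization statistics.** Three complementary two-channel statistics:

- *Coordinate-based colocalization* (`cbc()`): for each localization the
  radial density profiles of the two channels,
  `D(r) = (N(r)/r²)·(r_max²/N(r_max))` on r = 10…50 nm, are Spearman
  rank-correlated and weighted by `exp(−d_nn/r_max)`; values run from −1
  (segregated) through 0 (random) to +1 (colocalized).
- *Angular-averaged pair cross-correlation* (`cross_correlation()`): the
  A–B pair-distance histogram up to 1000 nm, normalized by seeded
  complete-spatial-randomness draws inside the analysis mask, so `C(r) = 1`
  under randomness and `C(r) > 1` at co-clustering distances.
- *Nearest-neighbor distances* (`nnd()`), with per-cell medians, plus an
  image-level Pearson coefficient (`image_pcc()`).

**Transfer quantification and SE geometry.** MESF bead-ladder calibration
(log–log least squares, `fit_mesf_curve()`), isotype-corrected geometric
mean intensities and percent synaptic transfer
`100·GMFI_BSLB/(GMFI_BSLB + GMFI_Tcell)` (`percent_transfer()`), bead site
densities, total released SE membrane area `n·π·d²` and derived CD40L
trimer densities (`se_total_area()`, `se_density()`), and cytokine-array
fold changes (`cytokine_fold_change()`).

**Proteomic candidates and network modules.** Fold-change filtering of LFQ
tables (≥ 3.35-fold enrichment in every experiment,
`fold_change_filter()`) and Markov clustering of confidence-scored
interaction networks (`mcl()`, inflation 2.5; `module_filter()` reports
modules of three or more proteins).

**Synthetic data.** `generate_scene()` draws cells, vesicles (84 ± 5 nm,
36 ± 3 per cell), co-clustered or 150 nm-offset receptor clusters and
fiducials; `simulate_localizations()`, `simulate_frames()`,
`simulate_cytometry()` and `simulate_proteome()` produce localization
tables, raw image stacks, cytometry panels and LFQ tables with full ground
truth attached.

## Worked example

Simulate one synapse under the default study conditions, segment its
vesicles from the membrane channel, and classify per-vesicle positivity:

```r
library(ectostorm)
library(dplyr)

se_total_area(84, 37)
#> [1] 0.8201819    # ~0.82 um^2 of SE membrane released per synapse

sc  <- generate_scene(scene_params(n_cells = 1), seed = 1)
sim <- simulate_localizations(sc,
         blink_model(mean_blinks = 2, mean_on_frames = 1),
         acquisition_config(n_frames = 1000), seed = 2)

ves <- sim$locs |>
  filter(channel == "561") |>                      # membrane reference
  segment_vesicles(eps = 50, min_pts = 5) |>
  assign_channels(list(TCR   = filter(sim$locs, channel == "488"),
                       CD40L = filter(sim$locs, channel == "640")),
                  assign_radius = 100) |>
  classify_positivity(min_locs = 3)

positivity_fractions(ves)
#> # A tibble: 3 x 3
#>   class               n percent
#> 1 tcr-only            9    25.7
#> 2 partner-only        6    17.1
#> 3 double-positive    20    57.1
```

The scene was generated with a 54.5% double-positive fraction; the pipeline
recovers 57.1% on these 35 segmented vesicles (within the binomial
sampling error of n = 35). Because the default partner is CD40L, whose
clusters sit ~150 nm off the TCR cluster, the coordinate-based
colocalization between the TCR and CD40L channels is negative:

```r
glance(cbc(filter(sim$locs, channel == "488"),
           filter(sim$locs, channel == "640")))
#> # A tibble: 1 x 4
#>   mean_value median_value n_evaluated n_excluded
#> 1     -0.133            0        1451          0
```

Every result type has an `autoplot()` method (CBC histograms, C(r) curves
with uncertainty ribbons, diameter distributions, drift trajectories,
rendered images) and fitted objects have broom-style `tidy()`/`glance()`
methods.

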