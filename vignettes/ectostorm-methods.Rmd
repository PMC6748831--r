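---
title: "Models and methods behind ectostorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ectostorm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ectostorm)
```

`ectostorm` analyzes synaptic ectosomes (SE): sub-100 nm vesicles budded
from the T-cell membrane into the immunological synapse, read out by
three-color dSTORM, calibrated flow cytometry and label-free proteomics.
This vignette documents the models behind each stage, the parameters that
matter, the numerical choices, and what the synthetic-data generator does
and does not emulate.

## The forward model: what the generator simulates

A scene is a hierarchy of tibbles: circular cell footprints (default radius
2.5 µm), vesicles per cell drawn as round(Normal(36, 3)) truncated at zero,
vesicle diameters Normal(84 nm, 5 nm) truncated positive, and protein
clusters per vesicle. These defaults are the study conditions the package
is built around: electron microscopy and dSTORM agree on ~84 nm vesicles,
and roughly three dozen are released per synapse.

Each vesicle carries a membrane glycan label (WGA/CD81 channel) modeled as
a uniform density over the vesicle disk — a filled-disk model is the right
null for a lectin that decorates the whole membrane. Receptors are compact
Gaussian clusters (σ = 10 nm, 30 molecules) because TCR and its partners
form microclusters rather than diffuse coats. Co-clustered partners (ICOS,
BST2) share the TCR cluster center. CD40L clusters are displaced by
Normal(150 nm, 10 nm), capped at the vesicle radius, so vesicles smaller
than the drawn offset place CD40L at the rim; this reproduces lateral
segregation while keeping the cluster on the vesicle, and the cap is why a
cross-correlation peak at 150 nm must be validated on constructed
displacement fixtures rather than on full scenes. Class fractions default
to 54.5% double-positive with the remainder split evenly between
single-positive classes.

Photophysics is deliberately minimal: a labeled molecule (labeling
efficiency 0.8) blinks 1 + Poisson(mean − 1) times at uniformly random
frames, each blink lasting a geometric run of consecutive frames (mean 2),
with log-normal photon counts (mean 4000, log-sd 0.3) per emitted
localization. The photon mean is set above the 2000-photon inclusion
threshold so that the filter and the consecutive-frame merging rule are
both exercised with realistic survivor fractions. Localizations are the
molecule position plus the stage drift at their frame, plus the
inter-channel warp (488 nm channel only — the 561/640 difference is treated
as negligible, so 561 passes through unregistered), plus isotropic Gaussian
error. Fiducial beads are always on, in every channel and frame. There is
no dark-state chemistry, no 3-D/astigmatic PSF and no EMCCD gain/read-noise
model; raw frames add only a Poisson background under pixel-integrated
Gaussian PSFs. Consequently, passing parameter-recovery tests demonstrates
estimator correctness under this forward model — not robustness to
overlapping emitters, heavy-tailed photon statistics or axial blur in real
data.

## Localization processing

Peaks are strict 3×3 local maxima above an intensity threshold; plateau
ties keep one pixel. Fits minimize least squares of a pixel-integrated 2-D
Gaussian with constant background (BFGS, relative tolerance 1e-12;
amplitude and width parameterized on the log scale to keep them positive);
non-convergent or out-of-window fits are dropped and counted rather than
imputed, matching the threshold-based inclusion philosophy of the rest of
the pipeline. The localization precision is the first-order Thompson rule
σ/√N. It ignores background and pixelation corrections; it is used for
rendering and truth-matching, where that accuracy suffices.

Merging links localizations in *consecutive* frames within one camera pixel
(default 107 nm, a 150× EMCCD geometry) into a photon-weighted mean with
summed photons. Chains of any length are linked by default: the
five-consecutive-frame figure in the underlying protocol is read as the
longest on-time worth merging, not a hard cap, but `max_frames = 5`
restores the capped reading. Rendering uses unit-mass Gaussians normalized
on the discrete output grid, so the image integral equals the number of
rendered localizations exactly, with a 6σ kernel window.

## Drift and registration

Drift is estimated by binning each 500-frame subset into a 2-D histogram
image and cross-correlating it against the first subset via FFT, with
three-point parabolic interpolation per axis performed on the logarithm of
the correlation samples (exact for a Gaussian-shaped peak). The correlation
image pixel defaults to one tenth of the camera pixel: coarser grids leave
visible pixel-locking in the sub-pixel estimate, and a ~11 nm grid keeps
the interpolation stable without excessive memory. Knot displacements sit
at subset centers; the trajectory is piecewise-linear between knots with
constant extrapolation at the ends — the simplest rule consistent with
subset-resolution estimates. Constant end-extrapolation contributes a small
deterministic error within the first and last half-subsets, which is the
dominant term in the recovery error for a linear drift. Subsets with too
few localizations are flagged and interpolated over. Correction subtracts
the interpolated displacement; it is linear, hence deliberately not
idempotent.

Channel registration fits per-axis polynomials (default order 1, i.e.
affine; order 2 available) by least squares on fiducial pairs, requiring at
least as many pairs as coefficients and rejecting degenerate (collinear)
geometries through the rank of the design matrix. The inverse mapping is
solved per point by Newton iteration with the analytic Jacobian, converging
in one step for affine transforms.

## Vesicle segmentation and sizing

Segmentation is density-based spatial clustering with grid-hashed region
queries (ε = 50 nm, min_pts = 5). ε sits at the colocalization search
radius scale: about half a vesicle diameter, large enough to hold an SE
together and small enough to separate vesicles a few hundred nanometers
apart. Noise points are excluded. No installed package provides this
clustering, so it is implemented directly; it is deterministic given input
order.

The diameter is the full width at half maximum of the radially averaged
rendered intensity profile about the cluster centroid. The angular average
of a unit Gaussian at centroid distance d is proportional to
`exp(−(r−d)²/2σ²)·I₀(rd/σ²)`, evaluated with the exponentially scaled
Bessel function for numerical stability, so the profile is computed in
closed form on a 512-point radial grid without rasterizing an image. The
FWHM is read at the outermost half-maximum crossing with linear
interpolation. Two known biases are documented rather than corrected: the
curved edge of a disk convolved with the rendering kernel pulls the
half-maximum crossing slightly inward (a few percent at 84 nm with 10 nm
precision), and re-blinking concentrates samples on a finite set of
molecule positions, which lumps the profile and shrinks estimates further
on fully simulated scenes. A degenerate cluster whose members coincide
returns the rendering-limited FWHM (2.355 × precision) and is flagged.

Receptor localizations are assigned to the nearest vesicle centroid within
100 nm; exact ties go to the lowest vesicle id for determinism. A channel
is "positive" on a vesicle at ≥ 3 assigned localizations — enough to reject
single spurious localizations, few enough not to miss a sparsely labeled
cluster; it is exposed as a sensitivity parameter because the original
scoring rule for per-vesicle positivity is not recorded. Class percentages
are reported over vesicles positive for at least one channel and sum to
100 exactly.

## Colocalization statistics

The per-point coordinate-based colocalization statistic rank-correlates the
two channels' neighbor-density profiles `D(r) = (N(r)/r²)·(r_max²/N(r_max))`
on five radii (default step r_max/5 — at least five ranks for a meaningful
Spearman) and weights by `exp(−d_nn/r_max)`; the weighting can be switched
off (`weighting = "none"`). Ties take average ranks. The evaluated point is
excluded from its own channel's counts, and an exactly coincident partner
in the other channel is excluded too, so a duplicated channel scores
exactly +1. Points with no same-channel neighbor inside r_max are undefined
and excluded with a count; profiles constant in both channels score +1 when
identical and 0 otherwise. Because both normalized profiles always end at
exactly 1, the statistic has a small positive bias under complete spatial
randomness (of order +0.1 at the default five radii); that bias is a
property of the published definition and is left intact.

The pair cross-correlation tabulates A–B distances into 10 nm bins up to
1000 nm and normalizes by the mean histogram of seeded uniform re-draws of
the same point counts inside the analysis mask (default 20 draws). This
Monte-Carlo normalization supplies the edge correction for arbitrary
rectangular or polygonal masks, at the cost of a small normalization noise
that shrinks as draws increase. The per-bin uncertainty is the standard
deviation of the re-draws on the normalized scale — an honest null-scale
error bar. Peak extraction excludes bins whose relative uncertainty exceeds
0.25: the shortest-distance bins hold only a handful of reference pairs and
their ratio estimates are shot-noise dominated. Nearest-neighbor distances
are computed exactly (chunked distance evaluation, no spatial
approximation) and summarized as per-cell medians when labels are given.

## Cytometry, geometry, proteome

The MESF calibration is a log–log least-squares line after blank
subtraction, refusing non-monotone ladders; conversions outside the
calibrated range are flagged. GMFIs are geometric means over strictly
positive events with excluded counts reported, and isotype-corrected values
clamp at zero — transfer cannot be negative, and the clamp is recorded in
the function contract rather than silently applied. Percent transfer is the
bead-side share of the summed corrected GMFIs. Vesicle and bead areas use
the sphere surface `πd²`; with d = 84 nm the 37-vesicle total area is
0.82 µm², and the derived CD40L density divides monomers by three for
trimers. The T-cell surface area in the "fraction of cell surface"
estimate is an explicit caller-supplied assumption (≈ 410 µm² reproduces
the ~0.2% figure); it is not measured by this package.

The fold-change filter works on tidy LFQ tables with explicit missing
values: detected-in-plus/absent-in-minus is infinite enrichment (kept),
absent-in-plus is fold change 0 (kept only under two-sided filtering, which
is off by default because the candidate definition is enrichment over the
control beads). The default threshold is the linear 3.35; the equivalent
log2 formulation (>1.75, i.e. 3.364) differs in the third digit and either
can be passed explicitly. The generator's default true effect is 6-fold:
strongly ligated cargo is enriched well above the threshold, so recovery
under 0.2 log-sd noise is informative; a 4-fold effect sits close enough to
3.35 that noisy recovery is intrinsically partial, which the noiseless test
case makes exact instead.

Markov clustering column-normalizes the confidence-weighted adjacency with
self-loops (loop weight = column maximum), then alternates expansion
(matrix square) and inflation (entrywise power 2.5 with renormalization),
pruning entries below 1e-6 and stopping when the matrix changes by less
than 1e-8 (at most 200 iterations; non-convergence is an error with the
last delta reported). Clusters are connected components of the limit
matrix's support. Because every iterate of a block-diagonal matrix stays
block-diagonal, disconnected graph components can never merge — asserted as
a property test. Reported modules need ≥ 3 members.

## Problem sizes and determinism

All generators are pure functions of (parameters, seed), restoring the
caller's RNG state. The shipped tests and the acceptance script use desk
scales chosen to make each check statistically meaningful at interactive
runtimes: scenes of 1–3 cells (≈ 35–110 vesicles), 1000-frame acquisitions,
drift fixtures of 4000 molecules × 10 blinks over 5000 frames, 200 vesicles
per diameter condition, 100-seed loops for the displacement and clustering
property checks, 2000 events per cytometry population and 200-protein
proteomes. The per-vesicle label budget (40 membrane molecules, 30 per
receptor cluster) is on the sparse side of realistic WGA/antibody
densities, which keeps segmentation honest about finite-sampling effects.

## Limitations

Everything above is validated against the package's own forward model.
Real dSTORM data add overlapping emitters, variable duty cycles,
non-Gaussian PSF tails and axial structure that this package neither
simulates nor corrects. The CBC statistic inherits the positive CSR bias
of its published definition; the diameter estimator carries a known
negative bias of a few percent on filled disks; the cross-correlation's
Monte-Carlo normalization trades analytic exactness for mask generality.
FCS binary parsing, gating, spillover compensation, peptide-level
proteomics and interaction-database retrieval are out of scope: the
package consumes CSV exports, summary tables and edge lists.
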