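---
title: "Quantifying plasma-membrane protein nanodomains from confocal and immunogold data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying plasma-membrane protein nanodomains from confocal and immunogold data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanodomain)
```

Polarly localized plasma-membrane proteins of plant cells — the PIN
auxin-efflux carriers are the canonical example — are not spread uniformly
over the membrane face they occupy: they aggregate into sub-micron clusters
whose density, size and spatial organisation differ between the apical,
basal and lateral domains of the cell. `nanodomain` implements the two
complementary quantification routes used to measure this organisation, a
thresholding-free blob detector for confocal stacks and a distance-based
clustering analysis for immunogold particle coordinates, together with
seeded generators of synthetic data so every stage can be validated without
access to original micrographs.

## The confocal route

### Model and procedure

Clusters in confocal stacks are diffraction-limited bright spots lying on a
membrane sheet that is roughly perpendicular to the optical axis. Because
the structures of interest occupy only a handful of voxels, segmentation by
a global intensity threshold is fragile — bleaching, depth attenuation and
expression differences shift absolute intensities between (and within)
images. The detector therefore never compares intensities to a fixed value,
only to each other:

1. **Projection.** Each membrane region of interest (an axis-aligned
   sub-volume with a declared membrane-normal axis) is collapsed by a
   maximum-intensity projection (`project_membrane()`). The axial
   elongation of the confocal point-spread function makes clusters appear
   stretched along z; projecting along the membrane normal removes that
   artefact from the in-plane analysis.
2. **Strict local maxima.** A pixel is a peak when all eight neighbours are
   strictly dimmer (`find_local_maxima()`). Plateaus produce no peak;
   border pixels with incomplete neighbourhoods are excluded.
3. **Growing windows.** Around each peak, windows of side $2n+1$
   ($n = 1, 2, \dots$) grow until some pixel in the window is strictly
   brighter than the peak (`estimate_cluster_size()`). The largest clean
   $n$ defines the size class, side $2n+1$ pixels. A call whose growth is
   stopped by the image border or by the cap `n_cap` (default 6) is marked
   `capped`: its size is only bounded, not resolved.
4. **Gating and density.** Calls with side 5–9 px are retained
   (`filter_size_classes()`); at the default 0.089 µm lateral pixel size
   these correspond to physical diameters of 0.445–0.801 µm (conventionally
   printed as 0.44 and 0.80). Smaller classes are single bright pixels,
   larger ones are typically overlapping membrane sections. The membrane
   area is estimated by brightness thresholding of the projected plane
   (Otsu by default, absolute override available) and the result is
   reported as clusters per µm² (`cluster_density()`).

Two pixel-size conventions coexist for the same measurement: the default
reports the full odd window side $2n+1$; an alternative `diameter2n` flag
reports $2n$. The $2n+1$ convention is the one consistent with the 5–9 px
retained range and is the default.

### Size classes are a noise-mediated measurement

A point worth making explicit, because it governs every synthetic
experiment in this package: for an *isolated, smooth* spot on a flat
background, the growing window never meets a brighter pixel beyond the spot
itself, so its size would grow to the cap and the call would be discarded.
What stops growth at a realistic size is the image noise riding on the spot
and its surroundings — a noise excursion beats the radial intensity deficit
of the spot profile at a distance that scales with the spot width and the
amplitude-to-noise ratio. Size classification is therefore only meaningful
in the regime where spot amplitude is a moderate multiple of the noise
scale (roughly 4–8 noise standard deviations at the projected plane, after
point-spread-function and projection losses). Far above that regime the
sizes cap out; far below, peaks stop at side 3. The synthetic stack
generator is parameterised to sit inside the informative regime.

### False-positive curation

On real data, dim bright pixels popping out of noise — on the membrane, at
its border, or in empty background — satisfy the local-maximum rule and
must be discarded; in the original workflow this is done by eye. The
package replaces that manual step with a reproducible *low-contrast flag*:
the mean of the 3×3 core around the peak must exceed the median of the
membrane-classified pixels (at or above an Otsu brightness threshold) of a
wide annulus (Chebyshev radius `n_cap + 2` to `3 * n_cap`) by at least
`low_contrast_k` robust noise standard deviations (default 2; the noise
scale comes from the median absolute lag-1 pixel difference,
`plane_noise_sd()`). Restricting the reference to membrane-bright pixels is
what makes the flag work at borders: a bright pixel at the edge of the
membrane is compared against membrane brightness, not against the dark
surround that would inflate its apparent prominence. The flag is
scale- and offset-invariant, like the detector itself. Flagged calls are
never dropped silently; `drop_low_contrast = TRUE` must be requested
(the synthetic validation experiments do so, standing in for the manual
curation).

During implementation we found that the simpler rule "flag calls whose 3×3
mean lies below a fixed percentile of the plane" cannot work: the correct
percentile depends on the fraction of the plane covered by clusters, so any
fixed choice either swallows true clusters at high density or admits noise
maxima at low density. The annulus-prominence flag is density-independent.

One further consequence of noise-mediated sizing: a single cluster can
produce a second, dimmer local maximum on its flank that also passes the
gate. `filter_size_classes()` therefore applies non-maximum suppression by
default (`suppress_overlaps = TRUE`): among retained calls, one whose
window overlaps a brighter call's window is suppressed, so one cluster
yields one call.

## The immunogold route

Freeze-fracture replica labeling (SDS-FRL) gives en-face membrane views in
which each target molecule is marked by a gold particle; thin-section
immunogold electron microscopy (IEM) gives membrane profiles. Both reduce
to planar point patterns in nanometre coordinates.

* **Linkage.** Two particles belong together when their centre-to-centre
  distance is at most 55 nm (equivalently, 27.5 nm-radius circles around
  the centres overlap); groups are the connected components of this
  relation (`link_particles()`, single linkage, inclusive at the
  threshold). The threshold reflects label geometry: each gold particle can
  sit up to ~20 nm from its epitope because of the antibody bridge, so two
  labels of one molecular assembly can be separated by roughly this
  distance. The implementation is a grid-bucketed union-find; tests verify
  exact agreement with an independent single-linkage dendrogram cut.
* **Classes.** Groups of 1, 2 and ≥3 particles are *scattered*, *doublets*
  and *clusters*; fractions are reported as percentages of particles, not
  of groups, so the three fractions sum to 100 %
  (`classify_particle_groups()`).
* **Diameters.** A group's diameter is its Feret diameter (maximum pairwise
  centre distance), optionally inflated by the physical gold diameter
  (`group_diameter()`); no formula being standard, this is the simplest
  reproducible choice.
* **Polar bands.** Particles within 2 µm of the apical edge are apical,
  within 2 µm of the basal edge basal, and within a 2 µm-wide band centred
  on the cell midline central (`assign_membrane_domains()`). When apical or
  basal bands would overlap the central band, the polar bands take
  precedence; cells shorter than twice the band width are rejected. Band
  densities divide counts by the polygon-clipped band area of the analysed
  region (Sutherland–Hodgman half-plane clipping; shoelace areas).
* **Profiles.** `particles_per_cluster_gradient()` bins clusters by the
  axial distance of their centroid from the apical edge and reports mean
  particles per cluster and cluster counts per bin (empty bins are missing,
  not zero). `iem_profile_summary()` summarises per-image cluster counts as
  mean ± SD, per µm of membrane profile when lengths are given.

`detect_gold_particles()` covers the upstream extraction step for users
starting from micrographs rather than coordinate tables: 8-connected
components of a thresholded image, filtered by pixel area, reported as
centroids in nm.

## The polarity index

`apical_lateral_ratio()` computes, per cell, the mean voxel intensity over
an apical membrane ROI divided by that over a lateral ROI, optionally after
subtracting a background ROI mean from both. Mean (not integrated)
intensity is used so the ratio does not depend on ROI size, and background
subtraction is off by default; both choices are stated rather than implied
because conventions vary. Ratios are computed per cell and then averaged
across cells (`aggregate_polarity()`), so large cells do not dominate.

## Statistics

Group comparisons use the Mann–Whitney U test (exact null for small untied
samples, mid-rank normal approximation with ties) or Student/Welch t-tests,
two-sided, through `compare_groups()`; `summarize_conditions()` produces
mean ± SD tables with comparisons against a declared control.
Significance-star conventions differ between venues, so the p-value
thresholds behind the stars are an explicit argument and are echoed in the
output rather than hard-coded.

## Synthetic data: what is emulated, and what is not

Neither raw micrographs nor a generative model are available for the
original measurements, so the generators are explicit stand-ins whose
defaults encode the study conditions this package validates itself under.

### Confocal stacks (`simulate_membrane_stack()`)

A membrane face is a slab (default 2 voxels thick) perpendicular to a
principal axis, optionally restricted to a strip so the projected plane
contains both membrane and dark background, as real ROIs do. Clusters are
planted as a Poisson process on the face (expected count = density × area)
and rendered as isotropic in-plane Gaussian spots of full width at half
maximum `cluster_diameter_um`, extruded through the slab. The volume is
blurred with a separable anisotropic Gaussian (axial sigma > lateral,
emulating z-elongation) and corrupted by additive Gaussian and/or Poisson
noise; negative values clip at zero.

Defaults, chosen once to sit in the informative sizing regime and then
frozen: 180×180×16 voxels at 0.089/0.089/0.313 µm; spot FWHM 0.75 µm
(mid-to-upper part of the 0.45–0.80 µm retained size range); spot amplitude
1000 over a membrane baseline of 1500; noise σ 160 (amplitude-to-noise 6.25);
PSF sigmas 0.1 µm lateral, 0.35 µm axial. Under these conditions the
full pipeline recovers planted densities of 0.19 and 0.06 µm⁻² with mean
estimate-to-truth ratios of about 0.7 and 0.95 over ten seeds — an
acceptable but visibly imperfect efficiency, dominated by spots whose
growing window stops at side 3 or runs past side 9, which is intrinsic to
noise-mediated sizing, plus merging of closely spaced spots.

Not emulated: realistic optics beyond a Gaussian PSF, membrane curvature
and texture, spot amplitude heterogeneity, bleaching. Passing the recovery
tests shows the pipeline is internally consistent under the stated model;
it does not certify accuracy on real membranes, where cluster contrast and
crowding differ.

### Immunogold fields (`simulate_particle_field()`)

A Thomas-type cluster process: parents from an inhomogeneous Poisson
process whose intensity decays exponentially with distance from the apical
edge (decay length `gradient_decay_um`, infinite = uniform), each emitting
a Poisson number of labels with isotropic Gaussian scatter (default σ
15 nm), plus a homogeneous scattered component. Every label is displaced
uniformly within a 20 nm disc (the epitope-to-gold offset), retained with
the labeling efficiency, and clipped to the field.

Ground truth uses *configuration truth*: the 55 nm linkage applied to the
noiseless, pre-displacement, pre-thinning configuration assigns every label
its true class, so recovery experiments measure exactly the effect of
displacement, partial labeling and clipping. Parents may fall up to three
offspring sigmas outside the field (plus-sampling) so edge intensity is
unbiased.

The two validation conditions mirror the study's contrast between a
polar, clustered protein and a uniform control: a PIN2-like field
(parents 2.4 µm⁻², offspring Poisson(5), scattered 9 µm⁻²; total ≈ 21
labels µm⁻², clustered fraction ≈ 0.55) and a PIP2a-like field (parents
0.039 µm⁻², offspring Poisson(3), scattered 2.88 µm⁻²; total ≈ 3 µm⁻²,
clustered ≈ 0.03). With 20 nm displacement and efficiency 0.8 the
recovered clustered fractions track configuration truth to within 0.05
(bias ≈ −0.03 for the clustered condition: thinning demotes some
three-particle clusters to observed doublets).

Not emulated: fracture-face occlusion (only one membrane leaflet carries
the epitope), antibody steric competition at dense clusters, non-circular
cluster shapes.

## Numerical choices and degenerate inputs

* Ties in peak detection: strict inequality, so plateaus yield no peak —
  deterministic, at the cost of missing mathematically flat maxima (which
  do not survive noise anyway).
* Window growth is capped at `n_cap = 6` (side 13): sizes above the gate
  are discarded regardless, and growth must terminate.
* Border windows: a brighter pixel found in a border-clipped window stops
  growth normally (clipping never hides an in-image pixel); a clean clipped
  window marks the call capped.
* Inclusive thresholds throughout the linkage (≤ 55 nm), matching the
  overlapping-circles construction; coordinates are nm, areas µm².
* The linkage grid uses cells of side `dmax` and scans the eight
  neighbouring cells, so no sub-threshold pair is missed; union-find
  guarantees a partition (every particle in exactly one group).
* Empty inputs: empty planes/ROIs are rejected with messages; empty
  particle sets classify to `NaN` fractions with an explicit `empty` flag;
  empty gradient bins are `NA`, not zero.
* Zero-variance t-tests with equal means report p = 1 with a flag.
* All simulators take a mandatory seed and are bit-reproducible for a
  given (parameters, seed) pair; the acceptance script derives all its
  seeds from one command-line seed.

## Problem sizes used in the shipped experiments

The validation experiments use 180×180×16-voxel stacks (10 seeds per
density level), 10×10 µm particle fields (20 seeds per condition), 100
random planes up to 32×32 px and 100 random point sets up to n = 300 for
the oracle-equivalence checks. These sizes give stable Monte-Carlo means
(standard errors a few percent of the quantities checked) while keeping a
full run in the minutes range on one CPU.

## Known limitations

* Density recovery efficiency is condition-dependent (see above); absolute
  densities from the confocal route should be compared only between images
  acquired and analysed identically — which is how such densities are used.
* The growing-window size class is not a physical diameter estimator; it is
  a reproducible ranking of blob footprints under fixed imaging conditions.
* Band densities assume the analysed-region polygon is simple (non
  self-intersecting).
* The IEM route treats membrane profiles as planar point sets with an
  axial coordinate; no correction for section thickness is attempted.
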