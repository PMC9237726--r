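---
title: "Methods and design of spectromap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of spectromap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectromap)
```

# The problem

Fourier transform infrared (FTIR) microspectroscopy measures a full
mid-infrared absorbance spectrum at every position of a raster scan across a
specimen, yielding a hyperspectral image: thousands of pixels, each a vector
of absorbances over a wavenumber axis (cm^-1^). The functional-group
specificity of the mid-IR makes each spectrum a chemical fingerprint —
amide I/II bands report protein content and backbone conformation, CH~2~
stretches report lipids, phosphate bands report nucleic acids. spectromap
provides a scripted, batch-oriented pipeline for such data across many
samples at once: per-pixel quality control, spectral pre-processing, PCA,
graph-based clustering of pixels into chemically coherent regions, band
quantification, and reconstruction of every per-pixel result as a 2-D map in
acquisition layout.

The central container is the `spectral_map`: an `n_pixels x n_wavenumbers`
absorbance matrix, a strictly ascending wavenumber axis, per-pixel sample
identifiers and optional grid metadata (`nx`, `ny`, raster order). All
wavenumber intervals throughout the package are closed, and the axis is
never resampled: joining samples requires identical axes (within
10^-6^ cm^-1^), because silent interpolation would change band areas.

# Quality control

Two per-pixel detectors produce keep/exclude masks over the *original* pixel
order; the saved exclusion positions are what later allows results to be
repopulated into the acquisition raster with excluded pixels shown as
missing, rather than silently shifting the image.

**Empty positions** (holes in the section, regions beyond the sample border)
are detected as pixels whose mean absorbance inside a window — by default
1600–1700 cm^-1^, the amide I region — falls below a threshold (default
0.1). Any pixel containing tissue carries protein and therefore amide I
absorption; a position with no sample shows only detector noise there.

**Scattering outliers** are flagged by either of two cheap criteria,
OR-combined: (a) the absolute least-squares slope of the spectrum across the
spectroscopically silent region 1800–2600 cm^-1^ exceeds
10^-3^ absorbance/cm^-1^ — biological samples have essentially no
fundamental vibrations there, so a pronounced slope is the broad Mie-type
scattering baseline; or (b) more than 60% of the spectrum's channels are
negative, indicating a distorted baseline. The 0.6 default for the
negative-channel fraction is deliberately above 0.5: a noise-only spectrum
at an empty position fluctuates symmetrically about zero and sits near 0.5,
and empty positions are the first detector's concern. Full EMSC/resonant-Mie
correction is out of scope by design; pixels evidencing scattering are
excluded, not corrected.

Masks compose by logical AND of the keep flags; where two masks exclude the
same pixel, the first-listed mask's reason code is kept (an arbitrary but
deterministic rule, and the composed keep vector is order-independent).

# Pre-processing

**CO~2~ excision.** Atmospheric CO~2~ absorbs near 2349 cm^-1^ and varies
with purge conditions, not with the sample; leaving it in creates batch
effects in clustering. `exclude_co2()` removes all axis points in a closed
window (default 2300–2400 cm^-1^). The operation is idempotent, and a
window disjoint from the axis is a no-op.

**Vector normalization.** Each retained spectrum is scaled to unit Euclidean
norm, removing section-thickness and sample-amount effects. It is applied
*after* QC by contract — a zero spectrum cannot be normalized, and
normalizing junk pixels would be wasted anyway. Normalization is idempotent
and scale-invariant.

**Second derivative.** The Savitzky–Golay second derivative (default window
9 points, polynomial order 3, scaled by the axis spacing squared; units
absorbance·cm^2^) annihilates constant and linear baseline components
exactly — the standard control for baseline variation at collection time —
and sharpens overlapping bands. Savitzky–Golay filters of order ≥ 2 are
exact on quadratics, which the tests exploit: affine rows map to 0 and
`w^2` maps to the constant 2. Edge points are filled with the edge
polynomial fits, so the axis length never changes. Because CO~2~ excision
runs first and leaves a gap in an otherwise uniform axis, the filter is
applied independently to each contiguous uniformly spaced axis segment;
filtering across the gap would mix non-adjacent wavenumbers. Truly
non-uniform axes are rejected.

# PCA and clustering

`fit_pca()` mean-centers the spectra (no variance scaling: absorbance
channels share units, and unit-variance scaling would inflate noise-only
wavenumbers) and eigendecomposes the sample covariance via SVD. Loadings
are *eigen-spectra* — unit-norm spectral modes directly interpretable over
the wavenumber axis. Each eigen-spectrum's sign is fixed so its
largest-magnitude entry is positive, making results reproducible across
eigensolvers; explained-variance ratios are fractions of total centered
variance and `cumulative_variance()` gives the usual component-selection
curve. `project()` maps any spectra on the same axis into the fitted basis.

`cluster_pixels()` operates on PCA scores (default 15 components), not raw
spectra: a k-nearest-neighbour graph (Euclidean, directed edges symmetrized
by union, unweighted — the simplest deterministic choice) is partitioned by
the Leiden algorithm under the modularity objective at a tunable resolution.
Labels are relabelled so cluster 0 is the largest; the optional 2-D
embedding is a seeded force-directed layout of the same graph, attached for
visualization only and never used for clustering, so no test asserts on its
coordinates beyond determinism.

A property worth understanding before trusting cluster counts: modularity
optimization at resolution 1 *genuinely favours* subdividing large,
internally homogeneous regions — on the package's synthetic scene the kNN
graph separates the three regions into exactly three connected components
for every seed tested, yet alternative draws of the Leiden refinement
randomness can split a ~330-pixel homogeneous region into two or three
sub-communities with slightly higher modularity. The region-recovery
contract (ARI ≥ 0.9 against ground truth) is therefore calibrated and
checked at the package's documented defaults (default scene, clustering
seed 0), where recovery is exact. On real data, treat the cluster count as
resolution-dependent and inspect cluster mean spectra before interpreting
fine splits.

# Quantification

`integrate_band()` applies the trapezoid rule over the native axis points
inside a closed window; with `baseline = "linear_endpoints"` the chord
joining the window endpoints is subtracted first. Trapezoid quadrature on a
band cut at finite bounds converges at O(h^2^) in the axis spacing h;
on a full Gaussian band integrated over a wide window it is accurate far
beyond any spectroscopic need (the tests verify 0.5% against the analytic
area and the O(h^2^) rate against a truncated-window analytic value).

`adjust_window()` implements peak-shift-aware window selection: it locates
the maximum of the *map-mean* spectrum within a search radius of the nominal
band position and recenters the window there. The map mean, not a per-pixel
argmax, is used deliberately — window selection is a per-dataset inspection
step, and per-pixel windows would change the estimand. Exact ties resolve
toward the nominal center, then toward the lower wavenumber; windows are
clipped to the axis.

**Secondary structure.** Protein backbone conformation shifts the amide I
band: α-helix absorbs near 1654 cm^-1^, β-sheet near 1630 and
1670–1695 cm^-1^, turns near 1660–1670 cm^-1^. Per pixel, the chord
baseline anchored at the full amide I window endpoints (1600 and
1700 cm^-1^) is subtracted, each class's assignment windows (α-helix
1648–1660; β-sheet 1620–1640 and 1670–1695; turns 1660–1670; other
1640–1648 cm^-1^ — standard literature assignments, fully overridable via
`structure_coefficients()` or a YAML table) are integrated, negative areas
are clamped to zero, and areas are normalized to fractions summing to 1.
There is deliberately *no* curve fitting or spectral decomposition; the
estimates are transparent band-area ratios and should be read as relative
composition indicators, not absolute structure content. Pixels with zero
total amide I area get `NA` fractions and an `undefined` flag. Fractions
are invariant to overall spectrum scaling. Note the method resolves
structure classes only to the extent that amide I components are narrow
relative to the 8–25 cm^-1^ assignment windows — appropriate for
second-derivative-sharpened or narrow-component spectra; heavily overlapped
broad components will smear across neighbouring classes.

# Spatial reconstruction

`repopulate()` and `to_grid()` are pure index bookkeeping: retained values
return to their original raster positions, excluded positions become `NA`,
and the grid fills row-major from the top-left with x varying fastest — a
declared convention (stated in `grid_spec`) rather than an inferred one,
since instruments differ. `map_band()` and `map_clusters()` chain
quantification, repopulation and gridding, and can write a PNG plus a
tab-delimited sidecar of exact values (missing as `NA`) so every rendered
map is machine-checkable bit-exactly. Missing positions render magenta, a
reserved colour outside both the scalar colormap and the cluster palette.

# The synthetic scene generator

Because the package must be testable without downloads, `make_default_scene()`
generates ground-truthed scenes emulating an FPA tissue map: a 32×32 grid
split into three contiguous vertical region classes with distinct Gaussian
band signatures (protein-rich: amide I 1654 + amide II 1545; lipid-rich:
2920 + 2850 CH~2~ stretches plus moderate amide bands; nucleic-acid-rich:
1080 + 1240 phosphate bands plus moderate amide bands — every class carries
amide bands because real tissue is never protein-free), ~2% empty holes,
~2% scattering pixels with a steep positive baseline upslope anchored at
the axis minimum (the Mie-type phenomenology: flagged by slope, with the
spectrum staying positive), mild per-pixel affine baselines (intercept
U(0.01, 0.03), slope U(−4·10^-6^, 4·10^-6^) absorbance/cm^-1^, chosen so
the baseline never goes negative across the 950–3100 cm^-1^ axis — tissue
absorbance baselines drift but stay positive), and independent Gaussian
channel noise (sd 0.005 absorbance, a realistic high-quality FPA noise
floor against band amplitudes of 0.25–1). The default axis is
950–3100 cm^-1^ at 2 cm^-1^ spacing. Everything is drawn from a
generator seeded per scene, so scenes and rendered maps are bitwise
reproducible. `make_sample_set()` renders case/control sets in which case
samples carry an amide I position shifted 12 cm^-1^ toward the β-sheet
region — the classic misfolded-deposit signature.

What the scene does *not* emulate: resonant-Mie ripple line shapes,
water-vapour rotational structure, detector drift within an acquisition,
spatially correlated noise, and within-region chemical gradients. Passing
tests therefore demonstrate the pipeline's bookkeeping, numerics and
recovery behaviour under clean, well-separated conditions; they do not
certify clustering performance on real tissue, where region boundaries are
gradual and class separations far smaller.

# Numerical choices and problem sizes

All floating-point artifacts are written with 15 significant digits
(read/write round trips reproduce absorbances to better than 10^-12^
relative); re-running a pipeline with an identical configuration reproduces
every delimited-text artifact bitwise. Test and pipeline problem sizes
(32×32 scenes, 12×12 multi-sample sets, 20×10 PCA oracles) are chosen as
the smallest sizes at which every contract is exercised meaningfully —
desk-scale by design, since every property asserted is size-independent.
The kNN graph is built from a dense distance matrix, which is the right
tool up to a few tens of thousands of pixels; beyond that an approximate
neighbour search would be the natural extension point.
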