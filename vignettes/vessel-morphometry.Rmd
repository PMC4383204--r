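---
title: "Quantifying neointimal disease in 3D: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neointimal disease in 3D: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cav3d)
```

## The measurement problem

Chronic allograft vasculopathy (CAV) narrows the coronary arteries of
transplanted hearts by neointimal proliferation. In mouse transplant models
the standard readout is the **Neointimal Index**,

$$\mathrm{NI} = 100 \cdot \frac{A_\mathrm{neointima}}
        {A_\mathrm{neointima} + A_\mathrm{lumen}},$$

measured on a single histological cross-section. Mouse coronaries are about
0.1 mm wide and impossible to orient by eye during embedding, so real
sections cut the vessel obliquely. For a *straight* vessel an oblique cut
scales the lumen and the wall areas by the same factor $1/\cos\theta$ and
NI survives; an oblique cut through a *curved* vessel does not enjoy this
cancellation, and a cut that runs tangential to the wall can produce almost
arbitrary NI values. The linear wall thickness is worse still: it grows as
$t/\cos\theta$ for any vessel.

This package implements the 3-D remedy: reconstruct the vessel from serial
sections, re-slice it *perpendicular to its own axis*, and integrate over
the segment to obtain the **Neointimal Volume Index**,

$$\mathrm{NVI} = 100 \cdot \frac{V_\mathrm{neointima}}
        {V_\mathrm{neointima} + V_\mathrm{lumen}},$$

which does not depend on how any individual section was oriented.

## Pipeline and the model behind each stage

The pipeline is `phantom/input → align → assemble → label → centerline →
perpendicular re-slice → morphometry`. Each stage is an exported function;
`run_pipeline()` chains them under one seeded configuration.

### Serial-section geometry

A stack is an ordered list of 2-D images with an in-plane pixel size
(default 0.369 µm/pixel, the resolution of a 20x whole-slide scan) and a
section thickness (default 4 µm). Assembly is pure restacking: voxel
spacing becomes `(4, 0.369, 0.369)` µm, roughly 10:1 anisotropic, and all
later geometry is computed in physical micrometers so this anisotropy is
handled uniformly. Indices are `(z, y, x)` with z the cutting order, and
all physical coordinates refer to voxel centers.

### Rigid stack registration

Sections land on slides with random in-plane translation and rotation. The
model is deliberately **rigid-only**: automated sectioning keeps stretching
artifacts approximately uniform between neighboring sections, so an
elastic model would mostly fit noise. `align_pair()` searches a rotation
grid (≤ 0.25°) scored by Hann-windowed, normalized spectral
cross-correlation, then iteratively refines: the moving image is resampled
under the current estimate and the *residual* translation (by local DFT
zoom of the correlation surface, 0.05 px grid) and residual rotation (by a
shrinking three-point parabola) are measured near identity, where window-
and interpolation-induced biases cancel. A single-pass estimate carries a
systematic error of a few tenths of a pixel; re-measuring the residual
removes it, which matters because `align_stack()` chains pairwise
transforms outward from a reference section (default: the middle one) and
per-pair errors accumulate as a random walk along the chain. Exhaustive
grid plus refinement is deterministic — there is no optimizer
initialization to be sensitive to.

### Seeded three-class segmentation

Labels (background 0, lumen 1, neointima 2) are propagated from manual
seeds by a minimal-cost geodesic on the 6-connected voxel graph. The step
cost between neighbors $u, v$ at physical distance $h$ µm is

$$w(u,v) = \varepsilon h \;+\; \lVert I(u) - I(v)\rVert_2^2
         \;+\; \beta\,\bar g_{uv}\, h,$$

with $I$ the (possibly multichannel) intensity of a box-smoothed copy of
the volume (window 3 voxels by default), $\bar g$ the mean per-µm gradient
magnitude at the two voxels, $\beta \ge 0$ the gradient sensitivity
(default 1, exposed because no canonical value exists), and
$\varepsilon = 10^{-6}$ a distance term that reduces the whole cost to
physical distance on constant volumes. Design notes:

* the **squared** intensity difference makes one sharp class boundary far
  costlier than the same contrast spread over many small noisy steps, so
  labels do not leak across boundaries in noisy data;
* the *smoothing* suppresses the voxel-noise contribution to both terms,
  while the gradient penalty keeps the (smeared) boundary expensive;
* edge lengths are physical, so a 4 µm z-step costs ~10x an in-plane step,
  matching the data's anisotropy;
* equal-cost ties resolve to the lowest class code — the result is fully
  deterministic.

This cost was chosen because it is directly checkable: on volumes up to
8×8×8 the labeling is compared against an exhaustive per-class
shortest-path computation written independently in plain R, and the suite
runs 100 random instances of that comparison. A random-walker formulation
would satisfy the same interface but has no such simple oracle.

### Centerline and perpendicular re-slicing

The vessel axis is traced from per-slice lumen centroids (physical
coordinates), smoothed with a centered moving average (default 5 sections),
with tangents by central differences. Per-slice centroids were preferred
over 3-D skeletonization because they respect the per-section nature of the
data and are robust to the 10:1 spacing anisotropy; the price is a validity
limit: when the local axis leans more than ~50° away from the stack normal,
slice footprints become long tangential ovals and the centroid drifts off
axis. Analyses should therefore be confined to segments whose axis stays
within that cone, and the flat cut ends of a specimen bias the first and
last ~1 outer radius of the track, which the bundled experiments exclude
from their measurement windows. Branch points are refused outright
(`extract_centerline()` errors on multiple lumen components per slice):
analysis is per unbranched segment, orifice to bifurcation.

Cross-section planes are resampled with a deterministic in-plane frame
(least-parallel coordinate axis, Gram–Schmidt, right-handed completion),
trilinear interpolation for intensities and nearest-neighbor for labels so
label images stay in `{0, 1, 2}` and areas remain countable. Perpendicular
sampling may interpolate *between* physical sections; that is precisely the
point of virtual re-sectioning. `perpendicular_series()` emits
`floor(L / step) + 1` sections at arclength steps of `step` µm.

### Morphometry

Areas are pixel counts times the pixel area, with no subpixel boundary
fitting — deliberately, so per-section NI and volumetric NVI are the same
kind of measure and agree exactly on constant-profile segments. NVI is
reported at 3 decimals in tables (full precision retained in memory). The
proximal/distal comparison splits the series at the arclength midpoint by
default and uses a paired t-test (`stats::t.test`) per part. The apparent
wall thickness measurement (`radial_wall_width()`) casts rays from the
lumen centroid and accumulates the neointima crossed per direction — the
caliper-style measurement whose $1/\cos\theta$ inflation motivates
area-based indices in the first place.

### Virtual angiography

The computational content of autofluorescence angiography is channel
arithmetic: a voxelwise weighted sum (negative weights = digital
subtraction), suppression below a threshold, and maximum intensity
projection, axis-aligned or along an arbitrary direction via plane
resampling. Spectral hardware settings are metadata, not computation, and
are not modeled.

## The phantom: what it emulates, what it does not

`vessel_spec()` + `generate_vessel_volume()` build annular vessels —
straight or circular-arc centerlines, constant or varying lumen radius —
with exact voxel-center membership (no partial-volume anti-aliasing), so
label volumes are exact set-theoretic objects with closed-form volumes:
$\pi r^2 L$ per class integral for straight tubes and, by Pappus' theorem,
the same arclength integral for arcs. Axial membership is half-open
`[0, L)` so stacked segments tile without double-counting, and a straight
vessel may run through the whole block, which avoids artificial flat end
caps inside the volume. Voxel intensities are class constants plus two
optional stochastic components:

* `noise_sd`: i.i.d. per-voxel Gaussian noise — scanner noise;
* `texture_sd` / `texture_scale_um`: a stationary band-limited Gaussian
  field (box-smoothed white noise, standardized), with per-axis correlation
  lengths — tissue microstructure. Real myocardium is fibrous, with
  myocyte and collagen bundles tens of micrometers long, so the
  registration experiments use anisotropic scales `(40, 6, 6)` µm: the
  texture continues across neighboring 4 µm sections, which is exactly the
  signal real section-to-section alignment locks onto. With `texture_sd =
  0` consecutive phantom sections share only the (nearly rotation
  symmetric) vessel rings, and no algorithm could recover per-section
  rotations from them.

`sectioning_spec()` + `section_volume()` simulate the microtome: resampling
on planes perpendicular to a cutting axis tilted `tilt_deg` from the vessel
axis at the origin (`tilt_azimuth_deg` picks the in-plane direction; 180°
tilts *away* from an arc's curving direction, which drives the cutting
plane through tangency — the falsely-elevated-NI scenario), one section per
thickness step, then a per-section random rigid perturbation whose exact
inverses are returned as registration ground truth. One RNG stream per
stack, seeded explicitly, drawn in section order.

Not emulated: branching trees, non-circular lumens, staining color,
tears/folds/stretching. Consequently a passing suite demonstrates
*geometric* correctness of reconstruction and morphometry, and noise/
texture robustness of registration and segmentation — not robustness to
sectioning damage or staining variability in real slides.

## Numerical choices and degenerate inputs

* Resampling outside a volume or image reads as 0 (background); labels
  resample strictly nearest-neighbor everywhere.
* The frame construction switches its seed axis when the normal crosses a
  45° diagonal; frames are orthonormal everywhere but not continuous at the
  switch. NI/NVI are frame-invariant, so this only matters if cross-section
  images are compared pixelwise across such a switch.
* `align_pair()` requires non-constant images and reports "no registration
  signal" otherwise; `compare_series()` returns `t = 0, p = 1` for
  zero-variance differences instead of NaN.
* NI with zero total vessel area and NVI of an all-background volume are
  errors, not NaN; an all-lumen segment gives NVI 0.
* Time-bounded study sizes: the bundled experiments use 1 µm isotropic
  phantoms of roughly 100–320 voxels per axis, 20–30-section stacks at
  0.5–1 µm pixels, and a 100-instance oracle sweep at ≤ 8×8×8 — small
  enough for a laptop core within minutes, large enough that discretization
  errors sit well below the tolerances they are tested against.

## Known limitations

* Chained pairwise registration accumulates a random walk of per-pair
  errors; for stacks much longer than the tens of sections used here a
  groupwise or anchor-based scheme would be preferable.
* The centroid centerline fails beyond ~50° axis obliquity and at branch
  points; tangential re-slicing near specimen ends needs an exclusion
  window (one outer radius is used throughout).
* The segmentation cost is a model of "gradients and intensities", chosen
  for determinism and testability; no claim is made that it reproduces any
  proprietary segmentation tool voxel-for-voxel.
* Oblique-plane resampling treats sections as perfectly registered slabs;
  within-section depth structure (the 4 µm of tissue per slide) is not
  modeled.

## A worked miniature

```{r example}
spec <- vessel_spec("straight", length_um = 95, outer_radius_um = 50,
                    lumen_radius_um = 25)
g <- generate_vessel_volume(spec, spacing = c(1, 1, 1),
                            extent = c(100, 110, 110))
analytic_ni(spec, 0.5)          # exact geometry: 75
nvi(g$labels)$nvi               # voxel counting on the same geometry
cl <- extract_centerline(g$labels)
ser <- perpendicular_series(NULL, g$labels, cl, step = 8,
                            size = 130, pixel_size = 1)
range(vapply(ser, function(e) ni_from_label_section(e$labels)$ni,
             numeric(1)))
```
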