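---
title: "Label-free in-flow enumeration of large circulating cells: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free in-flow enumeration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vortexcount)
```

## The problem

Circulating tumor cells (CTCs) are rare tumor-derived cells in peripheral
blood, typically much larger than leukocytes. After microfluidic vortex
trapping concentrates the large-cell fraction, the trapped cells are released
past a brightfield imaging window and recorded by a high-speed camera
(nominally 256 × 376 px at 6006 frames/s for 15 s). `vortexcount`
implements the downstream computation: find the transiting objects in the
video, measure their morphology, keep the ones that look like large intact
cells, count each physical cell once even though it appears in several
frames, convert to a per-mL rate, and call samples positive against a
healthy-donor background. Companion rule classifiers cover the
marker-based ground truths used to validate such label-free counts:
immunofluorescence CK/CD45/DAPI calls and ALK break-apart FISH patterns.

## Detection chain

For each frame the pipeline computes, in order:

1. **Background subtraction.** An empty reference frame is subtracted from
   every subsequent frame; the absolute difference is used, so objects darker
   than background (the usual brightfield absorption contrast) and brighter
   ones both leave positive traces, and the arithmetic is done in doubles so
   integer pixel types cannot wrap around. The default reference is the
   first frame — flow is stopped before recording starts, so frame 0 is
   empty — with a per-pixel median across a frame subsample available as a
   robust alternative.
2. **×3 upscaling with bilinear interpolation,** which refines the boundary
   before binarization.
3. **Binarization** at `binarize_k × σ̂` (default k = 4), where σ̂ is a
   robust noise scale: the median of the absolute background residuals,
   pooled over a few frames, divided by 0.6745 (the half-normal median).
   The robust estimator matters because frames containing cells would
   inflate a standard-deviation estimate; the median is unaffected by the
   small cell footprint. Note σ̂ is the noise of the *difference* image, √2
   times the per-frame sensor noise when the reference frame carries noise
   of its own.
4. **Morphological closing** (dilation then erosion) with a disc structuring
   element, radius 5 upscaled px by default, which fills the thin or broken
   traces left by low-contrast cell interiors.
5. **8-connected component labeling,** with components below `min_area`
   (default: the upscaled-pixel area of a 6 μm disk) discarded as noise
   specks.

Whether binarization should precede or follow upscaling is ambiguous in
workflows of this kind; we scale first, matching the order of the listed
processing steps, and the choice is configurable only through the scale
factor (`scale_factor = 1` disables upscaling).

### Morphometric features

Each component is measured in physical units using the pixel pitch `p` at
the sample plane and the scale factor `s`:

- **area** = pixel count × (p/s)², in μm²;
- **equivalent diameter** = 2·√(area/π) — "diameter" alone is ambiguous
  for irregular objects, so the equal-area circle convention is fixed here
  to make gates reproducible;
- **solidity** = component pixel count / convex-hull pixel count, the hull
  being computed on pixel centres; ≈1 for convex cells, low for jagged
  debris;
- **axial ratio** = √(λ₁/λ₂) of the second-moment (covariance) matrix of
  pixel coordinates, i.e. major/minor axis of the moment-equivalent
  ellipse. A 1/12-px² variance term (the variance of a unit pixel) keeps
  single-pixel and single-row components finite; a 1-px component is
  defined to have solidity 1 and axial ratio 1;
- **intensity range** = max − min of the *raw original-resolution* pixels
  inside the down-mapped component footprint. The published gate
  (0–20,000 counts) implies a 16-bit-scale spread statistic; max − min is
  our documented reading of "interior pixel intensity distribution", and it
  is computed before interpolation so resampling cannot distort it.

Components touching the frame edge are kept but flagged, so downstream
analyses can drop partially visible objects if desired.

### Physical calibration

The pixel pitch at the sample plane is not part of the published recording
parameters (a 10× objective with 8.5 μm depth of focus is), so the default
of **2.8 μm/px** is a documented, user-overridable calibration guess chosen
to make the 256 × 376 px window ≈ 0.7 × 1.05 mm, a plausible field of view
for a 10× objective on a high-speed sensor. Every physical-unit feature
scales with it; users with a calibration target should set `pixel_pitch`
in the `io` config section.

## Gating

The published accept ranges, trained on A549 lung-carcinoma cells imaged
in flow, are the defaults: diameter strictly between 12 and 55 μm
(exclusive bounds, following "greater than 12 μm and less than 55 μm"),
solidity in [0.7, 1], axial ratio in [1, 1.8], intensity range in
[0, 20000] counts. The gates are applied in the order diameter → solidity →
axial ratio → intensity; order affects only the per-gate rejection tallies
(which `cmd_count()` logs), never the surviving set, since the gates are
independent interval tests.

## Deduplication

The system is operated so each released cell appears ~6 times in the
window; raw gated detections therefore overcount ≈6-fold. How the original
analysis collapsed this multiplicity is not described, so both obvious
estimators are provided:

- **Tracking (default).** Greedy nearest-neighbour frame-to-frame linking:
  each open track predicts its next position (last position + last
  velocity, zero for singletons) and claims the nearest unclaimed detection
  within `max_displacement`, claims resolved in ascending
  (distance, track id) order for determinism; unclaimed detections open new
  tracks; tracks idle beyond `max_frame_gap` (default 1, i.e. consecutive
  frames only) close. The `max_displacement` default, frame width / 6
  appearances × 1.5 ≈ 94 px, encodes the transit geometry.
- **Division fallback.** `count_by_division()` divides raw gated detections
  by the nominal appearance count and rounds; exposed for cross-checks.

No Kalman filtering or appearance re-identification is attempted: at ~60 px
inter-frame displacement and the low concurrency of released cells, the
constant-velocity greedy linker is exact on well-separated scenes, which
tests verify against ground truth.

## Rates, thresholds and cohort calls

A sample's rate is unique tracks / blood volume (cells/mL). The healthy
threshold is **mean + 2·SD** of healthy-donor rates; the sample SD (n−1
denominator) is used, since the denominator is not specified where the
thresholds are printed. Positivity is a **strict** comparison
(rate > threshold), the convention consistent with a sample at 7.63 cells/mL
being "above" a 3.15 threshold and one at 7.25 being "below" 7.7. The
published thresholds themselves (3.15 automated, 7.7 well-plate, 1.46
immunofluorescence, all cells/mL) are exposed as presets because the
individual healthy-donor rates behind them are not available as raw
values and cannot be recomputed. Spike-in concordance is summarised by a
through-origin least-squares slope (Σxy/Σx²) paired with the squared
Pearson correlation — R² is reported alongside a through-origin fit in the
source workflow without a definition, so the squared correlation of the
pairs is fixed here as the documented meaning.

## Rule classifiers

**Immunofluorescence.** The written enumeration criteria become a
precedence cascade: jagged/irregular morphology → debris; CD45+ → WBC
(including CK+/CD45+ doubly stained granulocytes); CK+/CD45− → CTC;
DAPI-only cells are CTCs only with a large (>9 μm) nucleus and large
nuclear-to-cytoplasmic ratio (≥0.5 by default — "large N:C" has no printed
number, so the cutoff is exposed in config) and a non-lobular nucleus;
anucleate non-flagged objects are debris. Reader-level nuances of manual
classification (e.g. cytoplasm texture) are intentionally out of scope.

**Break-apart FISH.** Red and green spots are paired greedily by ascending
pairwise distance (deterministic, index tie-breaks); pairs within
`fusion_distance` are fused (yellow) copies, and pairs beyond it — plus
unpaired spots of either colour — each count as one rearrangement-consistent
split copy. Isolated single red or green spots counting as split signals is
our reading of the "many variations of the signal pattern" seen in
rearranged nuclei. Any split copy makes a nucleus positive
(positive-with-polysomy at ≥3 total copies); otherwise 2 fused copies are
negative and ≥3 are negative polysomy; ≤1 resolvable copy is
uninterpretable. Greedy ascending pairing equals the matching whose sorted
distance vector is lexicographically minimal, which tests verify against
exhaustive enumeration of all pairings with ≤4 spots per colour. The
sample-level call uses the conventional 15% rearranged-fraction cutoff,
inclusive, over interpretable nuclei only.

## The synthetic-video generator

`generate()` renders ground-truthed recordings that emulate the release
phase: each object enters the window and transits along the column (flow)
axis at constant velocity chosen so it is visible in exactly
`appearances_per_cell` frames (default 6) — appearances are the controlled
quantity, velocity follows. Objects are scheduled in waves, one row lane
per object with lanes at least `min_separation` apart (default 2× the
largest diameter) and consecutive waves never co-visible, so ground-truth
association is unambiguous. Frame 0 is always empty to serve as the
background model.

- **Cells** are anti-aliased ellipses, darker than background by
  `cell_contrast` (default 60 counts on a 1000-count background),
  lightly blurred (σ = 0.6 px). The default diameter range 15–30 μm
  emulates A549 cells, comfortably inside the gate; the axial-ratio range
  1–1.4 stays inside [1, 1.8] even after measurement noise.
- **Debris** is rendered as sharp random star polygons (4–5 spikes, inner
  radius 25–35% of outer, outer diameter 35–50 μm), which measure below
  0.7 solidity by construction even after morphological closing.
- **Small cells** (7–10 μm) fall below the 12 μm gate.
- **Noise** is i.i.d. Gaussian (σ = 5 counts by default), truncated at
  ±3.5σ: real sensor noise at these exposure times is tightly bounded, and
  the truncation prevents isolated hot pixels from masquerading as
  particles in fixtures meant to be object-free.

The generator does *not* model diffraction, defocus gradients, cell
deformation, illumination drift, or the real release-flow velocity profile
(constant-velocity transit is an idealization). Passing end-to-end tests
on synthetic stacks therefore demonstrates the correctness of the
measurement and counting logic under the stated geometry, not robustness
to the full optical variability of patient recordings.

## Problem sizes and runtime choices

Validation fixtures use short stacks (tens to hundreds of frames at
256 × 376 px) rather than the full 15 s × 6006 fps ≈ 90,000 frames of a
real recording: the enumeration logic is independent of stack length, and
the synthetic spike-in series (true counts 10, 25, 50, 100, 200, 400, 600,
~6 appearances per cell, well-separated) already exercises ~8,300
rendered appearances across ~900 frames. On this series the full
detect → gate → track pipeline recovers every spiked count exactly,
giving a through-origin slope of 1.00 and R² of 1.00 against truth,
within the ±0.05 band around the published unity relationship (y = 1.02x,
R² = 0.97) that the acceptance script checks.

## Known limitations

- Physical-unit features inherit the uncertainty of the default pixel
  pitch; calibrate `pixel_pitch` for absolute sizes.
- The tracker assumes approximately constant velocity and modest density;
  occlusions or crossing trajectories can merge or split tracks. The
  division estimator is the cross-check.
- Solidity uses pixel-centre convex hulls; for components of only a few
  pixels the discretization error is larger, which the 6 μm `min_area`
  guard mostly hides.
- The FISH classifier consumes spot tables; spot detection from raw
  fluorescence images is out of scope, as are clinical decision thresholds
  beyond the printed 15%.
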