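---
title: "Detecting cortical interruptions and their trabecular void volume"
author: "cortigap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cortical interruptions and their trabecular void volume}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortigap)
```

## The problem

In early rheumatoid arthritis, inflammation at the joint erodes the thin
cortical shell of the metacarpal heads and phalangeal bases. On HR-pQCT
(high-resolution peripheral quantitative CT, 82 µm isotropic voxels) these
erosions appear as *cortical interruptions* — gaps in the cortex — usually
with an abnormal cavity (*trabecular void*) in the marrow space beneath
them. Counting and measuring these lesions by eye is slow and only
reliable for large defects; `cortigap` implements a semi-automated 3D
pipeline that finds interruptions down to 0.41 mm diameter, attaches the
underlying void volume, and supplies the reproducibility statistics
(ICC, RMS precision, least significant change) needed to interpret
longitudinal change.

## The detection model

The pipeline consumes a grayscale volume with isotropic voxel size
(0.082 mm by default; everything below is stated at that size) and
proceeds in two stages.

**Stage 1 — interruptions.** The volume is binarized
(Hamming-window low-pass + Laplacian edge enhancement + fixed-fraction
threshold), a filled periosteal contour is computed by ball-closing and
hole-filling the bone mask (operator-corrected contours can be loaded in
its place), and a cortical mask of constant depth 4 voxels (0.328 mm) is
peeled off the contour surface. Non-bone components inside this peel are
interruption candidates. A candidate is accepted when

1. it *spans* the peel — it has voxels adjacent both to the outside of the
   contour (periosteal face) and to the eroded interior (endosteal face);
   a gap breaching only one face is cortical porosity, reported separately
   by the morphometry module and never double-counted; and
2. its maximum inscribed-sphere diameter is ≥ 0.41 mm.

The diameter is `2 · (max EDT − 0.5)` voxels, where the Euclidean
distance transform (EDT) measures distance to the nearest *bone* voxel.
Measured against bone (rather than within the 4-voxel peel) the statistic
captures the true opening width of a gap; a transform confined to the
peel could never exceed the peel depth, and no gap could pass the 0.41 mm
cut. The −0.5 half-voxel term places the sphere boundary on the voxel
boundary rather than its centre, so an *n*-voxel slab measures exactly
*n* voxels; the same convention is used everywhere a diameter or
thickness is computed.

**Stage 2 — void extension.** For each joint:

* a region of interest is grown by dilating the interruption voxels with
  a Euclidean ball of 48 voxels (3.936 mm, about half a metacarpal-head
  width) and clipping to the contour — this bounds void search depth and
  keeps the intramedullary canal out;
* marrow space in the ROI with local thickness ≥ 0.738 mm is selected as
  void (equivalently: the morphological opening by a ball of half that
  diameter). The cut sits above the trabecular separation seen in healthy
  MCP joints, so normal marrow spacing is never selected;
* the selection is eroded by 2 voxels, severing connections ≤ 0.328 mm so
  voids cannot leak into the trabecular network;
* only eroded components overlapping or 26-adjacent to an interruption
  survive;
* survivors are restored by *geodesic* dilation — `erode_voxels`
  iterations of a unit-neighbourhood dilation, each clipped to the
  pre-erosion mask — and the interruption voxels are added. Constrained
  reconstruction is essential: a free dilation would regrow exactly the
  thin necks the erosion removed. An isolated cavity is restored to its
  original extent exactly (this is asserted in the test suite).

Per joint the pipeline reports the number of interruptions, their surface
(voxel volume divided by peel depth — a volumetric surrogate for the
through-cortex cross-section, chosen because mesh areas are unstable on
4-voxel-thin structures) and the total interruption + void volume. A
final component containing several interruptions is counted once, with
the member ids cross-referenced, so volume is conserved.

## Parameters that matter

| parameter | default | units | meaning |
|---|---|---|---|
| `mask_depth_voxels` | 4 | voxels | cortical peel depth (0.328 mm) |
| `min_diameter_mm` | 0.41 | mm | interruption diameter threshold |
| `roi_radius_voxels` | 48 | voxels | void search radius (3.936 mm) |
| `void_min_diameter_mm` | 0.738 | mm | trabecular void diameter threshold |
| `erode_voxels` | 2 | voxels | anti-leak erosion radius |
| `threshold_fraction` | 0.4 | – | binarization threshold (fraction of filtered range) |
| `hamming_cutoff` | 0.8 | fraction of Nyquist | low-pass cutoff |
| `laplace_weight` | 0.5 | – | edge-enhancement blend |
| `closing_radius_mm` | 2.5 | mm | periosteal closing ball |

The first five are the method's published operating point and are echoed
into every output. The filter coefficients are surrogates: the scanner
protocol's exact Laplace–Hamming coefficients are proprietary, so the
shape (Hamming-window low-pass blended with a discrete Laplacian) is
reproduced with exposed parameters; with `hamming_cutoff = 1` and
`laplace_weight = 0` the stage degenerates to plain thresholding. The
2.5 mm closing bridges defects up to ~5 mm; larger ones require an
operator-corrected contour, mirroring clinical practice. Structuring
elements are digitized Euclidean balls obtained by thresholding the
distance transform — 48 iterations of a cross-shaped element would yield
an octahedron, not the intended 4 mm sphere. Foreground connectivity is
26-neighbour and background 6-neighbour throughout, the standard
complementary pair.

## Morphometry surrogates

`morphometry()` provides distance-transform versions of the standard
structural endpoints: BV/TV (exact voxel fractions), Tb.Th / Tb.Sp /
Tb.SpSD (mean/SD local thickness of trabecular bone and marrow), Tb.N
(plate-model `1/(Tb.Th + Tb.Sp)`, flagged as such in the output), Ct.Th,
Ct.Po and Ct.Po.Dm. Two deliberate design choices:

* **Ct.Th** averages the local thickness of the *full* bone structure
  over the peel voxels. Thickness measured inside the 4-voxel peel alone
  is structurally capped at 0.33 mm and could never read a normal
  0.8 mm cortex.
* The **trabecular compartment** is the contour eroded by the estimated
  cortical thickness (plus one voxel), not merely by the peel depth — an
  endosteal surrogate for inner-contour protocols; eroding by the peel
  alone leaves the inner cortex inside the "trabecular" region and
  inflates Tb.Th.

Calibrated volumetric BMD (mg HA/cm³) is *not* computed: it requires a
scanner density calibration that synthetic data cannot supply. BV/TV and
mean attenuation stand in so the precision machinery can be exercised on
density-like endpoints.

## Precision statistics

`precision_report()` bundles the standard densitometry agreement toolkit for paired
scan/re-scan (or operator/operator) measurements: single-measure ICC(2,1)
(two-way random effects, absolute agreement — individual measurements are
compared, not rater means) with the McGraw–Wong F-based 95% CI; Glüer
RMS precision errors (`SD_j = |x1−x2|/√2`, `CV_j = 100·SD_j/mean_j`,
root-mean-squared over subjects); the least significant change
`LSC = 1.96·√2·RMS`; Bland–Altman limits; and the paired t-test
(`stats::t.test`). Ratings use the bands poor < 0.40 ≤ fair < 0.60 ≤
good < 0.75 ≤ excellent, with boundary values assigned upward (the source
bands overlap at the boundaries; upward assignment is the documented
tie-break). CV-based quantities are reported `n.a.` when a subject mean
is zero, as for count outcomes. `apply_exclusions()` implements the
stack-quality rule: a stack is dropped when its motion grade exceeds 3 on
either scan (union counting), and a joint is dropped when all its stacks
are. Rows are treated as independent subjects; joints from the same
patient are not modelled as clustered, a caveat inherited from the usual
study design.

## The synthetic phantom

`make_joint_phantom()` builds the ground-truth test object every stage is
validated against: a spherical cortical shell (0.8 mm, matching the
reported mean Ct.Th of ~0.89 mm) filled with a cubic rod lattice (rods
0.2 mm, pitch 0.6 mm — the maximal marrow inscribed diameter is then
√2·0.6 − 0.2 ≈ 0.65 mm, deliberately *below* the 0.738 mm void cut so
healthy marrow is never selected), imaged at two gray levels (bone 1000,
marrow 0) with Gaussian blur (σ 0.05 mm) and additive Gaussian noise
(σ 50, i.e. 5% of the bone level). Defects are radial cylindrical
channels over spherical cavities placed tangent to the periosteal
surface — the geometry of a real erosion cavity, which also guarantees
channel–void connectivity by construction. When defects exist and space
allows, an unconnected 1 mm³ decoy cavity is carved at the joint centre
so the connectivity filter is exercised negatively as well.
`rescan_variant()` emulates repositioning: an integer-voxel rigid shift
(≤ 3 voxels) of the noise-free volume plus a fresh noise realization.

The default object is 112³ voxels (outer radius 3.84 mm ≈ a
metacarpal-head half-width); validation suites use 56–96³ variants, and
the end-to-end reproducibility exercise runs 40 scan/re-scan pairs at
80³. What the phantom does *not* emulate: CT physics (beam hardening,
streaks), motion artifacts realistic enough for visual grading, true
trabecular plate/rod mixtures, and density calibration. Passing tests
therefore demonstrate geometric and statistical correctness of the
algorithm, not clinical equivalence on scanner data.

## Numerical choices and degenerate inputs

* The separable EDT (Felzenszwalb–Huttenlocher) is exact in squared
  voxel units; it is compared against brute force in the tests.
* Space beyond the volume border is treated as foreground — correct for
  anatomy cut by the stack boundary; components touching the axial
  boundary are flagged `truncated`. The periosteal closing is the one
  operation computed in padded space, so its dilation is never clipped.
* Local thickness uses descending-radius sphere painting; equality with
  the brute-force inscribed-sphere search is asserted on ≤ 32³ volumes.
* Digitization of curved surfaces biases thickness readings ~10% low
  (half-voxel convention plus curvature); slab geometries are exact.
  Spherical-shell peel volumes land within ~6% of the continuous-shell
  formula. Test tolerances state these measured biases explicitly.
* Degenerate inputs fail loudly: constant volumes ("no dynamic range"),
  empty masks, peel depths that consume the object, zero difference
  variance in the paired t, zero total variance in the ICC.
* Phantom generation and the re-scan are the only random components; both
  take explicit seeds, restore the caller's RNG state, and are
  bit-reproducible.

## Known limitations

Interruptions are not matched across scans — precision is assessed on
per-joint totals, so a lesion lost and a lesion gained cancel in the
count. Detectable void depth is bounded by the 4 mm ROI radius; deeper
cavities are truncated. The volumetric surface surrogate scales with the
channel volume inside the peel, not with a meshed area. The Tb.N ridge
definition is not implemented. MetaImage support covers uncompressed
LOCAL files only.
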